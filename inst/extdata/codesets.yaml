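# Default ICD-10 code sets and diagnosis-position rules for HNC phenotyping.
#
# hnc_codes covers lip / oral cavity / pharynx (C00-C14) and nasal cavity /
# middle ear / accessory sinuses / larynx (C30-C32).  The rare-topography
# list (salivary glands C07-C08, nasopharynx C11, bone C41, nasal cavity
# C300, middle ear C301, accessory sinuses C31) is additionally treated as
# HNC-relevant, which brings in C41 even though bone is not anatomically
# head-and-neck-specific; it is kept as-is, without anatomical sub-filtering.
#
# Codes are dot-free uppercase prefixes: an observed code matches an entry
# when it equals it or extends it (C110 matches C11).  Set
# prefix_matching: false for exact-equality semantics.
#
# Cohort membership and rare-topography evidence use different diagnosis
# positions: HNC-cohort membership requires a primary or related diagnosis,
# while rare-topography evidence is accepted from primary, related or
# associated positions.
hnc_codes:
  - C00
  - C01
  - C02
  - C03
  - C04
  - C05
  - C06
  - C07
  - C08
  - C09
  - C10
  - C11
  - C12
  - C13
  - C14
  - C30
  - C31
  - C32
rare_topography_codes:
  - C07
  - C08
  - C11
  - C41
  - C300
  - C301
  - C31
hnc_positions:
  - primary
  - related
rare_topo_positions:
  - primary
  - related
  - associated
prefix_matching: true
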