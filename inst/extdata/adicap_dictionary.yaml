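# SYNTHETIC ADICAP dictionary fixture.
#
# This is NOT the official ADICAP thesaurus: it is a small, documented
# dictionary sufficient to decode the 8-character codes the synthetic-EHR
# generator embeds in pathology reports, with the same field layout real
# codes use (four 2-character fields).  The field order is configuration,
# not logic: all decoding goes through named fields.
#
# Rarity and malignancy semantics live here, not in code:
#   sites       carry is_hnc and is_rare_topography (REFCOR rare sites:
#               salivary glands, sinus, nasal fossa, nasopharynx, middle ear)
#   behaviours  carry is_malignant
#   histologies carry is_scc (squamous-cell carcinoma is the common HNC
#               histology; any malignant non-SCC histology counts as rare)
field_order: [sample_type, site, behaviour, histology]
cue_pattern: "adicap"
sample_types:
  BH: biopsie
  PH: "pièce opératoire"
  CH: cytologie
sites:
  GS: {label: glande salivaire, is_hnc: true, is_rare_topography: true}
  PA: {label: parotide, is_hnc: true, is_rare_topography: true}
  SM: {label: glande sous-maxillaire, is_hnc: true, is_rare_topography: true}
  SL: {label: glande sublinguale, is_hnc: true, is_rare_topography: true}
  SI: {label: sinus, is_hnc: true, is_rare_topography: true}
  SX: {label: sinus maxillaire, is_hnc: true, is_rare_topography: true}
  SE: {label: "sinus ethmoïdal", is_hnc: true, is_rare_topography: true}
  FN: {label: fosse nasale, is_hnc: true, is_rare_topography: true}
  NP: {label: nasopharynx, is_hnc: true, is_rare_topography: true}
  OM: {label: oreille moyenne, is_hnc: true, is_rare_topography: true}
  OR: {label: oropharynx, is_hnc: true, is_rare_topography: false}
  LA: {label: larynx, is_hnc: true, is_rare_topography: false}
  HP: {label: hypopharynx, is_hnc: true, is_rare_topography: false}
  CB: {label: "cavité buccale", is_hnc: true, is_rare_topography: false}
  LG: {label: langue, is_hnc: true, is_rare_topography: false}
  AM: {label: amygdale, is_hnc: true, is_rare_topography: false}
  LV: {label: "lèvre", is_hnc: true, is_rare_topography: false}
  PO: {label: poumon, is_hnc: false, is_rare_topography: false}
  SN: {label: sein, is_hnc: false, is_rare_topography: false}
  ES: {label: estomac, is_hnc: false, is_rare_topography: false}
  CL: {label: "côlon", is_hnc: false, is_rare_topography: false}
behaviours:
  "70": {label: tumeur maligne primitive, is_malignant: true}
  B0: {label: "lésion bénigne", is_malignant: false}
histologies:
  "80": {label: "carcinome épidermoïde", is_scc: true}
  "81": {label: "adénocarcinome", is_scc: false}
  "82": {label: "carcinome mucoépidermoïde", is_scc: false}
  "83": {label: "mélanome muqueux", is_scc: false}
  "84": {label: "esthésioneuroblastome", is_scc: false}
  "85": {label: sarcome, is_scc: false}
  "86": {label: lymphome, is_scc: false}
  "87": {label: carcinome neuroendocrine, is_scc: false}
  "88": {label: "carcinome indifférencié du nasopharynx", is_scc: false}
  "92": {label: "carcinome adénoïde kystique", is_scc: false}
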