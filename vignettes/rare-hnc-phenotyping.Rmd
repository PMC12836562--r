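---
title: "Multimodal phenotyping of rare head and neck cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal phenotyping of rare head and neck cancer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarehnc)
```

## The phenotyping model

`rarehnc` derives a patient-level clinical status — rare head and neck
cancer (HNC), by rare topography and/or rare histology — from three
heterogeneous EHR signals: ICD-10 hospital claims, ADICAP codes embedded in
pathology reports, and the reports' free text.  The pipeline is strictly
rule-based: every decision is a set-membership or pattern-matching rule
driven by configuration files, so a run is fully auditable and
deterministic.

The underlying assumptions are worth stating explicitly:

* **Prevalence, not incidence.**  Cohort membership is existential over a
  patient's whole record ("at least one qualifying code/report/mention");
  dates are carried but never compared.  The design target is a prevalent
  cohort, so no date-windowing logic exists.
* **Patient-level aggregation.**  Note-level findings are lifted to the
  patient by existential quantification.  Whether a patient has one or ten
  qualifying pathology reports does not change any flag, only the recorded
  provenance.
* **Pathology reports are the anchor.**  A patient without at least one
  pathology report is excluded from the HNC cohort even if claims alone
  look diagnostic, because two of the three evidence sources live inside
  the report.  Multidisciplinary-meeting (MDM) notes are ingested and
  rendered by the generator but never mined: they serve rule development
  in the source setting, not classification.

## Evidence sources and their parameters

### ICD-10 claims

Codes are normalized to dot-free uppercase on ingest so both export
dialects (`C30.0`, `C300`) match the same rules.  Two distinct
diagnosis-position sets are used on purpose:

* HNC-cohort membership requires an HNC code in **primary or related**
  position (`hnc_positions`);
* rare-topography evidence accepts **primary, related or associated**
  positions (`rare_topo_positions`).

The asymmetry mirrors the two rules the algorithm was validated with, and
it means a rare code in associated position can make a patient
rare-flagged without by itself making them an HNC-cohort member.

The default HNC set is the anatomical core C00–C14 (lip, oral cavity,
pharynx) plus C30–C32 (nasal cavity, middle ear, sinuses, larynx); the
rare-topography list C07, C08, C11, C41, C300, C301, C31 is additionally
treated as HNC-relevant.  C41 (bone) is kept exactly as listed even though
it is not head-and-neck-specific; no anatomical sub-filtering is
attempted.  Matching is by prefix (an observed `C110` matches entry
`C11`), with an exact-match switch (`prefix_matching: false`) for
registries that enumerate full codes.  ICD-10 never contributes
rare-histology evidence: the classification simply cannot express it.

### ADICAP codes

ADICAP codes are 8-character tokens whose four 2-character fields describe
sample type, sample site, benign/malignant behaviour and histology type.
The field order is configuration (`field_order`), not logic, because
real-world layouts differ; all downstream logic addresses fields by name.
A token only counts in a *code context*: a cue (default `adicap`,
case-insensitive) earlier on the same line, or the token standing alone on
its line.  Tokens must contain at least one letter, which excludes
8-digit accession numbers and dates.  Both restrictions are deliberate:
the precision of bare 8-character matching without context is unknown, so
the extractor refuses to guess.

Decoding is a field-wise dictionary lookup.  Unknown codes resolve to an
explicit `UNKNOWN` record with all flags `FALSE` — an unrecognized site can
never assert HNC membership.  Rarity semantics live in the dictionary, not
in code: sites carry `is_hnc`/`is_rare_topography`, behaviours
`is_malignant`, histologies `is_scc`.  Evidence rules:

* rare histology ⇔ some code is malignant ∧ HNC site ∧ not SCC;
* rare topography ⇔ some code is in a rare site, by default additionally
  gated on malignancy (`require_malignant_for_topo = TRUE`): the cohort is
  a cancer cohort, and a benign lesion of a rare site is not a rare
  cancer.  The gate is a switch because the topography rule can be read
  either way.

The shipped dictionary is a **synthetic fixture** (21 sites, 10
histologies, 2 behaviours), sufficient for the generator and tests; it is
not the official ADICAP thesaurus, and users with access to the real
thesaurus should swap in their own YAML.

### Free-text mining

Matching is lexicon/regex-based, case- and accent-insensitive.  Both text
and patterns are folded (lowercase, 1:1 diacritic stripping) so matched
offsets remain valid in the original text.  Overlap resolution is
longest-match-wins at equal start, earlier-start-wins otherwise — so
`mélanome muqueux` beats `mélanome` and a mention is never double-counted.

Qualification is a ConText-style simplification: a mention is negated /
hypothetical / historical when a trigger of that class occurs in the same
sentence, on the trigger's side (forward triggers precede the mention,
backward ones follow it), within the trigger's token scope (default 8
tokens; shorter for weak triggers like *sans* or *possible*).  Sentences
are delimited by `". "`, newline, `!`, `?`.  Qualifiers are independent of
one another and never alter the mention's span or label.  Only *asserted*
rare mentions — no qualifier set — become evidence.

The shipped French lexicon (11 histology, 14 topography entries) and
trigger inventory (≈ 25 triggers) are documented fixtures approximating
the REFCOR rare-site definitions.  They are deliberately small: the test
suite separates lexicon-coverage failures from engine-logic failures by
generating text only from lexicon-covered vocabulary.  A deployment
against real reports must expect to grow both files; the 8-token default
scope is a starting point, not a validated constant.

One genuinely open reading: must a rare-histology mention co-occur with an
HNC topography mention?  The default is no (`histology_requires_hnc_context
= FALSE`) because the reports reaching this stage are already HNC-filtered
by cohort construction; the stricter same-note reading is available as a
switch.

## Cohort assembly

Five nested sets are produced: the HNC cohort; the rare-topography and
rare-histology subcohorts (evidence from any admissible source, evaluated
only within the HNC cohort); their union, the rare HNC cohort; and the
consolidated cohort.  Invariants asserted in the test suite: consolidated
⊆ rare ⊆ HNC; |rare| = |topo| + |histo| − |topo ∩ histo|; deleting one
source's evidence can only shrink the rare and consolidated sets; evidence
for a patient outside the HNC cohort is dropped with a warning, never
silently kept.

**Concordance granularity** was the main open design choice.  The
consolidated definition — at least two data sources — does not say whether
the two sources must agree on the *same* rarity flavour.  The default
counts sources at patient level across flavours (an ICD-10 topography hit
plus an NLP histology hit consolidates), which matches the looser printed
definition; `concordance_within_flavour = TRUE` gives the strict reading.
The ambiguity is preserved as a switch rather than resolved.

## Evaluation

Confusion matrices are computed by set arithmetic over an annotated
universe; a brute-force per-patient tally is kept in the tests as an
independent oracle.  Metrics are percentages; a zero denominator yields
`NA` (serialized as `null`), never 0, 100 or an error, because
zero-denominator cells are meaningful in small validation sets.

Two rounding modes exist.  `raw` (default) keeps full precision.  `paper`
rounds **half-to-even** to whole percents: among the 28 published
validation percentages the only exact half, a PPV of 15/24 = 62.5, is
printed as 62, which plain half-up rounding cannot produce while every
other cell is compatible with either rule.  Half-to-even satisfies all 28
cells and is what base R's `round()` implements.  The single-source rows
are judged against the overall rare-HNC gold flag (as in the published
tables); the flavour subcohort rows against their flavour-specific flags.
Both conventions of a "false-positive rate" (FP/total and FP/(FP+TN)) are
exposed side by side in `false_positive_rates()` because published figures
use either without warning.

## The synthetic generator

`simulate_ehr()` draws each patient's latent state first — HNC status, the
joint rare-flavour state, report availability, per-source detection — and
renders claims and notes from it afterwards.  Gold labels are a function
of the latent draw only, so no rendering bug can leak into gold
(*no-leakage* property, tested by deleting all notes and checking gold is
unchanged).

Default conditions:

* joint rare-flavour distribution given HNC: 14% both, 4% topography
  only, 4% histology only — i.e. 18% marginal each and 22% rare overall,
  matching the annotated validation sample;
* report availability 0.85, the published availability rate;
* per-source error rates from the published single-source confusion
  matrices: ADICAP miss 8/22, false 3/78; NLP miss 1/22, false 9/78.
  ICD-10 cannot express histology, so its miss rate applies to the
  rare-topography gold only; the default 3/18 is chosen so that the
  measured ICD-10 sensitivity against the overall rare gold lands near the
  published 15/22 ≈ 68%;
* `p_hnc = 0.9`: the generator emulates a pre-screened referral extract,
  not an all-cancer population, so that the evaluation universe stays
  dense at desk-scale n;
* distractor injection (negation 0.15, hypothesis 0.10, history 0.10):
  sentences that mention rare terms under a suppressing qualifier and must
  never produce evidence;
* sources err independently given the latent state (`shared_miss = 0`);
  the correlation knob exists but the published marginals give no basis
  for a default other than independence.

What the generator deliberately does **not** emulate: real report
narrative and section structure, vocabulary outside the fixture lexicon
(except inside flagged distractors), hospital-level clustering, calendar
time, and the empirical correlation structure between sources.  Passing
tests therefore demonstrate the pipeline's logical correctness and
statistical calibration under controlled conditions — not performance on
real clinical text.

## Numerical and degenerate-input choices

* Ties in lexicon overlap resolution break by entry order after start
  position and length — stable across runs.
* Mentions falling in no sentence (possible only with pathological
  segmentation input) are qualified against their own span instead of
  failing.
* Empty claims or notes tables, empty cohorts and empty evidence sets are
  legal everywhere and produce empty tibbles, not errors.
* The generator preserves the caller's RNG state; two calls with the same
  seed are byte-identical, and the seed is an ordinary 32-bit integer.

## Problem sizes

The test suite exercises the exhaustive single-patient truth table (16
combinations), property checks at n = 150–2000, exact gold recovery on an
error-free simulation at n = 1000, and statistical calibration at
n = 10 000, where the binomial standard error of a measured sensitivity is
well under one percentage point and a ±3-point tolerance is conservative.
The acceptance script uses the same sizes.

## Known limitations

* The fixture dictionary/lexicon/triggers are structural stand-ins; their
  coverage of real French pathology prose is untested by construction.
* The ICD-10 default HNC set is a documented approximation of the full
  (unavailable) deployment list; it is configuration, not code.
* Evaluation assumes the gold table covers the whole universe; there is no
  handling of partially annotated universes beyond a hard error.
* No confidence intervals are attached to the metrics; the published
  comparison values carry none, and the validation sets are small.
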