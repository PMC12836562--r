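# French histology/topography lexicon fixture.
#
# Patterns are regular expressions matched case- and accent-insensitively:
# both pattern and text are lowercased and accent-folded before matching, so
# patterns are written in unaccented lowercase.  Each pattern is wrapped in
# word boundaries by the matcher.
#
# is_rare flags follow the REFCOR definition: rare topography = salivary
# glands, sinus, nasal fossa, nasopharynx, middle ear; rare histology = any
# malignant type excluding squamous-cell carcinoma (SCC).  Non-rare entries
# are deliberately present so that common mentions are recognized (and
# counted as non-evidence) rather than silently unmatched.
entries:
  # --- histology ---
  - {pattern: "carcinome adenoide kystique", category: histology, label: adenoid_cystic_carcinoma, is_rare: true}
  - {pattern: "carcinome mucoepidermoide", category: histology, label: mucoepidermoid_carcinoma, is_rare: true}
  - {pattern: "adenocarcinome", category: histology, label: adenocarcinoma, is_rare: true}
  - {pattern: "melanome( muqueux)?", category: histology, label: mucosal_melanoma, is_rare: true}
  - {pattern: "esthesioneuroblastome", category: histology, label: esthesioneuroblastoma, is_rare: true}
  - {pattern: "(?:[a-z]+o)?sarcome", category: histology, label: sarcoma, is_rare: true}
  - {pattern: "lymphome", category: histology, label: lymphoma, is_rare: true}
  - {pattern: "carcinome neuroendocrine", category: histology, label: neuroendocrine_carcinoma, is_rare: true}
  - {pattern: "carcinome indifferencie( du nasopharynx)?", category: histology, label: undifferentiated_carcinoma, is_rare: true}
  - {pattern: "plasmocytome", category: histology, label: plasmacytoma, is_rare: true}
  - {pattern: "carcinome epidermoide", category: histology, label: squamous_cell_carcinoma, is_rare: false}
  # --- topography ---
  - {pattern: "parotide", category: topography, label: parotid, is_rare: true}
  - {pattern: "glande salivaire", category: topography, label: salivary_gland, is_rare: true}
  - {pattern: "(glande )?sous-maxillaire", category: topography, label: submandibular_gland, is_rare: true}
  - {pattern: "glande sublinguale", category: topography, label: sublingual_gland, is_rare: true}
  - {pattern: "sinus (maxillaire|ethmoidal|frontal|sphenoidal)", category: topography, label: paranasal_sinus, is_rare: true}
  - {pattern: "fosse nasale", category: topography, label: nasal_fossa, is_rare: true}
  - {pattern: "cavum|nasopharynx", category: topography, label: nasopharynx, is_rare: true}
  - {pattern: "oreille moyenne", category: topography, label: middle_ear, is_rare: true}
  - {pattern: "larynx", category: topography, label: larynx, is_rare: false}
  - {pattern: "oropharynx", category: topography, label: oropharynx, is_rare: false}
  - {pattern: "hypopharynx", category: topography, label: hypopharynx, is_rare: false}
  - {pattern: "cavite buccale", category: topography, label: oral_cavity, is_rare: false}
  - {pattern: "langue", category: topography, label: tongue, is_rare: false}
  - {pattern: "amygdale", category: topography, label: tonsil, is_rare: false}
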