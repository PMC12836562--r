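# Phrase pools used to render French-style pathology text.  All asserted
# phrases are covered by the shipped lexicon/dictionary so that lexicon
# coverage and engine logic are tested separately: only distractor
# sentences may mention rare terms under a suppressing qualifier.
RARE_TOPO_PHRASES <- c(
  "la parotide", "la glande sous-maxillaire", "le sinus maxillaire",
  "le sinus ethmoïdal", "la fosse nasale", "le cavum",
  "l'oreille moyenne"
)
COMMON_TOPO_PHRASES <- c("du larynx", "de l'oropharynx", "de la cavité buccale")
RARE_HISTO_PHRASES <- c(
  "carcinome adénoïde kystique", "adénocarcinome",
  "mélanome muqueux", "carcinome mucoépidermoïde",
  "esthésioneuroblastome", "lymphome", "carcinome neuroendocrine"
)
RARE_SITE_CODES <- c("GS", "PA", "SM", "SI", "SX", "SE", "FN", "NP", "OM")
COMMON_SITE_CODES <- c("OR", "LA", "HP", "CB", "LG", "AM")
NONHNC_SITE_CODES <- c("PO", "SN", "ES", "CL")
RARE_HISTO_CODES <- c("81", "82", "83", "84", "85", "86", "87", "88", "92")
COMMON_HNC_ICD10 <- c("C01", "C02", "C04", "C05", "C09", "C10", "C12",
                      "C13", "C32", "C320")
RARE_TOPO_ICD10 <- c("C07", "C08", "C11", "C110", "C300", "C301", "C31",
                     "C312", "C41")
NONHNC_ICD10 <- c("C50", "C341", "C61", "C18", "C20")
NOISE_ICD10 <- c("E11", "I10", "J44", "N18")
DISTRACTOR_NEGATION <- c(
  "Pas d'argument pour un mélanome muqueux.",
  "Absence de carcinome adénoïde kystique résiduel.",
  "Pas d'envahissement de la parotide."
)
DISTRACTOR_HYPOTHESIS <- c(
  "Ces remaniements évoquent un esthésioneuroblastome.",
  "Suspicion de lymphome à confirmer."
)
DISTRACTOR_HISTORY <- c(
  "Antécédent de lymphome traité en 2015.",
  "ATCD de carcinome adénoïde kystique opéré."
)

#' Synthetic-EHR generator parameters
#'
#' The defaults emulate the statistical structure of the source setting:
#' the joint rare-topography/rare-histology distribution given HNC matches
#' the annotated validation sample (14% both, 4% topography only, 4%
#' histology only, hence 18% each marginally and 22% rare overall), 85% of
#' patients have an available pathology report, and the per-source
#' miss/false rates are set from the published single-source confusion
#' matrices: ADICAP miss 8/22 and false 3/78, NLP miss 1/22 and false 9/78.
#' ICD-10 is structurally blind to histology, so its miss rate applies to
#' rare-topography patients only; the default 3/18 makes its measured
#' sensitivity against the overall rare gold come out near the published
#' 68% (15 of 22).
#'
#' @param p_hnc Probability a simulated patient truly has HNC.  The default
#'   0.9 emulates a pre-screened referral extract rather than an all-cancer
#'   population, keeping the evaluation universe dense at small n.
#' @param p_topo_only,p_histo_only,p_both Joint rare-flavour probabilities
#'   given HNC.
#' @param p_report_available Probability a pathology report exists.
#' @param icd10,adicap,nlp Per-source error rates, each
#'   `list(miss = ..., false = ...)`.
#' @param p_negation,p_hypothesis,p_history Injection rates for distractor
#'   sentences carrying a rare term under the respective qualifier; they
#'   must never create evidence.
#' @param p_mdm_note Probability of an (unmined) multidisciplinary-meeting
#'   note.
#' @param p_noise_claim Probability of an unrelated non-cancer claim.
#' @param shared_miss Probability that a rare patient is missed by all
#'   sources jointly (source-correlation knob; default 0 = independent).
#' @return A validated parameter list of class `sim_params`.
#' @export
sim_params <- function(p_hnc = 0.9,
                       p_topo_only = 0.04, p_histo_only = 0.04,
                       p_both = 0.14,
                       p_report_available = 0.85,
                       icd10 = list(miss = 3 / 18, false = 9 / 78),
                       adicap = list(miss = 8 / 22, false = 3 / 78),
                       nlp = list(miss = 1 / 22, false = 9 / 78),
                       p_negation = 0.15, p_hypothesis = 0.1,
                       p_history = 0.1,
                       p_mdm_note = 0.25, p_noise_claim = 0.3,
                       shared_miss = 0) {
  p <- list(p_hnc = p_hnc, p_topo_only = p_topo_only,
            p_histo_only = p_histo_only, p_both = p_both,
            p_report_available = p_report_available,
            icd10 = icd10, adicap = adicap, nlp = nlp,
            p_negation = p_negation, p_hypothesis = p_hypothesis,
            p_history = p_history, p_mdm_note = p_mdm_note,
            p_noise_claim = p_noise_claim, shared_miss = shared_miss)
  probs <- c(p_hnc, p_topo_only, p_histo_only, p_both, p_report_available,
             icd10$miss, icd10$false, adicap$miss, adicap$false,
             nlp$miss, nlp$false, p_negation, p_hypothesis, p_history,
             p_mdm_note, p_noise_claim, shared_miss)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all sim_params proportions must lie in [0, 1]",
          class = "rarehnc_config_error")
  }
  if (p_topo_only + p_histo_only + p_both > 1) {
    abort("rare-flavour probabilities must sum to at most 1",
          class = "rarehnc_config_error")
  }
  structure(p, class = "sim_params")
}

#' Error-free generator parameters
#'
#' Convenience preset: all miss/false rates and all distractor injection
#' rates zero, every pathology report available.  In this limit the
#' pipeline must recover the gold labels exactly.
#'
#' @param ... Overrides passed to [sim_params()].
#' @export
sim_params_noiseless <- function(...) {
  defaults <- list(
    p_report_available = 1,
    icd10 = list(miss = 0, false = 0),
    adicap = list(miss = 0, false = 0),
    nlp = list(miss = 0, false = 0),
    p_negation = 0, p_hypothesis = 0, p_history = 0
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  force(code)
}

#' Generate a synthetic EHR dataset with gold labels
#'
#' Draws, per patient: HNC status, the joint rare-flavour state, pathology
#' report availability, and per-source detection via the miss/false rates;
#' then renders ICD-10 claims and French-style pathology/MDM notes whose
#' embedded ADICAP codes and free-text mentions are consistent with (or,
#' under miss/false draws, deliberately discordant with) the latent state.
#' Gold labels are fixed by the latent draw *before* any rendering, so
#' corrupting the rendering can change pipeline output but never gold.
#' Deterministic given `seed`.
#'
#' @param n_patients Number of patients.
#' @param seed Integer RNG seed.
#' @param params Parameter list from [sim_params()].
#' @return An object of class `ehr_simulation`: a list with `dataset` (an
#'   [ehr_dataset()]), `gold` (per-patient gold labels), `truth`
#'   (per-source detection truth used for calibration checks), plus
#'   `params` and `seed`.
#' @examples
#' sim <- simulate_ehr(50, seed = 7)
#' sim$dataset
#' @export
simulate_ehr <- function(n_patients = 1000, seed = 1,
                         params = sim_params()) {
  stopifnot(inherits(params, "sim_params"), n_patients >= 1)
  with_preserved_rng({
    set.seed(as.integer(seed))
    n <- as.integer(n_patients)
    p <- params
    person_id <- sprintf("P%05d", seq_len(n))

    age <- pmin(pmax(round(stats::rnorm(n, 64, 12)), 18), 95)
    birth_year <- ifelse(stats::runif(n) < 0.02, NA_integer_,
                         as.integer(2024 - age))
    sex <- ifelse(stats::runif(n) < 0.02, "unknown",
                  ifelse(stats::runif(n) < 2 / 3, "male", "female"))

    is_hnc <- stats::runif(n) < p$p_hnc
    u <- stats::runif(n)
    rare_topo <- is_hnc & (u < p$p_both + p$p_topo_only)
    rare_histo <- is_hnc & ((u < p$p_both) |
      (u >= p$p_both + p$p_topo_only &
         u < p$p_both + p$p_topo_only + p$p_histo_only))
    is_rare <- rare_topo | rare_histo
    report <- stats::runif(n) < p$p_report_available

    # icd10 applies to rare-topography gold only (claims cannot express
    # histology); false draws apply to gold-negative (non-rare) HNC patients
    icd10_det <- (rare_topo & stats::runif(n) >= p$icd10$miss) |
      (is_hnc & !is_rare & stats::runif(n) < p$icd10$false)
    adicap_det <- (is_rare & stats::runif(n) >= p$adicap$miss) |
      (is_hnc & !is_rare & stats::runif(n) < p$adicap$false)
    nlp_det <- (is_rare & stats::runif(n) >= p$nlp$miss) |
      (is_hnc & !is_rare & stats::runif(n) < p$nlp$false)
    if (p$shared_miss > 0) {
      joint <- is_rare & stats::runif(n) < p$shared_miss
      icd10_det <- icd10_det & !joint
      adicap_det <- adicap_det & !joint
      nlp_det <- nlp_det & !joint
    }

    # flavour carried by each detecting source: gold flavours for rare
    # patients, a coin flip for manufactured false positives
    fp_topo <- stats::runif(n) < 0.5
    adicap_topo <- adicap_det & (rare_topo | (!is_rare & fp_topo))
    adicap_histo <- adicap_det & (rare_histo | (!is_rare & !fp_topo))
    fp_topo_nlp <- stats::runif(n) < 0.5
    nlp_topo <- nlp_det & (rare_topo | (!is_rare & fp_topo_nlp))
    nlp_histo <- nlp_det & (rare_histo | (!is_rare & !fp_topo_nlp))

    # ---- claims ----
    base_code <- ifelse(is_hnc,
                        sample(COMMON_HNC_ICD10, n, replace = TRUE),
                        sample(NONHNC_ICD10, n, replace = TRUE))
    claims <- tibble(person_id = person_id, icd10_code = base_code,
                     diagnosis_position = "primary")
    rare_idx <- which(icd10_det)
    if (length(rare_idx) > 0) {
      claims <- bind_rows(claims, tibble(
        person_id = person_id[rare_idx],
        icd10_code = sample(RARE_TOPO_ICD10, length(rare_idx),
                            replace = TRUE),
        diagnosis_position = sample(DIAG_POSITIONS, length(rare_idx),
                                    replace = TRUE)
      ))
    }
    noise_idx <- which(stats::runif(n) < p$p_noise_claim)
    if (length(noise_idx) > 0) {
      claims <- bind_rows(claims, tibble(
        person_id = person_id[noise_idx],
        icd10_code = sample(NOISE_ICD10, length(noise_idx), replace = TRUE),
        diagnosis_position = "associated"
      ))
    }

    # ---- pathology notes ----
    sample_type <- sample(c("BH", "PH", "CH"), n, replace = TRUE)
    site_code <- ifelse(!is_hnc,
                        sample(NONHNC_SITE_CODES, n, replace = TRUE),
                        ifelse(adicap_topo,
                               sample(RARE_SITE_CODES, n, replace = TRUE),
                               sample(COMMON_SITE_CODES, n, replace = TRUE)))
    behaviour_code <- ifelse(is_hnc, "70",
                             ifelse(stats::runif(n) < 0.5, "70", "B0"))
    histo_code <- ifelse(adicap_histo,
                         sample(RARE_HISTO_CODES, n, replace = TRUE),
                         "80")
    adicap_raw <- paste0(sample_type, site_code, behaviour_code, histo_code)

    topo_sentence <- ifelse(
      nlp_topo,
      sprintf("Prélèvement au niveau de %s.",
              sample(RARE_TOPO_PHRASES, n, replace = TRUE)),
      sprintf("Prélèvement %s.",
              sample(COMMON_TOPO_PHRASES, n, replace = TRUE))
    )
    histo_sentence <- ifelse(
      nlp_histo,
      sprintf("L'aspect histologique est celui d'un %s.",
              sample(RARE_HISTO_PHRASES, n, replace = TRUE)),
      "Aspect de carcinome épidermoïde bien différencié."
    )
    nonhnc_body <- "Prolifération tumorale sans spécificité ORL."
    distract <- function(rate, pool) {
      ifelse(stats::runif(n) < rate,
             sample(pool, n, replace = TRUE), "")
    }
    extra <- paste(distract(p$p_negation, DISTRACTOR_NEGATION),
                   distract(p$p_hypothesis, DISTRACTOR_HYPOTHESIS),
                   distract(p$p_history, DISTRACTOR_HISTORY))
    extra <- trimws(gsub(" +", " ", extra))

    body <- ifelse(is_hnc, paste(topo_sentence, histo_sentence),
                   nonhnc_body)
    path_text <- paste0(
      "Compte rendu anatomopathologique.\n",
      body,
      ifelse(nzchar(extra), paste0(" ", extra), ""),
      "\nCode ADICAP : ", adicap_raw, "\n"
    )
    path_idx <- which(report)
    notes <- tibble(
      note_id = sprintf("N%05d-path", path_idx),
      person_id = person_id[path_idx],
      note_type = "pathology_report",
      text = path_text[path_idx]
    )

    # ---- MDM notes (rendered, never mined) ----
    mdm_idx <- which(stats::runif(n) < p$p_mdm_note)
    if (length(mdm_idx) > 0) {
      mdm_text <- ifelse(
        is_rare[mdm_idx],
        sprintf("RCP ORL : %s de %s. Proposition de chirurgie.",
                sample(RARE_HISTO_PHRASES, length(mdm_idx), replace = TRUE),
                sample(RARE_TOPO_PHRASES, length(mdm_idx), replace = TRUE)),
        "RCP ORL : dossier discuté. Surveillance proposée."
      )
      notes <- bind_rows(notes, tibble(
        note_id = sprintf("N%05d-mdm", mdm_idx),
        person_id = person_id[mdm_idx],
        note_type = "mdm_report",
        text = mdm_text
      ))
    }

    dataset <- ehr_dataset(
      tibble(person_id = person_id, birth_year = birth_year, sex = sex),
      claims, notes
    )
    gold <- tibble(
      person_id = person_id,
      is_rare_topography = rare_topo,
      is_rare_histology = rare_histo,
      is_rare_hnc = is_rare
    )
    truth <- tibble(
      person_id = person_id, is_hnc = is_hnc,
      report_available = report,
      icd10_detected = icd10_det,
      adicap_detected = adicap_det, nlp_detected = nlp_det,
      adicap_topo = adicap_topo, adicap_histo = adicap_histo,
      nlp_topo = nlp_topo, nlp_histo = nlp_histo
    )
    structure(list(dataset = dataset, gold = gold, truth = truth,
                   params = p, seed = as.integer(seed), n_patients = n),
              class = "ehr_simulation")
  })
}

#' @export
print.ehr_simulation <- function(x, ...) {
  cat(sprintf("<ehr_simulation> %d patients, seed %d\n", x$n_patients,
              x$seed))
  cat(sprintf("  gold: %d HNC, %d rare (%d topo / %d histo)\n",
              sum(x$truth$is_hnc), sum(x$gold$is_rare_hnc),
              sum(x$gold$is_rare_topography), sum(x$gold$is_rare_histology)))
  print(x$dataset)
  invisible(x)
}

#' One-row summary of a simulation
#'
#' @param x An `ehr_simulation`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ehr_simulation <- function(x, ...) {
  tibble(
    n_patients = x$n_patients, seed = x$seed,
    n_hnc = sum(x$truth$is_hnc),
    n_rare = sum(x$gold$is_rare_hnc),
    n_rare_topography = sum(x$gold$is_rare_topography),
    n_rare_histology = sum(x$gold$is_rare_histology),
    n_with_report = sum(x$truth$report_available),
    n_notes = nrow(x$dataset$notes)
  )
}

#' Write a simulation to disk
#'
#' Writes `persons.csv`, `claims.csv`, `notes.csv`, `gold.csv` and
#' `truth.json` under `dir`.
#'
#' @param sim An `ehr_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$dataset$persons, file.path(dir, "persons.csv"),
                   progress = FALSE)
  readr::write_csv(sim$dataset$claims, file.path(dir, "claims.csv"),
                   progress = FALSE)
  readr::write_csv(sim$dataset$notes, file.path(dir, "notes.csv"),
                   progress = FALSE)
  readr::write_csv(sim$gold, file.path(dir, "gold.csv"), progress = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
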