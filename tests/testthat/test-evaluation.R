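# brute-force oracle: tally each patient individually
oracle_confusion <- function(predicted, positives, universe) {
  tp <- fp <- fn <- tn <- 0L
  for (p in universe) {
    pred <- p %in% predicted
    pos <- p %in% positives
    if (pred && pos) tp <- tp + 1L
    else if (pred && !pos) fp <- fp + 1L
    else if (!pred && pos) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

random_gold <- function(universe, p = 0.3) {
  tibble::tibble(
    person_id = universe,
    is_rare_topography = stats::runif(length(universe)) < p,
    is_rare_histology = stats::runif(length(universe)) < p
  ) %>% dplyr::mutate(is_rare_hnc = is_rare_topography | is_rare_histology)
}

test_that("set-arithmetic confusion equals a per-patient brute-force tally", {
  set.seed(7)
  universe <- sprintf("U%03d", 1:60)
  for (rep in 1:25) {
    gold <- random_gold(universe)
    predicted <- sample(universe, rbinom(1, 60, 0.4))
    cm <- confusion_matrix(predicted, gold, universe)
    want <- oracle_confusion(predicted,
                             gold$person_id[gold$is_rare_hnc], universe)
    expect_equal(c(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn), want)
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, length(universe))
  }
})

test_that("degenerate predictions produce the forced corner matrices", {
  universe <- sprintf("U%03d", 1:100)
  gold <- tibble::tibble(person_id = universe,
                         is_rare_topography = c(rep(TRUE, 22), rep(FALSE, 78)),
                         is_rare_histology = FALSE) %>%
    dplyr::mutate(is_rare_hnc = is_rare_topography)
  none <- confusion_matrix(character(), gold, universe)
  expect_equal(unlist(none), c(tp = 0L, fp = 0L, fn = 22L, tn = 78L))
  all <- confusion_matrix(universe, gold, universe)
  expect_equal(unlist(all), c(tp = 22L, fp = 78L, fn = 0L, tn = 0L))
})

test_that("missing gold and out-of-universe predictions are hard errors", {
  gold <- random_gold(c("A", "B"))
  expect_error(confusion_matrix("A", gold, c("A", "B", "C")),
               regexp = "C", class = "rarehnc_evaluation_error")
  expect_error(confusion_matrix("Z", gold, c("A", "B")),
               regexp = "Z", class = "rarehnc_evaluation_error")
})

test_that("metric identities hold exactly before rounding", {
  set.seed(11)
  for (rep in 1:200) {
    cm <- tibble::tibble(tp = rpois(1, 20), fp = rpois(1, 10),
                         fn = rpois(1, 5), tn = rpois(1, 60))
    m <- dx_metrics(cm)
    if (!is.na(m$sensitivity)) {
      expect_equal(m$sensitivity * (cm$tp + cm$fn), 100 * cm$tp)
    }
    if (!is.na(m$specificity)) {
      expect_equal(m$specificity * (cm$tn + cm$fp), 100 * cm$tn)
    }
    if (!is.na(m$ppv)) expect_equal(m$ppv * (cm$tp + cm$fp), 100 * cm$tp)
    if (!is.na(m$npv)) expect_equal(m$npv * (cm$tn + cm$fn), 100 * cm$tn)
    # raw metrics are scale-invariant
    k <- sample(2:5, 1)
    scaled <- dx_metrics(cm * k)
    expect_equal(scaled[, c("sensitivity", "specificity", "ppv", "npv")],
                 m[, c("sensitivity", "specificity", "ppv", "npv")])
  }
})

test_that("swapping gold labels swaps Se<->Sp and PPV<->NPV", {
  set.seed(13)
  universe <- sprintf("U%03d", 1:50)
  for (rep in 1:20) {
    gold <- random_gold(universe)
    flipped <- gold %>% dplyr::mutate(
      is_rare_hnc = !is_rare_hnc)
    predicted <- sample(universe, rbinom(1, 50, 0.5))
    complement <- setdiff(universe, predicted)
    m <- dx_metrics(confusion_matrix(predicted, gold, universe))
    m2 <- dx_metrics(confusion_matrix(complement, flipped, universe))
    expect_equal(m2$sensitivity, m$specificity)
    expect_equal(m2$specificity, m$sensitivity)
    expect_equal(m2$ppv, m$npv)
    expect_equal(m2$npv, m$ppv)
  }
})

test_that("zero denominators yield NA metrics, never errors", {
  m <- dx_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0, tn = 100))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_equal(m$specificity, 100)
  expect_equal(m$npv, 100)
  # NA serializes as null, not 0 or 100
  json <- jsonlite::toJSON(m, na = "null")
  expect_match(as.character(json), '"sensitivity":null')
})

test_that("paper rounding is half-to-even on the percent scale", {
  m <- dx_metrics(tibble::tibble(tp = 15, fp = 9, fn = 7, tn = 69), "paper")
  expect_equal(m$ppv, 62)  # 15/24 = 62.5 rounds to even
  expect_equal(m$sensitivity, 68)
  m2 <- dx_metrics(tibble::tibble(tp = 21, fp = 9, fn = 1, tn = 69), "paper")
  expect_equal(unlist(m2[, c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 95, specificity = 88, ppv = 70, npv = 99))
})

test_that("both false-positive-rate conventions are exposed", {
  fpr <- false_positive_rates(tibble::tibble(tp = 21, fp = 9, fn = 1, tn = 69))
  expect_equal(fpr$fp_per_total, 9)
  expect_equal(fpr$fp_per_negative, 100 * 9 / 78)
})

test_that("a perfect predictor scores 100 on every defined metric", {
  universe <- sprintf("U%03d", 1:40)
  set.seed(17)
  gold <- random_gold(universe)
  asg <- tibble::tibble(
    person_id = universe,
    in_hnc = TRUE,
    in_rare_topography = gold$is_rare_topography,
    in_rare_histology = gold$is_rare_histology,
    in_rare = gold$is_rare_hnc,
    in_consolidated = gold$is_rare_hnc,
    sources = purrr::map(gold$is_rare_hnc,
                         ~ if (.x) c("ADICAP", "NLP") else character())
  )
  ev <- dplyr::bind_rows(
    tibble::tibble(person_id = gold$person_id[gold$is_rare_topography],
                   source = "ADICAP", flavour = "rare_topography",
                   provenance = "x"),
    tibble::tibble(person_id = gold$person_id[gold$is_rare_histology],
                   source = "ADICAP", flavour = "rare_histology",
                   provenance = "x"),
    tibble::tibble(person_id = gold$person_id[gold$is_rare_hnc],
                   source = "NLP", flavour = "rare_histology",
                   provenance = "x"),
    tibble::tibble(person_id = gold$person_id[gold$is_rare_hnc],
                   source = "ICD10", flavour = "rare_topography",
                   provenance = "x")
  )
  # note: the manufactured ICD10/NLP evidence here is deliberately
  # patient-level-perfect against is_rare_hnc, not flavour-faithful
  ev_eval <- evaluate_cohorts(asg, ev, gold)
  per_source <- as.data.frame(ev_eval)[1:3, ]
  expect_true(all(per_source$sensitivity == 100))
  expect_true(all(per_source$specificity == 100))
  cohorts <- as.data.frame(ev_eval)[4:7, ]
  # flavour rows are judged against flavour gold; rare/consolidated vs rare
  expect_true(all(cohorts$sensitivity == 100, na.rm = TRUE))
  expect_true(all(cohorts$specificity == 100, na.rm = TRUE))
})

test_that("tidy, glance and autoplot work on an evaluation", {
  universe <- sprintf("U%03d", 1:30)
  set.seed(19)
  gold <- random_gold(universe)
  asg <- tibble::tibble(
    person_id = universe, in_hnc = TRUE,
    in_rare_topography = gold$is_rare_topography,
    in_rare_histology = FALSE,
    in_rare = gold$is_rare_topography,
    in_consolidated = FALSE,
    sources = purrr::map(gold$is_rare_topography,
                         ~ if (.x) "ICD10" else character())
  )
  ev <- tibble::tibble(person_id = gold$person_id[gold$is_rare_topography],
                       source = "ICD10", flavour = "rare_topography",
                       provenance = "x")
  res <- evaluate_cohorts(asg, ev, gold)
  td <- tidy(res)
  expect_equal(nrow(td), 7 * 4)
  expect_setequal(unique(td$metric),
                  c("sensitivity", "specificity", "ppv", "npv"))
  gl <- glance(res)
  expect_equal(gl$n_annotated, 30)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("cohort summaries agree with a sort-based oracle", {
  set.seed(23)
  n <- 40
  persons <- tibble::tibble(
    person_id = sprintf("S%02d", 1:n),
    birth_year = sample(1940:1990, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
  asg <- tibble::tibble(
    person_id = persons$person_id, in_hnc = TRUE,
    in_rare_topography = FALSE, in_rare_histology = FALSE,
    in_rare = FALSE, in_consolidated = FALSE,
    sources = list(character())
  )
  sm <- cohort_summary(asg, persons, reference_year = 2024)
  hnc <- sm[sm$cohort == "hnc", ]
  ages <- sort(2024 - persons$birth_year)
  expect_equal(hnc$median_age, stats::median(ages))
  expect_equal(hnc$age_q1, unname(stats::quantile(ages, 0.25)))
  expect_equal(hnc$age_q3, unname(stats::quantile(ages, 0.75)))
  expect_equal(hnc$sex_ratio,
               sum(persons$sex == "male") / sum(persons$sex == "female"))
  expect_equal(sm$n[sm$cohort == "rare"], 0L)
  # all-unknown sex: undefined ratio, reported as NA with counts
  persons$sex <- "unknown"
  sm2 <- cohort_summary(asg, persons)
  expect_true(is.na(sm2$sex_ratio[sm2$cohort == "hnc"]))
  expect_equal(sm2$n_sex_unknown[sm2$cohort == "hnc"], n)
  # simple fixed case
  p3 <- tibble::tibble(person_id = c("A", "B", "C"),
                       birth_year = 2024 - c(60, 64, 70),
                       sex = "male")
  a3 <- asg[1:3, ] %>% dplyr::mutate(person_id = c("A", "B", "C"))
  expect_equal(cohort_summary(a3, p3)$median_age[1], 64)
})
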