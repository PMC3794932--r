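test_that("threshold events use a strict inequality and count recurrences separately", {
  labs <- quiet_cohort(
    labs = lab_series("A1", c(4.1, 5.4, 5.6, 5.5, 5.6, 5.6, 5.6, 4.2)),
    admissions = mk_adm("A1", 0, 7))$labs
  ev <- detect_lab_threshold_events(labs, "potassium", 5.5)
  expect_equal(nrow(ev), 4)              # 5.5 itself never qualifies
  expect_equal(ev$index_date, d(c(2, 4, 5, 6)))
  expect_equal(ev$severity_value, rep(5.6, 4))
  expect_equal(unique(ev$event_kind), "lab_threshold")

  nominal <- quiet_cohort(labs = mk_lab("A1", "positive", 3, analyte = "tox"),
                          admissions = mk_adm("A1", 0, 7))$labs
  expect_error(detect_lab_threshold_events(nominal, "tox", 5.5),
               "quantitative")
})

test_that("raising the threshold never increases the number of events", {
  set.seed(11)
  vals <- round(runif(60, 3.5, 7.5), 2)
  labs <- quiet_cohort(labs = lab_series("A1", vals),
                       admissions = mk_adm("A1", 0, 59))$labs
  counts <- vapply(seq(4, 7.5, by = 0.25), function(t) {
    nrow(detect_lab_threshold_events(labs, "potassium", t))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("order and result events are both emitted, stratified by outcome", {
  labs <- quiet_cohort(
    labs = dplyr::bind_rows(
      mk_lab("A1", "positive", 13, order_days = 10, analyte = "tox"),
      mk_lab("A1", "negative", 8, order_days = 6, analyte = "tox")),
    admissions = mk_adm("A1", 0, 20))$labs
  ev <- detect_order_and_result_events(labs, "tox")
  expect_equal(nrow(ev), 4)
  orders <- ev[ev$event_kind == "test_order", ]
  expect_equal(orders$index_date, d(c(6, 10)))
  expect_equal(ev$index_date[ev$event_kind == "test_result_positive"], d(13))
  expect_equal(ev$index_date[ev$event_kind == "test_result_negative"], d(8))
})

test_that("an order with no result yields the order event only, with a warning", {
  labs <- tibble::tibble(patient_id = "p", admission_id = "A1",
                         analyte = "tox", value = NA_character_,
                         value_num = NA_real_,
                         order_date = d(10), result_date = as.Date(NA))
  expect_warning(ev <- detect_order_and_result_events(labs, "tox"),
                 "order event only")
  expect_equal(ev$event_kind, "test_order")
  expect_equal(nrow(ev), 1)
})

test_that("admission timing eligibility includes exactly admit+4 .. discharge-1", {
  adm <- mk_adm("A1", 0, 10)
  ev <- detect_lab_threshold_events(
    quiet_cohort(labs = lab_series("A1", c(rep(4, 3), rep(5.6, 8))),
                 admissions = adm)$labs, "potassium", 5.5)
  w <- apply_admission_eligibility(ev, adm)
  status <- setNames(w$eligible, as.integer(w$index_date - d(0)))
  expect_false(status[["3"]])
  expect_true(status[["4"]])
  expect_true(status[["9"]])    # discharge - 1
  expect_false(status[["10"]])  # discharge day
  reasons <- setNames(w$exclusion_reasons, names(status))
  expect_equal(reasons[["3"]], "too_early")
  expect_equal(reasons[["10"]], "too_late")
  expect_error(apply_admission_eligibility(
    dplyr::mutate(ev, admission_id = "A9"), adm), "A9")
})

test_that("baseline exclusion needs observed abnormality before the window", {
  # three admissions: abnormal baseline, normal baseline, no baseline
  adm <- dplyr::bind_rows(mk_adm("A1", 0, 12), mk_adm("A2", 0, 12),
                          mk_adm("A3", 0, 12))
  labs <- quiet_cohort(labs = dplyr::bind_rows(
    mk_lab("A1", c(5.8, 4.0, 5.6), c(0, 1, 6)),
    mk_lab("A2", c(4.0, 5.6), c(0, 6)),
    mk_lab("A3", 5.6, 6)), admissions = adm)$labs
  ev <- detect_lab_threshold_events(labs, "potassium", 5.5)
  w <- apply_baseline_exclusion(apply_admission_eligibility(ev, adm),
                                labs, "potassium", 5.5)
  # A1's day-0 baseline is itself above threshold and yields an extra
  # (too-early) event; the day-6 event is the one the baseline rule excludes
  by_adm <- split(w[w$index_date == d(6), ],
                  w$admission_id[w$index_date == d(6)])
  expect_false(by_adm$A1$eligible)
  expect_equal(by_adm$A1$exclusion_reasons[[1]], "abnormal_baseline")
  expect_true(by_adm$A2$eligible)
  expect_true(by_adm$A3$eligible)
  expect_equal(by_adm$A3$flags[[1]], "no_baseline")
})

test_that("diagnosis exclusion matches ICD-10 prefixes and can be disabled", {
  adm <- dplyr::bind_rows(lapply(paste0("A", 1:5), mk_adm, admit = 0,
                                 discharge = 12))
  labs <- quiet_cohort(
    labs = dplyr::bind_rows(lapply(paste0("A", 1:5), mk_lab, value = 5.6,
                                   days = 6)),
    admissions = adm)$labs
  dx <- mk_dx(c("pt_A1", "pt_A3", "pt_A4"), c("N18.5", "I12.0", "E11.9"))
  ev <- detect_lab_threshold_events(labs, "potassium", 5.5)
  w0 <- apply_admission_eligibility(ev, adm)
  w <- apply_diagnosis_exclusion(w0, dx, c("N18", "I12.0"))
  expect_equal(sum(!w$eligible), 2)
  expect_setequal(w$patient_id[!w$eligible], c("pt_A1", "pt_A3"))
  expect_true(all(apply_diagnosis_exclusion(w0, dx, character())$eligible))
})

test_that("filters partition windows and commute", {
  set.seed(21)
  params <- cohort_params(n_patients = 40, seed = 33,
                          drugs = list(drug_intent("X", 0.2, 2)),
                          renal_dx_prob = 0.25)
  co <- simulate_cohort(params)
  ev <- detect_lab_threshold_events(co$labs, "potassium", 5.5)
  w0 <- apply_admission_eligibility(ev, co$admissions)
  expect_equal(nrow(w0), nrow(ev))
  filters <- list(
    base = function(w) apply_baseline_exclusion(w, co$labs, "potassium", 5.5),
    dx = function(w) apply_diagnosis_exclusion(w, co$diagnoses, "N18"))
  key <- function(w) paste(w$admission_id, w$index_date)[w$eligible]
  ab <- filters$dx(filters$base(w0))
  ba <- filters$base(filters$dx(w0))
  expect_equal(nrow(ab), nrow(w0))
  expect_setequal(key(ab), key(ba))
  # filters only flip eligible -> ineligible
  expect_true(all(key(ab) %in% key(w0)))
})

test_that("the minimum event gap keeps the earliest event of each cluster", {
  adm <- mk_adm("A1", 0, 30)
  labs <- quiet_cohort(
    labs = mk_lab("A1", rep(5.8, 4), c(6, 7, 9, 20)),
    admissions = adm)$labs
  cfg <- event_config(min_event_gap_days = 3)
  ev <- detect_events(labs, cfg)
  expect_equal(ev$index_date, d(c(6, 9, 20)))
  cfg0 <- event_config()
  expect_equal(nrow(detect_events(labs, cfg0)), 4)
})
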