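make_curve <- function(counts, drug = "drug") {
  cumulate(window_counts(counts, drug_code = drug))
}

test_that("window counts localise prescriptions to day offsets and pool additively", {
  adm <- mk_adm("A1", 0, 12)
  labs <- quiet_cohort(labs = mk_lab("A1", 5.8, 6), admissions = adm)$labs
  ev <- detect_lab_threshold_events(labs, "potassium", 5.5)
  w <- eligible_windows(apply_admission_eligibility(ev, adm))
  rx <- mk_rx("A1", "KCL", 6)   # on D0
  wc <- tabulate_window_counts(rx, w, "KCL")
  expect_equal(unname(wc$counts), c(0, 0, 0, 0, 1, 0))
  # two identical pooled windows double every count
  w2 <- dplyr::bind_rows(w, w)
  wc2 <- tabulate_window_counts(rx, w2, "KCL")
  expect_equal(wc2$counts, 2 * wc$counts)
  expect_equal(wc2$n_windows, 2)
  # ineligible windows are refused
  w_bad <- apply_admission_eligibility(ev, mk_adm("A1", 4, 12))
  expect_error(tabulate_window_counts(rx, w_bad, "KCL"), "eligible")
})

test_that("pooled counts equal a brute-force scan on randomized toy cohorts", {
  for (seed in c(101, 202, 303)) {
    params <- cohort_params(n_patients = 30, seed = seed,
                            drugs = list(drug_intent("X", 0.3, 3),
                                         drug_intent("Y", 0.25, 0.3)))
    co <- simulate_cohort(params)
    w <- eligible_windows(build_windows(co, event_config()))
    for (drug in c("X", "Y")) {
      wc <- tabulate_window_counts(co$prescriptions, w, drug)
      expect_equal(wc$counts, oracle_window_counts(co$prescriptions, w, drug))
    }
  }
})

test_that("cumulative curves are running totals whose differences invert them", {
  expect_equal(unname(make_curve(rep(1, 6))$cumulative), 1:6)
  expect_equal(unname(make_curve(rep(0, 6))$cumulative), rep(0, 6))
  set.seed(5)
  for (i in 1:10) {
    counts <- rpois(6, 4)
    cv <- make_curve(counts)
    expect_equal(diff(c(0, unname(cv$cumulative))), as.numeric(counts))
    expect_true(all(diff(cv$cumulative) >= 0))
    expect_equal(cv$n_prescriptions, sum(counts))
  }
})

test_that("average slopes reproduce the worked example and reject bad spans", {
  cv <- make_curve(c(20, 17, 17, 8, 6, 6))
  expect_equal(unname(cv$cumulative), c(20, 37, 54, 62, 68, 74))
  expect_equal(average_slope(cv, -4, -2), 17)
  expect_equal(average_slope(cv, -1, 1), 6)
  expect_equal(average_slope(make_curve(c(3, 0, 0, 0, 0, 0)), -4, -2), 0)
  expect_error(average_slope(cv, 1, -1), "strictly less")
  expect_error(average_slope(cv, -5, 0), "offsets")
})

test_that("the PCI is the after/before slope ratio with tagged degenerate cases", {
  res <- compute_pci(make_curve(c(20, 17, 17, 8, 6, 6)))
  expect_equal(res$pci, 6 / 17)
  expect_equal(round(res$pci, 3), 0.353)
  expect_equal(as.character(res$pattern), "discontinuation")

  sym <- compute_pci(make_curve(c(1, 3, 4, 2, 3, 4)))
  expect_equal(sym$pci, 1)
  expect_equal(as.character(sym$pattern), "maintenance")

  inf <- compute_pci(make_curve(c(2, 0, 0, 5, 3, 0)))
  expect_identical(inf$pci, Inf)
  expect_equal(as.character(inf$pattern), "intervention")

  und <- compute_pci(make_curve(c(2, 0, 0, 5, 0, 0)))
  expect_true(is.na(und$pci))
  expect_equal(as.character(und$pattern), "indeterminate")
})

test_that("only the D-3, D-2, D0, D+1 counts ever move the PCI", {
  set.seed(9)
  for (i in 1:20) {
    counts <- rpois(6, 3)
    res <- compute_pci(make_curve(counts))
    direct <- if (counts[2] + counts[3] > 0) {
      (counts[5] + counts[6]) / (counts[2] + counts[3])
    } else if (counts[5] + counts[6] > 0) Inf else NA_real_
    expect_equal(res$pci, direct)
    # perturb the anchor days D-4 and D-1 only
    perturbed <- counts + c(7, 0, 0, 11, 0, 0)
    expect_equal(compute_pci(make_curve(perturbed))$pci, res$pci)
    # integer scaling leaves the index unchanged
    if (!is.na(res$pci) && is.finite(res$pci)) {
      expect_equal(compute_pci(make_curve(counts * 5))$pci, res$pci)
    }
  }
})

test_that("classification follows the stated boundary inequalities", {
  pci <- c(0.666, 0.667, 0.668, 1.500, 1.501, Inf, NA)
  expect_equal(as.character(classify_pattern(pci)),
               c("discontinuation", "discontinuation", "maintenance",
                 "maintenance", "intervention", "intervention",
                 "indeterminate"))
  expect_error(classify_pattern(-0.1), "nonnegative")
  custom <- cutoff_config(lower = 0.5, upper = 2)
  expect_equal(as.character(classify_pattern(c(0.6, 1.8), custom)),
               c("maintenance", "maintenance"))
  expect_error(cutoff_config(lower = 2, upper = 1))
})

test_that("run_pace composes the pipeline and handles empty inputs", {
  params <- cohort_params(n_patients = 60, seed = 13,
                          drugs = list(drug_intent("X", 0.3, 3)))
  co <- simulate_cohort(params)
  res <- run_pace(co, event_config(), c("X", "NEVER"))
  expect_equal(nrow(res), 2)
  never <- res[res$drug_code == "NEVER", ]
  expect_true(is.na(never$pci))
  expect_equal(as.character(never$pattern), "indeterminate")
  expect_error(run_pace(co, event_config(), character()), "non-empty")

  # no eligible windows -> indeterminate with a run-level warning
  short <- simulate_cohort(cohort_params(n_patients = 5, seed = 1,
                                         stay_range = c(8, 10),
                                         event_day_prob = 0,
                                         drugs = list(drug_intent("X", 0.3))))
  expect_warning(res0 <- run_pace(short, event_config(), "X"),
                 "no eligible")
  expect_equal(as.character(res0$pattern), "indeterminate")
})

test_that("pooled counts over disjoint sub-cohorts add", {
  p1 <- cohort_params(n_patients = 25, seed = 61,
                      drugs = list(drug_intent("X", 0.3, 2)))
  p2 <- cohort_params(n_patients = 25, seed = 62,
                      drugs = list(drug_intent("X", 0.3, 2)))
  c1 <- simulate_cohort(p1)
  c2 <- simulate_cohort(p2)
  # relabel c2 ids so the pooled cohort is disjoint
  relabel <- function(x) {
    for (tb in names(x)) {
      for (col in intersect(c("patient_id", "admission_id"), names(x[[tb]]))) {
        x[[tb]][[col]] <- paste0("b_", x[[tb]][[col]])
      }
    }
    x
  }
  c2 <- relabel(c2)
  pooled <- quiet_cohort(
    prescriptions = dplyr::bind_rows(c1$prescriptions, c2$prescriptions),
    labs = dplyr::bind_rows(c1$labs, c2$labs),
    admissions = dplyr::bind_rows(c1$admissions, c2$admissions),
    diagnoses = dplyr::bind_rows(c1$diagnoses, c2$diagnoses))
  count_of <- function(co) {
    w <- eligible_windows(build_windows(co, event_config()))
    tabulate_window_counts(co$prescriptions, w, "X")$counts
  }
  expect_equal(count_of(pooled), count_of(c1) + count_of(c2))
})
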