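#' Prescribing intent for one synthetic drug
#'
#' Generative parameters for one drug in a simulated cohort: a constant
#' daily probability of prescription before the drug's trigger, multiplied
#' by `post_event_multiplier` from the trigger (plus `onset_offset` days)
#' onward. A multiplier above 1 encodes an intervention intent, below 1 a
#' discontinuation intent, and exactly 1 event-independent (maintenance)
#' prescribing.
#'
#' @param drug_code drug identifier.
#' @param baseline_daily_prob daily prescription probability in (0, 1).
#' @param post_event_multiplier nonnegative multiplier `r`;
#'   `r * baseline_daily_prob` must not exceed 1.
#' @param trigger what switches the rate: `"lab_threshold"` (first day the
#'   quantitative analyte exceeds `trigger_level`), `"test_order"` (the day
#'   the nominal test is ordered), or `"test_result_positive"` (the day a
#'   positive result returns).
#' @param trigger_level threshold for the `lab_threshold` trigger.
#' @param onset_offset days after the trigger at which the multiplier takes
#'   effect (default 0 = the event day itself).
#' @return A list of class `pace_drug_intent`.
#' @export
drug_intent <- function(drug_code, baseline_daily_prob,
                        post_event_multiplier = 1,
                        trigger = c("lab_threshold", "test_order",
                                    "test_result_positive"),
                        trigger_level = 5.5, onset_offset = 0) {
  trigger <- match.arg(trigger)
  if (!(baseline_daily_prob > 0 && baseline_daily_prob < 1)) {
    abort("baseline_daily_prob must lie in (0, 1)")
  }
  if (post_event_multiplier < 0) abort("post_event_multiplier must be nonnegative")
  if (post_event_multiplier * baseline_daily_prob > 1) {
    abort("infeasible intent: post_event_multiplier * baseline_daily_prob exceeds 1")
  }
  structure(list(drug_code = drug_code,
                 baseline_daily_prob = baseline_daily_prob,
                 post_event_multiplier = post_event_multiplier,
                 trigger = trigger, trigger_level = trigger_level,
                 onset_offset = as.integer(onset_offset)),
            class = "pace_drug_intent")
}

#' Parameters of a synthetic inpatient cohort
#'
#' Generative model: one admission per patient with a uniform stay length;
#' one quantitative lab value per hospital day drawn around a normal
#' baseline, with independent per-day excursions above the event threshold
#' whose magnitudes come from `event_magnitude`; optionally one nominal
#' test (order, delayed result, positive with fixed probability) per
#' admission; and per drug, independent daily prescription draws whose rate
#' switches at the drug's trigger. Each admission is written by a single
#' prescriber drawn uniformly; per-prescriber intent overrides allow
#' simulating prescribers with differing knowledge.
#'
#' @param n_patients number of patients (one admission each).
#' @param seed mandatory integer seed; the same seed reproduces the cohort
#'   exactly, and patients are generated on per-patient substreams so that
#'   growing `n_patients` leaves existing patients unchanged.
#' @param drugs list of [drug_intent()] objects.
#' @param stay_range inclusive range of stay lengths in days.
#' @param lab_analyte quantitative analyte name.
#' @param lab_baseline_mean,lab_baseline_sd daily baseline value
#'   distribution (defaults 4.2 and 0.3 mmol/L, a normokalemic inpatient).
#' @param event_day_prob per-day probability of an excursion day.
#' @param event_magnitude excursion value distribution: a `c(min, max)`
#'   uniform range (default 5.6-7.0 mmol/L) or a `function(n)` returning
#'   `n` draws.
#' @param n_prescribers number of prescribers.
#' @param prescriber_intents optional named list (prescriber id ->
#'   list of [drug_intent()]) overriding `drugs` for that prescriber's
#'   admissions.
#' @param nominal_analyte optional nominal test name; enables order/result
#'   simulation.
#' @param test_order_prob per-admission probability the nominal test is
#'   ordered.
#' @param result_delay_days days between order and result (a toxin assay
#'   takes about 3 days to return).
#' @param positive_prob probability a result is positive.
#' @param renal_dx_prob per-patient probability of carrying an excludable
#'   renal diagnosis code (N18.5).
#' @param admit_start first possible admission date.
#' @param admit_span_days admissions are staggered over this many days.
#' @return A list of class `pace_cohort_params`.
#' @export
cohort_params <- function(n_patients, seed, drugs = list(),
                          stay_range = c(8, 20),
                          lab_analyte = "potassium",
                          lab_baseline_mean = 4.2, lab_baseline_sd = 0.3,
                          event_day_prob = 0.05,
                          event_magnitude = c(5.6, 7.0),
                          n_prescribers = 10,
                          prescriber_intents = NULL,
                          nominal_analyte = NULL,
                          test_order_prob = 0.15,
                          result_delay_days = 3,
                          positive_prob = 0.4,
                          renal_dx_prob = 0,
                          admit_start = as.Date("2020-01-01"),
                          admit_span_days = 180) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  if (n_patients < 1) abort("n_patients must be at least 1")
  stopifnot(length(stay_range) == 2, stay_range[1] >= 6,
            stay_range[2] >= stay_range[1],
            event_day_prob >= 0, event_day_prob <= 1,
            test_order_prob >= 0, test_order_prob <= 1,
            positive_prob >= 0, positive_prob <= 1,
            renal_dx_prob >= 0, renal_dx_prob <= 1,
            n_prescribers >= 1)
  for (d in drugs) stopifnot(inherits(d, "pace_drug_intent"))
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed), drugs = drugs,
                 stay_range = as.integer(stay_range),
                 lab_analyte = lab_analyte,
                 lab_baseline_mean = lab_baseline_mean,
                 lab_baseline_sd = lab_baseline_sd,
                 event_day_prob = event_day_prob,
                 event_magnitude = event_magnitude,
                 n_prescribers = as.integer(n_prescribers),
                 prescriber_intents = prescriber_intents,
                 nominal_analyte = nominal_analyte,
                 test_order_prob = test_order_prob,
                 result_delay_days = as.integer(result_delay_days),
                 positive_prob = positive_prob,
                 renal_dx_prob = renal_dx_prob,
                 admit_start = as.Date(admit_start),
                 admit_span_days = as.integer(admit_span_days)),
            class = "pace_cohort_params")
}

patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647)
}

draw_magnitude <- function(spec, n) {
  if (is.function(spec)) return(spec(n))
  runif(n, spec[1], spec[2])
}

#' Simulate a synthetic inpatient cohort
#'
#' Draws a cohort from the generative model described in
#' [cohort_params()]. The same parameters (including the seed) always
#' produce an identical cohort, and each patient is drawn on a
#' deterministic substream indexed by patient number, so enlarging the
#' cohort preserves already-generated patients.
#'
#' @param params a [cohort_params()].
#' @return A validated `pace_cohort`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "pace_cohort_params"))
  n <- params$n_patients
  stays <- params$stay_range[1]:params$stay_range[2]
  prescriber_ids <- sprintf("DR%03d", seq_len(params$n_prescribers))
  acc <- list(rx = vector("list", n), lab = vector("list", n),
              adm = vector("list", n), dx = vector("list", n))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  for (i in seq_len(n)) {
    set.seed(patient_seed(params$seed, i))
    pid <- sprintf("P%06d", i)
    aid <- sprintf("A%06d", i)
    L <- if (length(stays) == 1) stays else sample(stays, 1)
    admit <- params$admit_start + ((i - 1L) %% params$admit_span_days)
    days <- admit + 0:(L - 1)
    prescriber <- sample(prescriber_ids, 1)

    excursion <- runif(L) < params$event_day_prob
    values <- round(rnorm(L, params$lab_baseline_mean, params$lab_baseline_sd), 2)
    if (any(excursion)) {
      values[excursion] <- round(draw_magnitude(params$event_magnitude,
                                                sum(excursion)), 2)
    }
    lab <- list(patient_id = rep(pid, L), admission_id = rep(aid, L),
                analyte = rep(params$lab_analyte, L),
                value = format(values, trim = TRUE, nsmall = 2),
                order_date = days, result_date = days)

    order_day <- NA_integer_
    result_day <- NA_integer_
    positive <- FALSE
    if (!is.null(params$nominal_analyte)) {
      ordered <- runif(1) < params$test_order_prob
      latest_order <- L - 1 - params$result_delay_days
      if (ordered && latest_order >= 4) {
        order_day <- sample(4:latest_order, 1)
        result_day <- order_day + params$result_delay_days
        positive <- runif(1) < params$positive_prob
        lab$patient_id <- c(lab$patient_id, pid)
        lab$admission_id <- c(lab$admission_id, aid)
        lab$analyte <- c(lab$analyte, params$nominal_analyte)
        lab$value <- c(lab$value, if (positive) "positive" else "negative")
        lab$order_date <- c(lab$order_date, admit + order_day)
        lab$result_date <- c(lab$result_date, admit + result_day)
      }
    }

    intents <- params$drugs
    override <- params$prescriber_intents[[prescriber]]
    if (!is.null(override)) {
      for (ov in override) {
        hit <- which(vapply(intents, function(d) d$drug_code == ov$drug_code, TRUE))
        if (length(hit)) intents[[hit]] <- ov else intents <- c(intents, list(ov))
      }
    }
    rx_days <- list()
    rx_drugs <- list()
    for (d in intents) {
      t0 <- switch(d$trigger,
        lab_threshold = {
          hits <- which(values > d$trigger_level)
          if (length(hits)) hits[1] - 1L else NA_integer_
        },
        test_order = order_day,
        test_result_positive = if (positive) result_day else NA_integer_)
      change <- if (is.na(t0)) Inf else t0 + d$onset_offset
      p_day <- ifelse(0:(L - 1) >= change,
                      d$post_event_multiplier * d$baseline_daily_prob,
                      d$baseline_daily_prob)
      on <- runif(L) < p_day
      if (any(on)) {
        rx_days[[length(rx_days) + 1]] <- days[on]
        rx_drugs[[length(rx_drugs) + 1]] <- rep(d$drug_code, sum(on))
      }
    }
    n_rx <- sum(lengths(rx_drugs))
    acc$rx[[i]] <- list(patient_id = rep(pid, n_rx),
                        admission_id = rep(aid, n_rx),
                        drug_code = unlist(rx_drugs, use.names = FALSE) %||% character(),
                        prescriber_id = rep(prescriber, n_rx),
                        admin_date = do.call(c, rx_days) %||% as.Date(character()))
    acc$lab[[i]] <- lab
    acc$adm[[i]] <- list(patient_id = pid, admission_id = aid,
                         admit_date = admit, discharge_date = admit + L - 1)
    if (params$renal_dx_prob > 0 && runif(1) < params$renal_dx_prob) {
      acc$dx[[i]] <- list(patient_id = pid, icd10_code = "N18.5")
    }
  }
  gather <- function(lst, fields) {
    lst <- lst[!vapply(lst, is.null, TRUE)]
    if (!length(lst)) return(NULL)
    as_tibble(setNames(lapply(fields, function(f) {
      do.call(c, lapply(lst, `[[`, f))
    }), fields))
  }
  rx <- gather(acc$rx, c("patient_id", "admission_id", "drug_code",
                         "prescriber_id", "admin_date"))
  lab <- gather(acc$lab, c("patient_id", "admission_id", "analyte", "value",
                           "order_date", "result_date"))
  adm <- gather(acc$adm, c("patient_id", "admission_id", "admit_date",
                           "discharge_date"))
  dx <- gather(acc$dx, c("patient_id", "icd10_code"))
  if (is.null(rx) || !nrow(rx)) rx <- empty_prescriptions()
  if (is.null(dx) || !nrow(dx)) dx <- empty_diagnoses()
  suppressMessages(cohort_data(prescriptions = rx, labs = lab,
                               admissions = adm, diagnoses = dx))
}

#' Analytic PCI limit under the generative model
#'
#' The pooled PCI over clean windows (before-days at the baseline rate)
#' converges to the ratio of the expected two-day prescription sums. For an
#' intent switching on the event day (`onset_offset = 0`) this is exactly
#' the post-event multiplier `r`; for a later onset it is the piecewise
#' expectation over the two after-days, e.g. `(1 + r)/2` for onset at D+1.
#'
#' @param intent a [drug_intent()].
#' @return The analytic pooled-PCI limit.
#' @export
expected_pci <- function(intent) {
  stopifnot(inherits(intent, "pace_drug_intent"))
  r <- intent$post_event_multiplier
  p <- intent$baseline_daily_prob
  rate <- function(k) if (k >= intent$onset_offset) r * p else p
  (rate(0L) + rate(1L)) / (rate(-3L) + rate(-2L))
}
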