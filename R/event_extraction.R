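#' Event-detection and eligibility configuration
#'
#' Collects the settings that define a clinical event and the exclusion
#' rules applied to its observation windows. Defaults reproduce the
#' hyperkalemia analysis: serum potassium above 5.5 mmol/L, baseline
#' exclusion at the same level, and renal-failure ICD-10 prefixes for the
#' dialysis/chronic-renal-failure exclusion.
#'
#' @param analyte lab analyte key the event is defined on.
#' @param kind event kind: `"lab_threshold"` (quantitative value strictly
#'   above `threshold`), `"test_order"`, `"test_result_positive"`,
#'   `"test_result_negative"`, or `"before_order"` (a reference point
#'   `before_order_days` before the order date).
#' @param threshold numeric event threshold for `lab_threshold` events.
#' @param upper_ref upper normal reference bound for the baseline exclusion;
#'   `NULL` defaults to `threshold`. The reference range is not standardised
#'   across laboratories, so it is configurable.
#' @param exclusion_icd10_prefixes ICD-10 code prefixes whose carriers are
#'   excluded (default: renal-failure codes I12.0, I13.0, I13.1, N17-N19).
#'   An empty character vector disables the exclusion.
#' @param min_event_gap_days de-duplicate events closer than this many days
#'   within one admission, keeping the earliest of each run; 0 keeps every
#'   event (each event is counted separately).
#' @param before_order_days offset used by the `before_order` event kind.
#' @return A list of class `pace_event_config`.
#' @export
event_config <- function(analyte = "potassium",
                         kind = c("lab_threshold", "test_order",
                                  "test_result_positive",
                                  "test_result_negative", "before_order"),
                         threshold = 5.5,
                         upper_ref = NULL,
                         exclusion_icd10_prefixes = c("I12.0", "I13.0",
                                                      "I13.1", "N17", "N18",
                                                      "N19"),
                         min_event_gap_days = 0,
                         before_order_days = 5) {
  kind <- match.arg(kind)
  stopifnot(is.finite(threshold), min_event_gap_days >= 0,
            before_order_days >= 0)
  structure(list(analyte = analyte, kind = kind, threshold = threshold,
                 upper_ref = upper_ref %||% threshold,
                 exclusion_icd10_prefixes = exclusion_icd10_prefixes,
                 min_event_gap_days = min_event_gap_days,
                 before_order_days = before_order_days),
            class = "pace_event_config")
}

empty_events <- function() {
  tibble(patient_id = character(), admission_id = character(),
         event_kind = character(), index_date = as.Date(character()),
         severity_value = numeric(), analyte = character())
}

#' Detect threshold-crossing laboratory events
#'
#' Each lab record of the analyte whose value is strictly greater than the
#' threshold yields one event anchored at its result date (D0). Multiple
#' qualifying records in one admission each yield their own event.
#'
#' @param labs lab tibble from a `pace_cohort` (must carry `value_num`).
#' @param analyte quantitative analyte key.
#' @param threshold finite numeric; strict `>` comparison.
#' @return Event tibble: `patient_id`, `admission_id`, `event_kind`
#'   (`"lab_threshold"`), `index_date`, `severity_value`, `analyte`.
#' @export
detect_lab_threshold_events <- function(labs, analyte, threshold) {
  stopifnot(is.finite(threshold))
  sub <- labs[labs$analyte == analyte, , drop = FALSE]
  if (nrow(sub) && all(is.na(sub$value_num))) {
    abort(sprintf("analyte '%s' has no numeric values; lab_threshold events need a quantitative analyte",
                  analyte))
  }
  hit <- sub[!is.na(sub$value_num) & sub$value_num > threshold, , drop = FALSE]
  if (!nrow(hit)) return(empty_events())
  tibble(patient_id = hit$patient_id, admission_id = hit$admission_id,
         event_kind = "lab_threshold", index_date = hit$result_date,
         severity_value = hit$value_num, analyte = analyte) |>
    arrange(.data$admission_id, .data$index_date)
}

#' Detect test-order and stratified test-result events
#'
#' For a nominal test analyte, each record yields a `test_order` event at
#' its order date and, when a result token is present, a
#' `test_result_positive` or `test_result_negative` event at its result
#' date. Records with no result token yield the order event only, with a
#' warning.
#'
#' @param labs lab tibble from a `pace_cohort`.
#' @param analyte nominal analyte key (values `"positive"`/`"negative"`).
#' @return Event tibble as in [detect_lab_threshold_events()];
#'   `severity_value` is `NA` for nominal events.
#' @export
detect_order_and_result_events <- function(labs, analyte) {
  sub <- labs[labs$analyte == analyte, , drop = FALSE]
  if (!nrow(sub)) return(empty_events())
  if (any(is.na(sub$order_date))) {
    abort(sprintf("analyte '%s': order_date is required for order/result events", analyte))
  }
  orders <- tibble(patient_id = sub$patient_id,
                   admission_id = sub$admission_id,
                   event_kind = "test_order", index_date = sub$order_date,
                   severity_value = NA_real_, analyte = analyte)
  has_result <- !is.na(sub$result_date) & sub$value %in% c("positive", "negative")
  n_missing <- sum(!has_result)
  if (n_missing) {
    warn(sprintf("%d %s record(s) without a result token: order event only",
                 n_missing, analyte))
  }
  res <- sub[has_result, , drop = FALSE]
  results <- tibble(patient_id = res$patient_id,
                    admission_id = res$admission_id,
                    event_kind = paste0("test_result_", res$value),
                    index_date = res$result_date,
                    severity_value = NA_real_, analyte = analyte)
  bind_rows(orders, results) |>
    arrange(.data$admission_id, .data$index_date, .data$event_kind)
}

#' Detect events according to an event configuration
#'
#' Dispatches on `config$kind` and applies the optional minimum-event-gap
#' de-duplication. The `before_order` kind re-anchors each order event
#' `config$before_order_days` days earlier, giving the pre-suspicion
#' reference condition.
#'
#' @param labs lab tibble from a `pace_cohort`.
#' @param config a [event_config()].
#' @return Event tibble.
#' @export
detect_events <- function(labs, config) {
  stopifnot(inherits(config, "pace_event_config"))
  events <- switch(config$kind,
    lab_threshold = detect_lab_threshold_events(labs, config$analyte,
                                                config$threshold),
    test_order = ,
    test_result_positive = ,
    test_result_negative = {
      ev <- detect_order_and_result_events(labs, config$analyte)
      ev[ev$event_kind == config$kind, , drop = FALSE]
    },
    before_order = {
      ev <- detect_order_and_result_events(labs, config$analyte)
      ev <- ev[ev$event_kind == "test_order", , drop = FALSE]
      ev$event_kind <- "before_order"
      ev$index_date <- ev$index_date - config$before_order_days
      ev
    })
  apply_event_gap(events, config$min_event_gap_days)
}

# greedy per-admission de-duplication: keep an event only if at least
# `gap` days after the previously kept one
apply_event_gap <- function(events, gap) {
  if (gap <= 0 || !nrow(events)) return(events)
  events <- arrange(events, .data$admission_id, .data$index_date)
  keep <- logical(nrow(events))
  last_adm <- ""
  last_day <- -Inf
  for (i in seq_len(nrow(events))) {
    d <- as.numeric(events$index_date[i])
    if (events$admission_id[i] != last_adm || d - last_day >= gap) {
      keep[i] <- TRUE
      last_adm <- events$admission_id[i]
      last_day <- d
    }
  }
  events[keep, , drop = FALSE]
}

#' Anchor observation windows and apply the admission-timing rule
#'
#' Turns events into observation windows spanning day offsets -4..+1 around
#' D0. A window is eligible only when the whole span lies inside the
#' hospitalization: the event must occur at least 4 days after admission and
#' at least 1 day before discharge (both boundaries inclusive). Ineligible
#' windows are retained with reason tags `"too_early"` / `"too_late"`.
#'
#' @param events event tibble.
#' @param admissions admissions tibble.
#' @return Window tibble: event columns plus `admit_date`, `discharge_date`,
#'   `eligible` (logical), `exclusion_reasons` (list of character), `flags`
#'   (list of character, non-excluding annotations).
#' @export
apply_admission_eligibility <- function(events, admissions) {
  idx <- match(events$admission_id, admissions$admission_id)
  if (anyNA(idx)) {
    abort(paste0("events reference unknown admission(s): ",
                 paste(unique(events$admission_id[is.na(idx)]), collapse = ", ")))
  }
  w <- events
  w$admit_date <- admissions$admit_date[idx]
  w$discharge_date <- admissions$discharge_date[idx]
  too_early <- as.numeric(w$index_date - w$admit_date) < 4
  too_late <- as.numeric(w$discharge_date - w$index_date) < 1
  w$exclusion_reasons <- purrr::map2(too_early, too_late, function(e, l) {
    c(if (e) "too_early", if (l) "too_late")
  })
  w$flags <- rep(list(character()), nrow(w))
  w$eligible <- !(too_early | too_late)
  w
}

add_exclusion_reason <- function(windows, hit, reason) {
  windows$exclusion_reasons[hit] <- lapply(windows$exclusion_reasons[hit],
                                           function(r) union(r, reason))
  windows$eligible <- lengths(windows$exclusion_reasons) == 0
  windows
}

#' Exclude windows with an abnormal baseline laboratory value
#'
#' The baseline is the chronologically first value of the analyte in the
#' window's admission measured before the window opens (before D-4). A
#' window whose baseline exceeds `upper_ref` is marked ineligible with
#' reason `"abnormal_baseline"`; a window with no measurement before the
#' window is kept but flagged `"no_baseline"` — exclusion requires observed
#' evidence of abnormality.
#'
#' @param windows window tibble.
#' @param labs lab tibble from the same cohort.
#' @param analyte quantitative analyte key for the baseline.
#' @param upper_ref finite numeric upper normal reference bound.
#' @return The window tibble with updated eligibility.
#' @export
apply_baseline_exclusion <- function(windows, labs, analyte, upper_ref) {
  stopifnot(is.finite(upper_ref))
  if (!nrow(windows)) return(windows)
  sub <- labs[labs$analyte == analyte & !is.na(labs$value_num), , drop = FALSE]
  n <- nrow(windows)
  baseline <- rep(NA_real_, n)
  if (nrow(sub)) {
    split_labs <- split(seq_len(nrow(sub)), sub$admission_id)
    for (i in seq_len(n)) {
      rows <- split_labs[[windows$admission_id[i]]]
      if (is.null(rows)) next
      before <- rows[sub$result_date[rows] < windows$index_date[i] - 4]
      if (!length(before)) next
      d0 <- min(sub$result_date[before])
      # tie on the earliest day: take the highest value (conservative)
      baseline[i] <- max(sub$value_num[before][sub$result_date[before] == d0])
    }
  }
  no_base <- is.na(baseline)
  windows$flags[no_base] <- lapply(windows$flags[no_base],
                                   function(f) union(f, "no_baseline"))
  add_exclusion_reason(windows, !no_base & baseline > upper_ref,
                       "abnormal_baseline")
}

#' Exclude windows of patients carrying configured diagnoses
#'
#' Marks windows ineligible (reason `"excluded_diagnosis"`) when the
#' patient has any diagnosis code starting with one of the ICD-10 prefixes.
#' Used to remove patients whose underlying condition (e.g. chronic renal
#' failure on dialysis) confounds the event. An empty prefix list disables
#' the filter.
#'
#' @param windows window tibble.
#' @param diagnoses diagnoses tibble.
#' @param icd10_prefixes character vector of code prefixes.
#' @return The window tibble with updated eligibility.
#' @export
apply_diagnosis_exclusion <- function(windows, diagnoses, icd10_prefixes) {
  if (!length(icd10_prefixes) || !nrow(windows)) return(windows)
  pat <- paste0("^(", paste(gsub("([.\\\\])", "\\\\\\1", icd10_prefixes),
                            collapse = "|"), ")")
  carriers <- unique(diagnoses$patient_id[grepl(pat, diagnoses$icd10_code)])
  add_exclusion_reason(windows, windows$patient_id %in% carriers,
                       "excluded_diagnosis")
}

#' Build fully filtered observation windows for a cohort
#'
#' Composes event detection with the three eligibility filters (admission
#' timing, abnormal baseline for quantitative threshold events, diagnosis
#' exclusion). The filters commute: each can only flip a window from
#' eligible to ineligible.
#'
#' @param cohort a `pace_cohort`.
#' @param config a [event_config()].
#' @return Window tibble (all windows, eligible and not).
#' @export
build_windows <- function(cohort, config) {
  events <- detect_events(cohort$labs, config)
  if (!nrow(events)) {
    w <- events
    w$admit_date <- as.Date(character())
    w$discharge_date <- as.Date(character())
    w$exclusion_reasons <- list()
    w$flags <- list()
    w$eligible <- logical()
    return(w)
  }
  w <- apply_admission_eligibility(events, cohort$admissions)
  if (config$kind == "lab_threshold") {
    w <- apply_baseline_exclusion(w, cohort$labs, config$analyte,
                                  config$upper_ref)
  }
  apply_diagnosis_exclusion(w, cohort$diagnoses,
                            config$exclusion_icd10_prefixes)
}

#' Keep only eligible windows
#' @param windows window tibble.
#' @return The eligible subset.
#' @export
eligible_windows <- function(windows) {
  windows[windows$eligible, , drop = FALSE]
}
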