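#' Pattern cut-off configuration
#'
#' The prescription change index is cut at a 1.5-fold change in either
#' direction: PCI <= `lower` (1.000/1.500 = 0.667) is a discontinuation
#' pattern, PCI > `upper` (1.500) an intervention pattern, and anything in
#' between a maintenance pattern.
#'
#' @param lower lower cut-off (default 0.667).
#' @param upper upper cut-off (default 1.500).
#' @return A list of class `pace_cutoffs`.
#' @export
cutoff_config <- function(lower = 0.667, upper = 1.500) {
  stopifnot(is.finite(lower), is.finite(upper), lower > 0, lower < upper)
  structure(list(lower = lower, upper = upper), class = "pace_cutoffs")
}

#' Construct per-day window counts
#'
#' Low-level constructor for the pooled per-offset prescription counts of
#' one drug over a set of observation windows.
#'
#' @param counts numeric vector of 6 nonnegative counts for day offsets
#'   -4..+1 (optionally named `"-4"`..`"1"`).
#' @param drug_code drug identifier.
#' @param n_windows number of pooled windows.
#' @return An object of class `pace_window_counts`.
#' @export
window_counts <- function(counts, drug_code = "drug", n_windows = NA_integer_) {
  stopifnot(length(counts) == length(WINDOW_OFFSETS), all(counts >= 0))
  counts <- setNames(as.numeric(counts), as.character(WINDOW_OFFSETS))
  structure(list(drug_code = drug_code, counts = counts,
                 n_windows = n_windows),
            class = "pace_window_counts")
}

#' Pool per-day prescription counts over observation windows
#'
#' Counts prescription records of one drug on each window day offset
#' (-4..+1 relative to D0), summed over all supplied windows. A record
#' falling into two overlapping windows is counted in each; multiple
#' records of the drug on the same day each count.
#'
#' @param prescriptions prescription tibble from a `pace_cohort`.
#' @param windows eligible window tibble (an error is raised if any window
#'   is ineligible).
#' @param drug_code single drug code.
#' @return A [window_counts()] object.
#' @export
tabulate_window_counts <- function(prescriptions, windows, drug_code) {
  stopifnot(nzchar(drug_code))
  if (nrow(windows) && !all(windows$eligible)) {
    abort("tabulate_window_counts expects eligible windows only; filter with eligible_windows()")
  }
  tab <- tabulate_counts_by_drug(prescriptions, windows, drug_code)
  window_counts(tab[[drug_code]] %||% rep(0, 6), drug_code = drug_code,
                n_windows = nrow(windows))
}

# shared counting core: returns a named list of per-offset count vectors,
# one per requested drug (absent drugs -> zero vector)
tabulate_counts_by_drug <- function(prescriptions, windows, drug_list) {
  zero <- setNames(rep(0, length(WINDOW_OFFSETS)), as.character(WINDOW_OFFSETS))
  out <- setNames(rep(list(zero), length(drug_list)), drug_list)
  if (!nrow(windows) || !nrow(prescriptions)) return(out)
  rx <- prescriptions[prescriptions$drug_code %in% drug_list, , drop = FALSE]
  if (!nrow(rx)) return(out)
  hit <- inner_join(
    rx[, c("admission_id", "drug_code", "admin_date")],
    windows[, c("admission_id", "index_date")],
    by = "admission_id", relationship = "many-to-many")
  hit$offset <- as.integer(hit$admin_date - hit$index_date)
  hit <- hit[hit$offset >= -4L & hit$offset <= 1L, , drop = FALSE]
  if (!nrow(hit)) return(out)
  agg <- hit |>
    dplyr::count(.data$drug_code, .data$offset)
  for (i in seq_len(nrow(agg))) {
    out[[agg$drug_code[i]]][as.character(agg$offset[i])] <- agg$n[i]
  }
  out
}

#' Cumulative prescription curve
#'
#' Running total of the per-day window counts from D-4 through D+1; the
#' non-decreasing curve whose segment slopes define the PCI.
#'
#' @param counts a [window_counts()] object.
#' @return An object of class `pace_curve` with fields `drug_code`,
#'   `cumulative` (named by offset), `n_windows`, `n_prescriptions`.
#' @export
cumulate <- function(counts) {
  stopifnot(inherits(counts, "pace_window_counts"))
  cum <- cumsum(counts$counts)
  structure(list(drug_code = counts$drug_code, cumulative = cum,
                 n_windows = counts$n_windows,
                 n_prescriptions = unname(cum[length(cum)]),
                 counts = counts$counts),
            class = "pace_curve")
}

#' Average slope of a cumulative curve between two window days
#'
#' `(cumulative(t2) - cumulative(t1)) / (t2 - t1)`, in prescriptions per
#' day. With the window's own cumulative counts, the slope over \[D-4, D-2\]
#' is the before-event slope (Slope A) and the slope over \[D-1, D+1\] the
#' after-event slope (Slope B).
#'
#' @param curve a `pace_curve`.
#' @param t1,t2 day offsets in -4..+1 with `t1 < t2`.
#' @return Numeric slope.
#' @export
average_slope <- function(curve, t1, t2) {
  stopifnot(inherits(curve, "pace_curve"))
  if (!(t1 %in% WINDOW_OFFSETS) || !(t2 %in% WINDOW_OFFSETS)) {
    abort("t1 and t2 must be day offsets in -4..+1")
  }
  if (t1 >= t2) abort("t1 must be strictly less than t2")
  unname((curve$cumulative[as.character(t2)] -
            curve$cumulative[as.character(t1)]) / (t2 - t1))
}

#' Compute the prescription change index for one curve
#'
#' PCI = Slope B / Slope A, where Slope A is the average slope of the
#' cumulative count over \[D-4, D-2\] and Slope B over \[D-1, D+1\]. Because
#' both segments are two days wide, the ratio reduces exactly to
#' `(n(D0) + n(D+1)) / (n(D-3) + n(D-2))`: the two-day prescription sum
#' around the event against the two-day sum before it. (The segment
#' endpoints D-4 and D-1 anchor the slopes; their own counts cancel and
#' never affect the index.)
#'
#' Degenerate denominators are tagged rather than raised: a zero before-sum
#' with a positive after-sum gives `pci = Inf` (a pure intervention, the
#' ratio's limit), and zero on both sides gives an undefined PCI (`NA`) and
#' an indeterminate pattern.
#'
#' @param curve a `pace_curve`.
#' @param cutoffs a [cutoff_config()].
#' @return One-row tibble: `drug_code`, `n_windows`, `n_prescriptions`,
#'   `slope_before`, `slope_after`, `pci`, `pattern`.
#' @export
compute_pci <- function(curve, cutoffs = cutoff_config()) {
  slope_a <- average_slope(curve, -4, -2)
  slope_b <- average_slope(curve, -1, 1)
  pci <- if (slope_a > 0) slope_b / slope_a
         else if (slope_b > 0) Inf
         else NA_real_
  tibble(drug_code = curve$drug_code,
         n_windows = curve$n_windows,
         n_prescriptions = curve$n_prescriptions,
         slope_before = slope_a, slope_after = slope_b,
         pci = pci,
         pattern = classify_pattern(pci, cutoffs))
}

#' Classify a PCI into a prescription pattern
#'
#' `pci <= lower` is a discontinuation pattern, `pci > upper` an
#' intervention pattern, values in between a maintenance pattern; an
#' undefined PCI (`NA`) is indeterminate. Vectorised.
#'
#' @param pci nonnegative numeric vector; `Inf` and `NA` allowed.
#' @param cutoffs a [cutoff_config()].
#' @return Factor with levels intervention, maintenance, discontinuation,
#'   indeterminate.
#' @export
classify_pattern <- function(pci, cutoffs = cutoff_config()) {
  if (any(!is.na(pci) & pci < 0)) abort("pci must be nonnegative")
  out <- dplyr::case_when(
    is.na(pci) ~ "indeterminate",
    pci <= cutoffs$lower ~ "discontinuation",
    pci > cutoffs$upper ~ "intervention",
    TRUE ~ "maintenance")
  pattern_factor(out)
}

#' Run the full pattern pipeline on a cohort
#'
#' Detects events, anchors and filters observation windows, pools per-day
#' prescription counts per drug, and returns the PCI and pattern for each
#' monitored drug. Optionally adds the exact binomial-test alternative on
#' the same two-day sums.
#'
#' @param cohort a `pace_cohort`.
#' @param config a [event_config()].
#' @param drug_list character vector of monitored drug codes.
#' @param cutoffs a [cutoff_config()].
#' @param compare_binomial also compute [binomial_pattern()] per drug.
#' @param alpha significance level for the binomial alternative.
#' @param windows optional precomputed window tibble (from
#'   [build_windows()] on the same cohort/config), to avoid repeated event
#'   extraction.
#' @return Tibble with one row per drug: `drug_code`, `n_windows`,
#'   `n_prescriptions`, `slope_before`, `slope_after`, `pci`, `pattern`,
#'   plus `n_before`, `n_after`, `binom_p`, `binom_pattern` when
#'   `compare_binomial` is set. The window tibble is attached as attribute
#'   `"windows"`.
#' @export
run_pace <- function(cohort, config = event_config(), drug_list,
                     cutoffs = cutoff_config(), compare_binomial = FALSE,
                     alpha = 0.05, windows = NULL) {
  if (!length(drug_list)) abort("drug_list must be non-empty")
  if (is.null(windows)) windows <- build_windows(cohort, config)
  elig <- eligible_windows(windows)
  if (!nrow(elig)) {
    warn("no eligible observation windows; all patterns are indeterminate")
  }
  tabs <- tabulate_counts_by_drug(cohort$prescriptions, elig, drug_list)
  res <- bind_rows(lapply(drug_list, function(d) {
    compute_pci(cumulate(window_counts(tabs[[d]], drug_code = d,
                                       n_windows = nrow(elig))),
                cutoffs)
  }))
  if (compare_binomial) {
    nb <- vapply(drug_list, function(d) sum(tabs[[d]][c("-3", "-2")]), 0)
    na_ <- vapply(drug_list, function(d) sum(tabs[[d]][c("0", "1")]), 0)
    bin <- binomial_pattern(nb, na_, alpha = alpha)
    res$n_before <- bin$n_before
    res$n_after <- bin$n_after
    res$binom_p <- bin$p_value
    res$binom_pattern <- bin$pattern
  }
  attr(res, "windows") <- windows
  res
}

#' @export
print.pace_window_counts <- function(x, ...) {
  cat(sprintf("<window counts> %s over %s window(s)\n", x$drug_code,
              x$n_windows))
  print(x$counts)
  invisible(x)
}

#' @export
print.pace_curve <- function(x, ...) {
  cat(sprintf("<cumulative curve> %s over %s window(s), %s prescription(s)\n",
              x$drug_code, x$n_windows, x$n_prescriptions))
  print(x$cumulative)
  invisible(x)
}
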