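#' PCI profile across event severity
#'
#' Re-runs the full pattern pipeline at each threshold of an increasing
#' severity grid (for serum potassium, the reference grid is 4.50 to 7.00
#' mmol/L in 0.25 steps) and collects the PCI of each monitored drug per
#' threshold. Every grid point is an independent full pipeline run, so a
#' sweep point is identical to a single run at the same threshold. The
#' baseline exclusion bound follows the threshold unless pinned with
#' `fixed_upper_ref`.
#'
#' @param cohort a `pace_cohort`.
#' @param analyte quantitative analyte to sweep on.
#' @param thresholds strictly increasing numeric grid.
#' @param drug_list monitored drug codes.
#' @param cutoffs a [cutoff_config()].
#' @param config base [event_config()]; its threshold/upper_ref are
#'   overridden per grid point.
#' @param fixed_upper_ref optional fixed baseline bound for the whole sweep.
#' @param min_windows points backed by fewer pooled windows than this are
#'   flagged `low_n` (default 5); the PCI is still reported.
#' @return Tibble of class `pace_severity_profile`: `drug_code`,
#'   `threshold`, `n_windows`, `n_prescriptions`, `pci`, `pattern`, `low_n`.
#' @export
severity_sweep <- function(cohort, analyte, thresholds, drug_list,
                           cutoffs = cutoff_config(),
                           config = event_config(analyte = analyte),
                           fixed_upper_ref = NULL, min_windows = 5) {
  if (length(thresholds) < 1 || any(diff(thresholds) <= 0)) {
    abort("thresholds must be strictly increasing")
  }
  rows <- lapply(thresholds, function(t) {
    cfg <- config
    cfg$analyte <- analyte
    cfg$kind <- "lab_threshold"
    cfg$threshold <- t
    cfg$upper_ref <- fixed_upper_ref %||% t
    res <- suppressWarnings(run_pace(cohort, cfg, drug_list, cutoffs))
    tibble(drug_code = res$drug_code, threshold = t,
           n_windows = res$n_windows, n_prescriptions = res$n_prescriptions,
           pci = res$pci, pattern = res$pattern,
           low_n = res$n_windows < min_windows)
  })
  out <- bind_rows(rows) |> arrange(.data$drug_code, .data$threshold)
  class(out) <- c("pace_severity_profile", class(out))
  out
}

CONDITION_KINDS <- c(before_order = "before_order", order = "test_order",
                     result_negative = "test_result_negative",
                     result_positive = "test_result_positive")

#' PCI profile across nominal clinical conditions
#'
#' For a test with a nominal outcome, runs the pipeline once per clinical
#' condition — before the test was ordered (a reference point a configured
#' number of days before the order date), at ordering, and at a negative or
#' positive result — and collects the PCI of each drug per condition.
#'
#' @param cohort a `pace_cohort`.
#' @param analyte nominal analyte (e.g. a toxin test).
#' @param conditions ordered subset of `"before_order"`, `"order"`,
#'   `"result_negative"`, `"result_positive"`.
#' @param drug_list monitored drug codes.
#' @param cutoffs a [cutoff_config()].
#' @param config base [event_config()] (supplies `before_order_days`,
#'   exclusions, gap).
#' @param min_windows flag threshold as in [severity_sweep()].
#' @return Tibble of class `pace_condition_profile`: `drug_code`,
#'   `condition` (factor ordered as supplied), `n_windows`,
#'   `n_prescriptions`, `pci`, `pattern`, `low_n`.
#' @export
condition_profile <- function(cohort, analyte,
                              conditions = names(CONDITION_KINDS),
                              drug_list, cutoffs = cutoff_config(),
                              config = event_config(analyte = analyte),
                              min_windows = 5) {
  if (!length(conditions)) abort("conditions must be non-empty")
  unknown <- setdiff(conditions, names(CONDITION_KINDS))
  if (length(unknown)) {
    abort(paste0("unknown condition label(s): ", paste(unknown, collapse = ", ")))
  }
  rows <- lapply(conditions, function(cond) {
    cfg <- config
    cfg$analyte <- analyte
    cfg$kind <- CONDITION_KINDS[[cond]]
    res <- suppressWarnings(run_pace(cohort, cfg, drug_list, cutoffs))
    tibble(drug_code = res$drug_code,
           condition = cond,
           n_windows = res$n_windows, n_prescriptions = res$n_prescriptions,
           pci = res$pci, pattern = res$pattern,
           low_n = res$n_windows < min_windows)
  })
  out <- bind_rows(rows)
  out$condition <- factor(out$condition, levels = conditions)
  out <- arrange(out, .data$drug_code, .data$condition)
  class(out) <- c("pace_condition_profile", class(out))
  out
}

#' Flatten profiles into a plot-ready long table
#'
#' Produces one long table usable by any plotting layer: one row per
#' (drug, x) point with the PCI, window count, and pattern. The x column is
#' the threshold for severity profiles and the condition label for
#' condition profiles. Undefined PCIs are emitted as missing values, never
#' as zeros.
#'
#' @param profiles a severity or condition profile tibble, or a list of
#'   them.
#' @return Tibble: `drug`, `x`, `pci`, `n_windows`, `pattern`.
#' @export
export_profile_plot_data <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  if (!length(profiles)) abort("profiles must be non-empty")
  bind_rows(lapply(profiles, function(p) {
    x <- if ("threshold" %in% names(p)) p$threshold else p$condition
    tibble(drug = p$drug_code, x = x, pci = p$pci,
           n_windows = p$n_windows, pattern = p$pattern)
  }))
}

#' Line plot of a PCI profile
#'
#' One line per drug with horizontal guides at the two pattern cut-offs.
#' The y axis is log-scaled so that a k-fold increase and a k-fold decrease
#' sit symmetrically about 1.
#'
#' @param profiles severity or condition profile tibble.
#' @param cutoffs a [cutoff_config()] for the guide lines.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, cutoffs = cutoff_config()) {
  dat <- export_profile_plot_data(profiles)
  dat <- dat[is.finite(dat$pci), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$pci,
                                    colour = .data$drug,
                                    group = .data$drug)) +
    ggplot2::geom_hline(yintercept = c(cutoffs$lower, cutoffs$upper),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "prescription change index",
                  colour = "drug") +
    ggplot2::theme_minimal()
}
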