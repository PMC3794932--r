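#' Per-prescriber prescription patterns
#'
#' Computes each prescriber's own pattern for each monitored drug by
#' running the pattern pipeline with the prescription table restricted to
#' that prescriber's orders within a lookback period (default one year
#' before the most recent prescription in the cohort). Observation windows
#' come from the whole cohort; windows in which the prescriber wrote no
#' orders contribute zero counts and therefore do not move the pooled PCI.
#' A (prescriber, drug) pair backed by fewer than `min_prescriptions`
#' prescriptions in the lookback is omitted as unreliable.
#'
#' @param cohort a `pace_cohort`.
#' @param config a [event_config()].
#' @param drug_list monitored drug codes.
#' @param cutoffs a [cutoff_config()].
#' @param min_prescriptions minimum lookback prescriptions of a drug for a
#'   pair to be reported (default 10).
#' @param lookback_days lookback period length in days (default 365).
#' @param reference_date end of the lookback period; defaults to the most
#'   recent `admin_date` in the cohort.
#' @return Tibble: `prescriber_id`, `drug_code`, `n_prescriptions`
#'   (prescriber's count of that drug in the lookback), `n_windows`, `pci`,
#'   `pattern`.
#' @export
pattern_by_prescriber <- function(cohort, config = event_config(), drug_list,
                                  cutoffs = cutoff_config(),
                                  min_prescriptions = 10,
                                  lookback_days = 365,
                                  reference_date = NULL) {
  rx <- cohort$prescriptions
  empty <- tibble(prescriber_id = character(), drug_code = character(),
                  n_prescriptions = numeric(), n_windows = integer(),
                  pci = numeric(), pattern = pattern_factor(character()))
  if (!nrow(rx)) return(empty)
  reference_date <- reference_date %||% max(rx$admin_date)
  rx <- rx[!is.na(rx$prescriber_id) &
             rx$admin_date > reference_date - lookback_days &
             rx$admin_date <= reference_date, , drop = FALSE]
  if (!nrow(rx)) return(empty)
  windows <- build_windows(cohort, config)
  out <- list()
  for (pid in sort(unique(rx$prescriber_id))) {
    own <- rx[rx$prescriber_id == pid, , drop = FALSE]
    tallies <- table(own$drug_code)
    drugs <- drug_list[drug_list %in% names(tallies) &
                         tallies[drug_list] >= min_prescriptions]
    if (!length(drugs)) next
    sub <- cohort
    sub$prescriptions <- own
    res <- suppressWarnings(
      run_pace(sub, config, drugs, cutoffs, windows = windows))
    out[[pid]] <- tibble(prescriber_id = pid, drug_code = res$drug_code,
                         n_prescriptions = as.numeric(tallies[res$drug_code]),
                         n_windows = res$n_windows, pci = res$pci,
                         pattern = res$pattern)
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Cohen's kappa from a confusion table
#'
#' Chance-corrected agreement for a square cross-tabulation:
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed diagonal
#' proportion and `pe` the agreement expected from the marginals. When the
#' expected agreement is 1 the statistic is undefined and `NA` is returned.
#'
#' @param tab square numeric matrix or table (raters in rows/columns, same
#'   category order).
#' @return An object of class `pace_kappa`: list with `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n_pairs`, `confusion`.
#' @export
kappa_from_table <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) abort("confusion table must be square")
  n <- sum(tab)
  if (n < 1) abort("confusion table must contain at least one pair")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  structure(list(kappa = kappa, observed_agreement = po,
                 expected_agreement = pe, n_pairs = n, confusion = tab),
            class = "pace_kappa")
}

#' Cohen's kappa between two pattern labelings
#'
#' Measures chance-corrected agreement between two sets of
#' (prescriber, drug)-keyed pattern labels — typically the patterns
#' calculated from prescriptions and the patterns a prescriber stated on a
#' knowledge questionnaire. Only keys present in both sets are compared;
#' pairs where either side is indeterminate are dropped (a questionnaire
#' admits only the three substantive answers).
#'
#' @param pairs_a,pairs_b tibbles with columns `prescriber_id`,
#'   `drug_code`, and a label column named `pattern` or `stated_pattern`.
#' @return A `pace_kappa` object; `n_dropped` records indeterminate or
#'   missing-label pairs removed before tabulation.
#' @export
cohens_kappa <- function(pairs_a, pairs_b) {
  a <- normalize_pairs(pairs_a, ".a")
  b <- normalize_pairs(pairs_b, ".b")
  m <- inner_join(a, b, by = c("prescriber_id", "drug_code"))
  if (!nrow(m)) abort("no shared (prescriber_id, drug_code) keys between the two labelings")
  ok <- !is.na(m$label.a) & !is.na(m$label.b) &
    m$label.a != "indeterminate" & m$label.b != "indeterminate"
  dropped <- sum(!ok)
  m <- m[ok, , drop = FALSE]
  if (!nrow(m)) abort("no comparable pairs after dropping indeterminate labels")
  obs <- union(unique(m$label.a), unique(m$label.b))
  canon <- PATTERN_LEVELS[PATTERN_LEVELS != "indeterminate"]
  levels <- if (all(obs %in% canon)) canon else sort(obs)
  tab <- table(factor(m$label.a, levels = levels),
               factor(m$label.b, levels = levels))
  out <- kappa_from_table(tab)
  out$n_dropped <- dropped
  out
}

normalize_pairs <- function(pairs, suffix) {
  pairs <- as_tibble(pairs)
  require_columns(pairs, c("prescriber_id", "drug_code"), "label pairs")
  label_col <- intersect(c("pattern", "stated_pattern"), names(pairs))[1]
  if (is.na(label_col)) abort("label pairs need a 'pattern' or 'stated_pattern' column")
  out <- tibble(prescriber_id = as.character(pairs$prescriber_id),
                drug_code = as.character(pairs$drug_code),
                label = as.character(pairs[[label_col]]))
  if (anyDuplicated(out[c("prescriber_id", "drug_code")])) {
    abort("duplicate (prescriber_id, drug_code) keys in one labeling")
  }
  names(out)[3] <- paste0("label", suffix)
  out
}

#' @export
print.pace_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (po = %.3f, pe = %.3f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n_pairs))
  print(x$confusion)
  invisible(x)
}
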