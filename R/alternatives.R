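#' Binomial-test pattern determination
#'
#' The alternative decision rule used for comparison: treat the two-day
#' prescription sums before (D-3 + D-2) and after (D0 + D+1) the event as
#' the two arms of an exact binomial experiment with success probability
#' 0.5 and classify a drug by the direction of a significant deviation. The
#' two-sided p-value follows the minimum-likelihood convention (the sum of
#' all outcome probabilities not exceeding the observed outcome's), which is
#' what [stats::binom.test()] computes.
#'
#' @param n_before nonnegative counts in the two days before the event;
#'   vectorised.
#' @param n_after nonnegative counts in the two days around the event.
#' @param alpha significance level in (0, 1).
#' @param drug_code optional drug codes carried through to the result.
#' @return Tibble: `n_before`, `n_after`, `p_value`, `pattern` (factor;
#'   intervention when significantly more prescriptions after,
#'   discontinuation when significantly fewer, maintenance when not
#'   significant, indeterminate when both counts are zero), `alpha`; plus
#'   `drug_code` when supplied.
#' @export
binomial_pattern <- function(n_before, n_after, alpha = 0.05,
                             drug_code = NULL) {
  if (any(n_before < 0) || any(n_after < 0)) abort("counts must be nonnegative")
  stopifnot(alpha > 0, alpha < 1, length(n_before) == length(n_after))
  p <- mapply(function(b, a) {
    if (b + a == 0) return(NA_real_)
    binom.test(a, a + b, p = 0.5)$p.value
  }, n_before, n_after)
  pattern <- dplyr::case_when(
    n_before + n_after == 0 ~ "indeterminate",
    p < alpha & n_after > n_before ~ "intervention",
    p < alpha & n_after < n_before ~ "discontinuation",
    TRUE ~ "maintenance")
  out <- tibble(n_before = as.numeric(n_before),
                n_after = as.numeric(n_after),
                p_value = as.numeric(p),
                pattern = pattern_factor(pattern),
                alpha = alpha)
  if (!is.null(drug_code)) out <- bind_cols(tibble(drug_code = drug_code), out)
  out
}
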