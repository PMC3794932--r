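# independent brute-force oracles, deliberately naive

# quadratic scan over (prescription row, window) pairs
oracle_window_counts <- function(prescriptions, windows, drug_code) {
  counts <- setNames(rep(0, 6), as.character(-4:1))
  for (w in seq_len(nrow(windows))) {
    for (r in seq_len(nrow(prescriptions))) {
      if (prescriptions$drug_code[r] != drug_code) next
      if (prescriptions$admission_id[r] != windows$admission_id[w]) next
      off <- as.integer(prescriptions$admin_date[r] - windows$index_date[w])
      if (off >= -4 && off <= 1) {
        counts[as.character(off)] <- counts[as.character(off)] + 1
      }
    }
  }
  counts
}

# two-sided exact binomial p-value by full enumeration of the outcome
# distribution (minimum-likelihood convention)
oracle_binom_p <- function(n_after, n_total, p = 0.5) {
  probs <- dbinom(0:n_total, n_total, p)
  obs <- probs[n_after + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Cohen's kappa from two label vectors, from first principles
oracle_kappa <- function(a, b) {
  lev <- sort(union(unique(a), unique(b)))
  n <- length(a)
  po <- mean(a == b)
  pe <- 0
  for (l in lev) pe <- pe + mean(a == l) * mean(b == l)
  (po - pe) / (1 - pe)
}
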