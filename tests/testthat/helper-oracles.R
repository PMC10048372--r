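# Independent brute-force oracles used to validate the vectorized
# implementations. Deliberately naive: nested loops, no shared code with R/.

# Exhaustive sliding-window eligibility: enumerate every window explicitly.
oracle_window_scan <- function(calls, positions, params) {
  n <- length(calls)
  if (n == 0) return(logical(0))
  w <- min(params$window_snp, n)
  nwin <- n - w + 1
  hom_window <- logical(nwin)
  for (s in seq_len(nwin)) {
    win <- calls[s:(s + w - 1)]
    n_het <- sum(win == 1, na.rm = TRUE)
    n_miss <- sum(is.na(win))
    hom_window[s] <- (n_het <= params$window_het) &&
      (n_miss <= params$window_missing)
  }
  out <- logical(n)
  for (j in seq_len(n)) {
    hits <- 0L
    total <- 0L
    for (s in seq_len(nwin)) {
      if (s <= j && j <= s + w - 1) {
        total <- total + 1L
        if (hom_window[s]) hits <- hits + 1L
      }
    }
    own_het <- !is.na(calls[j]) && calls[j] == 1
    out[j] <- (hits / total >= params$hit_threshold) && !own_het
  }
  out
}

# O(n_sites x n_segments) interval stabbing for ROH incidence.
oracle_incidence <- function(segments, m) {
  n_samples <- length(m$samples)
  sapply(seq_len(nrow(m$sites)), function(j) {
    cc <- m$sites$chrom[j]
    pp <- m$sites$pos[j]
    covered <- unique(segments$sample[segments$chrom == cc &
                                        segments$start <= pp &
                                        segments$end >= pp])
    length(covered) / n_samples
  })
}

# Per-site loop Hamming distance between two dosage vectors.
oracle_hamming_pair <- function(g1, g2) {
  d <- 0
  for (k in seq_along(g1)) {
    if (!is.na(g1[k]) && !is.na(g2[k])) d <- d + abs(g1[k] - g2[k])
  }
  d
}

# Two-sided Fisher exact p by enumerating all tables with fixed margins:
# sum the hypergeometric probabilities not exceeding that of the observed
# table.
oracle_fisher_p <- function(k1, n1, k2, n2) {
  k_total <- k1 + k2
  p_obs <- stats::dhyper(k1, n1, n2, k_total)
  ks <- max(0, k_total - n2):min(n1, k_total)
  probs <- stats::dhyper(ks, n1, n2, k_total)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Textbook one-way ANOVA from sums of squares.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}
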