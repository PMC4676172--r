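# Small configurations keep simulation-backed tests fast.

small_config <- function(...) {
  sim_config(n_patients = 8, n_recurrent = 4, n_wes = 2,
             panel_size = 400, n_somatic_per_clone = 40,
             n_germline_background = 150, n_genes = 60, ...)
}

# Hardy-Weinberg genotype probabilities at allele frequency p
hw_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

# textbook Welch two-sample t-test p-value (independent of stats::t.test)
welch_p_hand <- function(a, b) {
  m1 <- mean(a); m2 <- mean(b); v1 <- var(a); v2 <- var(b)
  n1 <- length(a); n2 <- length(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(t), df)
}
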