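# Independent arithmetic oracles: written directly from the closed forms,
# deliberately not sharing code with the package implementation.

# odds-ratio form of the FDR point estimate
oracle_fdr_odds <- function(m, S, sbar) (sbar * (m - S)) / (S * (m - sbar))

oracle_pi0 <- function(m, S, sbar) (1 - S / m) / (1 - sbar / m)

# the two printed forms of the log-FDR variance
oracle_var_ratio <- function(m, S, ssum, B) {
  m / (ssum * (m - ssum / B)) + m / (S * (m - S))
}
oracle_var_woolf <- function(m, S, ssum, B) {
  1 / ssum + 1 / (m * B - ssum) + 1 / S + 1 / (m - S)
}

oracle_ci <- function(fdr, v, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  fdr * exp(c(-1, 1) * z * sqrt(v))
}

# element-by-element counting loop
oracle_count <- function(p, t, strict = TRUE) {
  n <- 0L
  for (x in p) if (if (strict) x < t else x <= t) n <- n + 1L
  n
}

# random valid count configurations for property tests
random_counts <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- sample(50:5000, 1)
    S <- sample(seq_len(m - 1), 1)
    B <- sample(2:20, 1)
    s_star <- sample(0:(m - 1), B, replace = TRUE)
    if (sum(s_star) == 0) s_star[1] <- 1L
    list(m = m, S = S, s_star = s_star)
  })
}
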