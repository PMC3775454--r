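test_that("positive_counts validates its invariants and derives summaries", {
  pc <- positive_counts(2000, 100, c(40, 45, 50, 55, 60))
  expect_equal(pc$B, 5)
  expect_equal(pc$s_star_sum, 250)
  expect_equal(pc$s_star_mean, 50)
  expect_equal(pc$p_hat, 0.025)

  expect_error(positive_counts(2000, 2001, c(1)), "exceeds m")
  expect_error(positive_counts(2000, 10, integer(0)), "at least one")
  expect_error(positive_counts(2000, 10, c(5, 2500)), "outside \\[0, m")
  expect_error(positive_counts(2000, 10, c(5, -1)), "outside")
  expect_error(positive_counts(0, 0, c(0)), "integer >= 1")
  expect_error(positive_counts(10, 1.5, c(1)), "integer")
})

test_that("pi0 estimate matches direct arithmetic and handles edge counts", {
  expect_equal(estimate_pi0(positive_counts(2000, 100, rep(50, 4))),
               0.974359, tolerance = 1e-6)
  expect_equal(estimate_pi0(positive_counts(1000, 50, rep(50, 3))), 1.0)
  expect_equal(estimate_pi0(positive_counts(1000, 0, rep(0, 3))), 1.0)
  # S < mean permuted count pushes pi0 above 1: unclipped, with warning
  expect_warning(p <- estimate_pi0(positive_counts(1000, 10, rep(50, 2))),
                 "exceeds 1")
  expect_gt(p, 1)
  expect_error(estimate_pi0(positive_counts(100, 10, rep(100L, 2))),
               "denominator")
})

test_that("FDR point estimate matches the hand-computed oracle values", {
  pc <- positive_counts(2000, 100, c(40, 45, 50, 55, 60, 40, 45, 50, 55, 60))
  expect_equal(estimate_fdr(pc), 0.4871795, tolerance = 1e-6)
  expect_equal(estimate_fdr(positive_counts(1000, 10, rep(0, 5))), 0)
  # fixture at the scale of a transcriptome-wide scan: m = 17404, S = 11,
  # B = 1000 with 1650 permuted positives in total
  s <- rep(1L, 1000); s[1:650] <- 2L
  pc_big <- positive_counts(17404, 11, s)
  expect_equal(estimate_fdr(pc_big), 0.1499194, tolerance = 1e-5)

  expect_error(estimate_fdr(positive_counts(1000, 0, rep(5, 3))), "S = 0")
  expect_warning(f <- estimate_fdr(positive_counts(100, 100, rep(5, 3))),
                 "degenerate")
  expect_equal(f, 0)
  expect_warning(estimate_fdr(positive_counts(1000, 5, rep(50, 3))),
                 "exceeds 1")
})

test_that("fixed-lambda pi0 baseline counts tail p-values", {
  expect_equal(st_pi0_fixed_lambda(c(0.1, 0.2, 0.3, 0.6, 0.8, 0.9), 0.5), 1.0)
  expect_equal(st_pi0_fixed_lambda(c(0.2, 0.4), 0), 1.0)
  expect_equal(st_pi0_fixed_lambda(c(0.01, 0.02, 0.99, 0.98), 0.5), 1.0)
  # and a case away from 1
  expect_equal(st_pi0_fixed_lambda(c(0.01, 0.02, 0.6, 0.9), 0.5),
               2 / (0.5 * 4))
  expect_error(st_pi0_fixed_lambda(c(0.1, 1.2), 0.5), "\\[0, 1\\]")
  expect_error(st_pi0_fixed_lambda(c(0.1), 1), "lambda")
})

test_that("log-FDR variance agrees with both printed forms and the oracle", {
  pc <- positive_counts(2000, 100, rep(50, 10))
  expect_equal(var_log_fdr(pc), 0.0125776, tolerance = 1e-6)
  expect_equal(var_log_fdr(pc, form = "ratio"),
               oracle_var_ratio(2000, 100, 500, 10), tolerance = 1e-12)
  expect_equal(var_log_fdr(pc), oracle_var_woolf(2000, 100, 500, 10),
               tolerance = 1e-12)
  expect_error(var_log_fdr(positive_counts(100, 10, rep(0, 4))),
               "zero permuted")
  expect_error(var_log_fdr(positive_counts(100, 0, rep(5, 4))), "S = 0")
  expect_error(var_log_fdr(positive_counts(100, 100, rep(5, 4))), "S = m")
})

test_that("the two printed variance forms are identical over random counts", {
  for (cc in random_counts(500, seed = 11)) {
    pc <- positive_counts(cc$m, cc$S, cc$s_star)
    a <- var_log_fdr(pc, form = "woolf")
    b <- var_log_fdr(pc, form = "ratio")
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("large-m limit of the variance is approached and matches its oracle", {
  s <- rep(50L, 10)
  expect_equal(var_log_fdr_limit(positive_counts(2000, 100, s)), 0.012)
  big <- positive_counts(1000000, 100, s)
  expect_equal(var_log_fdr(big), var_log_fdr_limit(big), tolerance = 1e-3)
  s2 <- rep(1L, 1000); s2[1:650] <- 2L
  expect_equal(var_log_fdr_limit(positive_counts(17404, 11, s2)),
               0.0915152, tolerance = 1e-6)
  expect_equal(var_log_fdr_limit(positive_counts(10, 1, c(1L))), 2.0)
})

test_that("odds-ratio and factorization identities hold over random counts", {
  for (cc in random_counts(300, seed = 7)) {
    pc <- positive_counts(cc$m, cc$S, cc$s_star)
    fdr <- suppressWarnings(estimate_fdr(pc))
    expect_equal(fdr, oracle_fdr_odds(pc$m, pc$S, pc$s_star_mean),
                 tolerance = 1e-12)
    pi0 <- suppressWarnings(estimate_pi0(pc))
    expect_equal(fdr, pi0 * pc$s_star_mean / pc$S, tolerance = 1e-12)
  }
})

test_that("over-dispersion estimate matches hand arithmetic and flooring", {
  pc <- positive_counts(2000, 100, c(40, 45, 50, 55, 60, 40, 45, 50, 55, 60))
  phi <- estimate_overdispersion(pc, fdr_config(phi_floor = FALSE))
  expect_equal(as.numeric(phi), (500 / 9) / 48.75, tolerance = 1e-4)
  expect_false(attr(phi, "floored"))

  flat <- estimate_overdispersion(positive_counts(2000, 100, rep(50L, 10)))
  expect_equal(as.numeric(flat), 1.0)
  expect_true(attr(flat, "floored"))

  expect_error(estimate_overdispersion(positive_counts(100, 10, c(5L))),
               "B >= 2")
  expect_error(estimate_overdispersion(positive_counts(100, 10, rep(0L, 5))),
               "undefined")
})

test_that("raw over-dispersion is calibrated near 1 under independent binomials", {
  set.seed(42)
  phis <- replicate(1000, {
    s <- rbinom(10, 2000, 0.025)
    if (sum(s) == 0) s[1] <- 1
    as.numeric(estimate_overdispersion(positive_counts(2000, 5, s),
                                       fdr_config(phi_floor = FALSE)))
  })
  expect_gt(mean(phis), 0.9)
  expect_lt(mean(phis), 1.1)
})

test_that("confidence interval back-transform matches closed form", {
  ci <- confidence_interval(0.487179, 0.0125776, 0.95)
  expect_equal(unname(ci), c(0.391045, 0.606947), tolerance = 1e-4)
  expect_equal(unname(confidence_interval(0.3, 0, 0.95)), c(0.3, 0.3))
  z <- qnorm(0.975)
  expect_equal(unname(confidence_interval(1, 0.04, 0.95)),
               exp(c(-1, 1) * z * 0.2), tolerance = 1e-6)
  expect_error(confidence_interval(0, 0.01), "zero-substitution")
})

test_that("CI width shrinks as positive-test counts grow", {
  width <- function(S, ssum) {
    pc <- positive_counts(10000, S, rep(ssum / 10, 10))
    v <- var_log_fdr(pc)
    ci <- confidence_interval(suppressWarnings(estimate_fdr(pc)), v)
    diff(log(ci))  # width on the log scale isolates the variance effect
  }
  w_S <- sapply(c(10, 50, 100, 500), width, ssum = 100)
  expect_true(all(diff(w_S) <= 0))
  w_sum <- sapply(c(10, 50, 100, 500), function(ss) width(100, ss))
  expect_true(all(diff(w_sum) <= 0))
})

test_that("estimate_full chains the per-operation oracles", {
  pc <- positive_counts(2000, 100, c(40, 45, 50, 55, 60, 40, 45, 50, 55, 60))
  est <- estimate_full(pc)
  expect_s3_class(est, "fdr_estimate")
  expect_equal(est$fdr, 0.4871795, tolerance = 1e-6)
  expect_equal(est$phi, 1.13961, tolerance = 1e-4)
  expect_equal(est$var_log_fdr_adj, est$phi * est$var_log_fdr)
  # frozen from the independent oracle chain: exp back-transform of the
  # adjusted variance around the point estimate
  oc <- oracle_ci(oracle_fdr_odds(2000, 100, 50),
                  ((500 / 9) / 48.75) * oracle_var_woolf(2000, 100, 500, 10))
  expect_equal(est$ci_low, oc[1], tolerance = 1e-6)
  expect_equal(est$ci_high, oc[2], tolerance = 1e-6)
  expect_equal(est$ci_low, 0.385284, tolerance = 2e-4)
  expect_equal(est$ci_high, 0.616023, tolerance = 2e-4)
  expect_false(est$zero_substituted)
})

test_that("zero permuted positives trigger the substitution rule", {
  pc <- positive_counts(1000, 10, rep(0L, 10))
  expect_warning(est <- estimate_full(pc), "phi fixed at 1")
  expect_equal(est$fdr, 0)            # reported point estimate stays raw
  expect_true(est$zero_substituted)
  expect_gt(est$fdr_for_ci, 0)        # CI centred on the substituted estimate
  expect_equal(est$var_log_fdr, oracle_var_woolf(1000, 10, 1, 10),
               tolerance = 1e-12)
  expect_true(est$ci_low <= est$fdr_for_ci && est$fdr_for_ci <= est$ci_high)
  # with the rule disabled the CI is undefined
  expect_warning(
    est2 <- estimate_full(pc, fdr_config(zero_substitute = FALSE)),
    "phi fixed at 1")
  expect_true(is.na(est2$ci_low))
})

test_that("single permutation replicate falls back to phi = 1 with warning", {
  pc <- positive_counts(1000, 20, c(10L))
  expect_warning(est <- estimate_full(pc), "B = 1")
  expect_equal(est$phi, 1)
  expect_equal(est$var_log_fdr_adj, est$var_log_fdr)
  expect_equal(est$var_log_fdr, oracle_var_woolf(1000, 20, 10, 1),
               tolerance = 1e-12)
})

test_that("adjusted variance never shrinks below the raw variance when floored", {
  for (cc in random_counts(100, seed = 3)) {
    pc <- positive_counts(cc$m, cc$S, cc$s_star)
    est <- suppressWarnings(estimate_full(pc))
    expect_gte(est$var_log_fdr_adj, est$var_log_fdr)
  }
})

test_that("clip_fdr restricts reported values to [0, 1]", {
  pc <- positive_counts(1000, 5, rep(50L, 4))
  est <- suppressWarnings(estimate_full(pc, fdr_config(clip_fdr = TRUE)))
  expect_lte(est$fdr, 1)
  expect_lte(est$ci_high, 1)
})

test_that("BH-at-threshold and Bonferroni baselines compute as defined", {
  expect_equal(bh_fdr_at_threshold(c(0.01, 0.02, 0.03, 0.04), 0.025), 0.05)
  expect_equal(bh_fdr_at_threshold(c(0.001, 0.002), 1), 1)
  expect_equal(bh_fdr_at_threshold(c(0.5, 0.6), 0.55), 1.0)
  expect_error(bh_fdr_at_threshold(c(0.5, 0.6), 0.1), "undefined")

  expect_equal(bonferroni_threshold(17404, 0.05), 0.05 / 17404)
  expect_equal(signif(bonferroni_threshold(17404, 0.05), 3), 2.87e-6)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(20, 0.05), 0.0025)
})
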