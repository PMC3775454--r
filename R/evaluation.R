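#' True FDR from replicate-level discovery counts
#'
#' The realized false discovery proportion averaged over replicates,
#' `mean(F/S)` over replicates with at least one positive test. Replicates
#' with `S = 0` are excluded (the tail-area FDR conditions on `S > 0`);
#' their number is reported in the `"n_dropped"` attribute.
#'
#' @param F_counts Numeric vector of per-replicate false-discovery counts.
#' @param S_counts Numeric vector of per-replicate positive counts.
#' @return The mean of `F/S` over usable replicates, with attribute
#'   `"n_dropped"`.
#' @examples
#' true_fdr(c(1, 2, 3), c(10, 10, 10))
#' @export
true_fdr <- function(F_counts, S_counts) {
  if (length(F_counts) != length(S_counts)) {
    stop("`F_counts` and `S_counts` lengths differ", call. = FALSE)
  }
  use <- S_counts > 0
  if (!any(use)) {
    stop("true FDR undefined: no replicate with a positive test", call. = FALSE)
  }
  structure(mean(F_counts[use] / S_counts[use]),
            n_dropped = sum(!use))
}

#' Empirical coverage of a set of confidence intervals
#'
#' @param ci_pairs Two-column matrix (or data frame) of lower and upper
#'   bounds, one row per interval.
#' @param target The true value the intervals aim to cover.
#' @return Fraction of intervals containing `target`.
#' @examples
#' ci_coverage(rbind(c(0.1, 0.3), c(0.2, 0.4)), 0.25)
#' @export
ci_coverage <- function(ci_pairs, target) {
  ci_pairs <- as.matrix(ci_pairs)
  if (nrow(ci_pairs) == 0L) stop("no intervals supplied", call. = FALSE)
  mean(ci_pairs[, 1L] <= target & target <= ci_pairs[, 2L])
}

scenario_test_inputs <- function(sim) {
  if (!is.null(sim$labels)) {
    list(predictors = cbind(group = sim$labels), outcomes = sim$data,
         test_fn = test_fn_group_ttest())
  } else {
    list(predictors = sim$genotypes, outcomes = sim$traits,
         test_fn = test_fn_pairwise_lm())
  }
}

simulate_for_scenario <- function(config, seed) {
  config$seed <- seed
  if (inherits(config, "case_control_config")) {
    simulate_case_control(config)
  } else if (inherits(config, "snp_trait_config")) {
    simulate_snp_traits(config)
  } else {
    stop("unsupported generator config of class ",
         paste(class(config), collapse = "/"), call. = FALSE)
  }
}

#' Replicate-level evaluation of the FDR estimator on synthetic data
#'
#' For each replicate: simulate a dataset with a known truth mask, compute
#' observed and permuted p-values via [run_permutation_study()], form
#' positive-test counts at every threshold, and run [estimate_full()].
#' Aggregates across replicates into one row per threshold: the realized
#' true FDR (`mean(F/S)` over replicates with `S > 0`), the mean and
#' variance of the FDR estimate, its bias, the mean pi0 estimate, the mean
#' raw over-dispersion, and the empirical coverage and mean width of both
#' the over-dispersion-adjusted and the unadjusted confidence intervals
#' (evaluated against the realized true FDR of the scenario).
#'
#' Replicate simulation seeds are derived from the master seed
#' independently of `B`, so rerunning with a different number of
#' permutations reuses the same simulated datasets.
#'
#' @param config A [case_control_config()] or [snp_trait_config()].
#' @param B Number of permutations per replicate.
#' @param thresholds Numeric vector of significance thresholds.
#' @param n_replicates Number of replicate datasets (>= 2).
#' @param ci_level Confidence level for the intervals.
#' @param seed Master seed; the run is fully deterministic given it.
#' @param config_estimator An [fdr_config()] applied to every estimate.
#' @param keep_replicates If `TRUE`, the per-replicate records are attached
#'   as `attr(, "replicates")`.
#' @return A data frame of class `scenario_summary` with one row per
#'   threshold and columns `threshold`, `n_used` (replicates with `S > 0`),
#'   `true_fdr`, `mean_fdr_hat`, `bias`, `var_fdr_hat`, `mean_pi0`,
#'   `mean_phi_raw`, `coverage`, `coverage_unadj`, `mean_ci_width`,
#'   `mean_ci_width_unadj`, `prop_s_zero`.
#' @examples
#' cfg <- case_control_config(m = 200, n_blocks = 10, m1 = 50, shift = 0.5,
#'                            n_cases = 25, n_controls = 25)
#' run_scenario(cfg, B = 5, thresholds = c(0.01, 0.05), n_replicates = 5,
#'              seed = 1)
#' @export
run_scenario <- function(config, B = 10, thresholds, n_replicates = 50,
                         ci_level = 0.95, seed = 1,
                         config_estimator = fdr_config(ci_level = ci_level),
                         keep_replicates = FALSE) {
  check_count_scalar(n_replicates, "n_replicates", minimum = 2)
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0))
  thresholds <- sort(unique(thresholds))
  # simulation seeds first, permutation seeds second: the simulated
  # datasets are invariant to the choice of B
  sim_seeds <- derive_seeds(seed, n_replicates)
  set.seed(as.integer(seed) + 1L)
  perm_seeds <- sample.int(2147483646L, n_replicates)

  n_thr <- length(thresholds)
  rec <- function(name) matrix(NA_real_, n_replicates, n_thr,
                               dimnames = list(NULL, format(thresholds)))
  Fm <- rec(); Tm <- rec(); Sm <- rec()
  fdr_hat <- rec(); pi0_hat <- rec(); phi_raw <- rec()
  lo_adj <- rec(); hi_adj <- rec(); lo_raw <- rec(); hi_raw <- rec()

  for (r in seq_len(n_replicates)) {
    sim <- simulate_for_scenario(config, sim_seeds[r])
    inp <- scenario_test_inputs(sim)
    res <- run_permutation_study(inp$predictors, inp$outcomes, inp$test_fn,
                                 permutation_plan(B, seed = perm_seeds[r]))
    for (j in seq_len(n_thr)) {
      t <- thresholds[j]
      ct <- truth_counts(res$observed, sim$truth_mask, t)
      Fm[r, j] <- ct[["F"]]; Tm[r, j] <- ct[["T"]]; Sm[r, j] <- ct[["S"]]
      if (ct[["S"]] >= 1) {
        s_star <- colSums(res$permuted < t)
        m_tot <- length(res$observed)
        est <- suppressWarnings(
          estimate_full(positive_counts(m_tot, ct[["S"]], s_star),
                        config_estimator)
        )
        fdr_hat[r, j] <- est$fdr
        pi0_hat[r, j] <- est$pi0
        phi_raw[r, j] <- est$phi_raw
        lo_adj[r, j] <- est$ci_low
        hi_adj[r, j] <- est$ci_high
        if (!is.na(est$var_log_fdr) && est$fdr_for_ci > 0) {
          ci_u <- confidence_interval(est$fdr_for_ci, est$var_log_fdr,
                                      config_estimator$ci_level)
          lo_raw[r, j] <- ci_u[1L]
          hi_raw[r, j] <- ci_u[2L]
        }
      }
    }
  }

  summary_rows <- lapply(seq_len(n_thr), function(j) {
    use <- Sm[, j] > 0
    n_used <- sum(use)
    if (n_used == 0) {
      return(data.frame(
        threshold = thresholds[j], n_used = 0L, true_fdr = NA_real_,
        mean_fdr_hat = NA_real_, bias = NA_real_, var_fdr_hat = NA_real_,
        mean_pi0 = NA_real_, mean_phi_raw = NA_real_, coverage = NA_real_,
        coverage_unadj = NA_real_, mean_ci_width = NA_real_,
        mean_ci_width_unadj = NA_real_, prop_s_zero = 1
      ))
    }
    tf <- mean(Fm[use, j] / Sm[use, j])
    mf <- mean(fdr_hat[use, j])
    ci_ok <- use & !is.na(lo_adj[, j])
    ciu_ok <- use & !is.na(lo_raw[, j])
    data.frame(
      threshold = thresholds[j],
      n_used = n_used,
      true_fdr = tf,
      mean_fdr_hat = mf,
      bias = mf - tf,
      var_fdr_hat = if (n_used > 1) stats::var(fdr_hat[use, j]) else NA_real_,
      mean_pi0 = mean(pi0_hat[use, j]),
      mean_phi_raw = mean(phi_raw[use, j], na.rm = TRUE),
      coverage = if (any(ci_ok)) {
        mean(lo_adj[ci_ok, j] <= tf & tf <= hi_adj[ci_ok, j])
      } else NA_real_,
      coverage_unadj = if (any(ciu_ok)) {
        mean(lo_raw[ciu_ok, j] <= tf & tf <= hi_raw[ciu_ok, j])
      } else NA_real_,
      mean_ci_width = if (any(ci_ok)) {
        mean(hi_adj[ci_ok, j] - lo_adj[ci_ok, j])
      } else NA_real_,
      mean_ci_width_unadj = if (any(ciu_ok)) {
        mean(hi_raw[ciu_ok, j] - lo_raw[ciu_ok, j])
      } else NA_real_,
      prop_s_zero = mean(!use)
    )
  })
  out <- do.call(rbind, summary_rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "ci_level") <- ci_level
  attr(out, "n_replicates") <- n_replicates
  if (keep_replicates) {
    attr(out, "replicates") <- list(
      F = Fm, T = Tm, S = Sm, fdr_hat = fdr_hat, pi0_hat = pi0_hat,
      phi_raw = phi_raw, ci_low = lo_adj, ci_high = hi_adj,
      ci_low_unadj = lo_raw, ci_high_unadj = hi_raw
    )
  }
  class(out) <- c("scenario_summary", "data.frame")
  out
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("Scenario summary:", attr(x, "n_replicates"), "replicates, B =",
      attr(x, "B"), "permutations, seed", attr(x, "seed"), "\n")
  shown <- as.data.frame(x)
  num <- vapply(shown, is.double, logical(1L))
  shown[num] <- lapply(shown[num], signif, digits = 4)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
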