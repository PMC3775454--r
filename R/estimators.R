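#' Estimate the proportion of true null hypotheses
#'
#' Tractable estimator built from positive-test counts only:
#' \deqn{\hat\pi_0 = \frac{1 - S/m}{1 - \bar S^*/m}.}
#' The estimator is equivalent to the classic fixed-lambda tail estimator
#' with lambda set at the empirically adjusted p-value significance
#' threshold, and does not require p-values to be uniform under the null.
#' Values above 1 are possible when \eqn{S < \bar S^*} and are returned
#' as-is with a warning (no clipping).
#'
#' @param counts A [positive_counts()] object.
#' @return The estimated proportion of true nulls (non-negative scalar).
#' @examples
#' estimate_pi0(positive_counts(2000, 100, rep(50, 10)))
#' @export
estimate_pi0 <- function(counts) {
  counts <- as_positive_counts(counts)
  if (counts$s_star_mean >= counts$m) {
    stop("pi0 undefined: mean permuted positive count equals m (denominator zero)",
         call. = FALSE)
  }
  pi0 <- (1 - counts$S / counts$m) / (1 - counts$s_star_mean / counts$m)
  if (pi0 > 1) {
    warning("pi0 estimate ", format(pi0, digits = 6), " exceeds 1 ",
            "(S = ", counts$S, " < mean permuted count ",
            format(counts$s_star_mean, digits = 6), "); returned unclipped",
            call. = FALSE)
  }
  pi0
}

#' Tail-area FDR point estimate from positive-test counts
#'
#' \deqn{\widehat{FDR} = \frac{\bar S^*}{S}\,\frac{1 - S/m}{1 - \bar S^*/m}
#'  = \frac{\bar S^* (m - S)}{S (m - \bar S^*)},}
#' the odds ratio between the observed and permuted test outcomes. The
#' estimate factorizes as \eqn{\hat\pi_0 \cdot \bar S^*/S}. It is defined
#' conditionally on at least one observed positive test (`S >= 1`).
#'
#' @inheritParams estimate_pi0
#' @return The FDR point estimate (non-negative scalar; may exceed 1 when
#'   the permuted data yield more positives than the observed data, in which
#'   case a warning is raised).
#' @examples
#' estimate_fdr(positive_counts(2000, 100, c(40, 45, 50, 55, 60)))
#' @export
estimate_fdr <- function(counts) {
  counts <- as_positive_counts(counts)
  if (counts$S == 0) {
    stop("FDR undefined when no observed positive tests (S = 0); ",
         "the tail-area FDR conditions on S > 0 - consider a looser threshold",
         call. = FALSE)
  }
  if (counts$s_star_mean >= counts$m) {
    stop("FDR undefined: mean permuted positive count equals m", call. = FALSE)
  }
  if (counts$S == counts$m) {
    warning("every test is positive (S = m): degenerate threshold, FDR estimate 0",
            call. = FALSE)
    return(0)
  }
  fdr <- (counts$s_star_mean / counts$S) *
    (1 - counts$S / counts$m) / (1 - counts$s_star_mean / counts$m)
  if (fdr > 1) {
    warning("FDR estimate ", format(fdr, digits = 6),
            " exceeds 1 (permuted positives outnumber observed); ",
            "returned unclipped", call. = FALSE)
  }
  fdr
}

#' Fixed-lambda estimator of the proportion of true nulls
#'
#' The classic tail-count baseline \eqn{\hat\pi_0(\lambda) =
#' \#\{p_i > \lambda\} / ((1-\lambda) m)}. Provided for the documented
#' equivalence with [estimate_pi0()] when lambda is fixed at the empirically
#' adjusted significance threshold; it is not used inside the count-based
#' pipeline.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning parameter in `[0, 1)`.
#' @return Estimated proportion of true nulls.
#' @examples
#' st_pi0_fixed_lambda(c(0.1, 0.2, 0.3, 0.6, 0.8, 0.9), lambda = 0.5)
#' @export
st_pi0_fixed_lambda <- function(p_values, lambda) {
  if (length(p_values) == 0L) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda >= 1) {
    stop("`lambda` must be in [0, 1)", call. = FALSE)
  }
  sum(p_values > lambda) / ((1 - lambda) * length(p_values))
}

#' Delta-method variance of log(FDR-hat)
#'
#' Treating positive-test counts as binomial, the delta method after a log
#' transform gives
#' \deqn{\sigma^2_{FDR} = \frac{1}{\sum_i S^*_i} + \frac{1}{mB - \sum_i S^*_i}
#'   + \frac{1}{S} + \frac{1}{m - S},}
#' algebraically identical to
#' \eqn{m/\{(\sum_i S^*_i)(m - \bar S^*)\} + m/\{S(m - S)\}} and analogous to
#' the Woolf variance of a log odds ratio. Both forms are implemented; they
#' agree to machine precision and `form` selects which is evaluated.
#'
#' @inheritParams estimate_pi0
#' @param form `"woolf"` (default) evaluates the four-reciprocal form;
#'   `"ratio"` evaluates the first printed form. The two are equal to
#'   floating-point round-off.
#' @return Variance of the log FDR estimate (non-negative scalar).
#' @examples
#' var_log_fdr(positive_counts(2000, 100, rep(50, 10)))
#' @export
var_log_fdr <- function(counts, form = c("woolf", "ratio")) {
  form <- match.arg(form)
  counts <- as_positive_counts(counts)
  m <- counts$m; S <- counts$S; B <- counts$B
  ssum <- counts$s_star_sum
  if (ssum == 0) {
    stop("variance undefined: zero permuted positives (sum S* = 0); ",
         "apply the zero-substitution rule first", call. = FALSE)
  }
  if (S == 0) stop("variance undefined: S = 0", call. = FALSE)
  if (S == m) stop("variance undefined: S = m", call. = FALSE)
  if (ssum >= m * B) {
    stop("variance undefined: permuted positives fill every test slot",
         call. = FALSE)
  }
  if (form == "woolf") {
    1 / ssum + 1 / (m * B - ssum) + 1 / S + 1 / (m - S)
  } else {
    m / (ssum * (m - counts$s_star_mean)) + m / (S * (m - S))
  }
}

#' Large-m limit of the log-FDR variance
#'
#' When positive tests are few relative to the total number of tests,
#' the variance simplifies to \eqn{1/\sum_i S^*_i + 1/S}: precision is
#' driven almost entirely by counts of positive tests. Exposed for insight
#' (e.g. judging whether more permutations would help); pipelines use the
#' full [var_log_fdr()].
#'
#' @inheritParams estimate_pi0
#' @return Limiting variance of the log FDR estimate.
#' @examples
#' var_log_fdr_limit(positive_counts(2000, 100, rep(50, 10)))
#' @export
var_log_fdr_limit <- function(counts) {
  counts <- as_positive_counts(counts)
  if (counts$s_star_sum == 0) {
    stop("variance undefined: zero permuted positives", call. = FALSE)
  }
  if (counts$S == 0) stop("variance undefined: S = 0", call. = FALSE)
  1 / counts$s_star_sum + 1 / counts$S
}

#' Over-dispersion of permuted positive-test counts
#'
#' Dependencies between tests inflate the variance of positive-test counts
#' beyond the independent-binomial benchmark. The replicate permuted counts
#' provide a direct estimate of that inflation:
#' \deqn{\hat\phi = \frac{\sum_i (S^*_i - \bar S^*)^2 / (B - 1)}
#'   {m \hat p (1 - \hat p)}, \qquad \hat p = \bar S^*/m,}
#' used as a scalar multiplier on [var_log_fdr()]. With `phi_floor` on
#' (default) the returned value is `max(phi_hat, 1)` so the adjustment never
#' tightens the interval.
#'
#' @inheritParams estimate_pi0
#' @param config An [fdr_config()]; only `phi_floor` is consulted.
#' @return The over-dispersion estimate, with attribute `"floored"`
#'   indicating whether the floor at 1 was applied.
#' @examples
#' estimate_overdispersion(positive_counts(2000, 100, c(40, 45, 50, 55, 60)))
#' @export
estimate_overdispersion <- function(counts, config = fdr_config()) {
  counts <- as_positive_counts(counts)
  if (counts$B < 2) {
    stop("over-dispersion requires at least two permutation replicates (B >= 2)",
         call. = FALSE)
  }
  p_hat <- counts$p_hat
  if (p_hat <= 0 || p_hat >= 1) {
    stop("over-dispersion undefined: mean permuted positive count is ",
         if (p_hat <= 0) "0" else "m", call. = FALSE)
  }
  phi_raw <- stats::var(counts$s_star) / (counts$m * p_hat * (1 - p_hat))
  floored <- config$phi_floor && phi_raw < 1
  structure(if (floored) 1 else phi_raw, floored = floored)
}

#' Confidence interval for the FDR by exponential back-transform
#'
#' \deqn{CI = \exp\{\log \widehat{FDR} \pm z_{\alpha/2}\, \sigma_{FDR}\},}
#' the construction commonly used for odds ratios. Bounds are not clipped
#' to `[0, 1]` unless the caller requests clipping.
#'
#' @param fdr FDR point estimate, strictly positive (apply the
#'   zero-substitution rule first if the raw estimate is 0).
#' @param var_log_fdr Variance of the log FDR estimate (possibly
#'   over-dispersion adjusted), non-negative.
#' @param ci_level Two-sided confidence level in (0, 1).
#' @return Numeric vector `c(low, high)` with `low <= fdr <= high`.
#' @examples
#' confidence_interval(0.487179, 0.0125776, 0.95)
#' @export
confidence_interval <- function(fdr, var_log_fdr, ci_level = 0.95) {
  if (length(fdr) != 1L || is.na(fdr) || fdr <= 0) {
    stop("confidence interval needs a strictly positive FDR estimate; ",
         "for a zero estimate substitute a permuted positive count of 1 first ",
         "(zero-substitution rule)", call. = FALSE)
  }
  if (is.na(var_log_fdr) || var_log_fdr < 0) {
    stop("`var_log_fdr` must be non-negative", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  half <- z * sqrt(var_log_fdr)
  c(low = fdr * exp(-half), high = fdr * exp(half))
}

#' Full FDR estimate with over-dispersion-adjusted confidence interval
#'
#' Orchestrates the closed-form estimators: FDR point estimate and pi0 from
#' the raw counts; the zero-substitution rule (a permuted positive sum of 0
#' is conservatively set to 1 for variance/CI estimation only, flagged in
#' the result, while the reported point estimate stays 0); over-dispersion
#' from the replicate permuted counts (falls back to 1 with a warning when
#' `B < 2` or when no permuted positives were observed); and the
#' exponential back-transform interval on the adjusted variance.
#'
#' @inheritParams estimate_pi0
#' @param config An [fdr_config()].
#' @return An object of class `fdr_estimate`: a list with elements `fdr`,
#'   `pi0`, `var_log_fdr`, `phi`, `phi_raw`, `var_log_fdr_adj`, `ci_low`,
#'   `ci_high`, `ci_level`, `fdr_for_ci` (the point estimate the interval is
#'   centred on; differs from `fdr` only under zero substitution), the flags
#'   `zero_substituted` and `phi_floored`, and the input summaries `m`, `S`,
#'   `s_star_mean`, `B`.
#' @examples
#' estimate_full(positive_counts(2000, 100, c(40, 45, 50, 55, 60)))
#' @export
estimate_full <- function(counts, config = fdr_config()) {
  counts <- as_positive_counts(counts)
  if (counts$S == 0) {
    stop("FDR undefined when no observed positive tests (S = 0); ",
         "consider a looser threshold", call. = FALSE)
  }
  fdr <- estimate_fdr(counts)
  pi0 <- estimate_pi0(counts)

  zero_substituted <- FALSE
  counts_ci <- counts
  if (counts$s_star_sum == 0) {
    if (config$zero_substitute) {
      s_sub <- counts$s_star
      s_sub[1L] <- 1
      counts_ci <- positive_counts(counts$m, counts$S, s_sub)
      zero_substituted <- TRUE
    } else {
      counts_ci <- NULL
    }
  }

  phi_raw <- NA_real_
  phi <- 1
  phi_floored <- FALSE
  if (zero_substituted || is.null(counts_ci)) {
    warning("no permuted positive tests: over-dispersion not estimable, phi fixed at 1",
            call. = FALSE)
  } else if (counts$B < 2) {
    warning("single permutation replicate (B = 1): over-dispersion not estimable, ",
            "phi fixed at 1", call. = FALSE)
  } else {
    phi_est <- estimate_overdispersion(counts, config)
    phi_raw <- if (attr(phi_est, "floored")) {
      stats::var(counts$s_star) / (counts$m * counts$p_hat * (1 - counts$p_hat))
    } else {
      as.numeric(phi_est)
    }
    phi <- as.numeric(phi_est)
    phi_floored <- attr(phi_est, "floored")
  }

  if (is.null(counts_ci) || counts$S == counts$m) {
    var_raw <- NA_real_
    var_adj <- NA_real_
    fdr_for_ci <- NA_real_
    ci <- c(low = NA_real_, high = NA_real_)
  } else {
    var_raw <- var_log_fdr(counts_ci)
    var_adj <- phi * var_raw
    fdr_for_ci <- if (zero_substituted) estimate_fdr(counts_ci) else fdr
    ci <- confidence_interval(fdr_for_ci, var_adj, config$ci_level)
  }

  if (config$clip_fdr) {
    fdr <- min(fdr, 1)
    ci <- pmin(pmax(ci, 0), 1)
  }

  structure(
    list(
      fdr = fdr, pi0 = pi0,
      var_log_fdr = var_raw, phi = phi, phi_raw = phi_raw,
      var_log_fdr_adj = var_adj,
      ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
      ci_level = config$ci_level, fdr_for_ci = fdr_for_ci,
      zero_substituted = zero_substituted, phi_floored = phi_floored,
      m = counts$m, S = counts$S, s_star_mean = counts$s_star_mean,
      B = counts$B
    ),
    class = "fdr_estimate"
  )
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat("Tail-area FDR estimate (m =", format(x$m), ", S =", format(x$S),
      ", B =", x$B, ")\n")
  cat(sprintf("  FDR = %s   %d%% CI (%s, %s)\n",
              format(x$fdr, digits = 6), round(100 * x$ci_level),
              format(x$ci_low, digits = 6), format(x$ci_high, digits = 6)))
  cat(sprintf("  pi0 = %s   phi = %s   var[log FDR] = %s (adjusted %s)\n",
              format(x$pi0, digits = 6), format(x$phi, digits = 6),
              format(x$var_log_fdr, digits = 6),
              format(x$var_log_fdr_adj, digits = 6)))
  if (isTRUE(x$zero_substituted)) {
    cat("  note: zero permuted positives substituted by 1 for the CI;\n",
        "        interval centred on", format(x$fdr_for_ci, digits = 6), "\n")
  }
  invisible(x)
}

#' Benjamini-Hochberg style FDR at a fixed threshold
#'
#' The plug-in quantity `min(1, m * t / #{p < t})`, which implicitly assumes
#' all null hypotheses are true (pi0 = 1). Provided as a cross-check
#' baseline for the count-based estimator.
#'
#' @param p_values Numeric vector of p-values.
#' @param threshold Significance threshold in (0, 1].
#' @return The BH-style FDR value at `threshold`.
#' @examples
#' bh_fdr_at_threshold(c(0.01, 0.02, 0.03, 0.04), 0.025)
#' @export
bh_fdr_at_threshold <- function(p_values, threshold) {
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 ||
      threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  n_pos <- sum(p_values < threshold)
  if (n_pos == 0) {
    stop("no p-values below the threshold: BH FDR undefined", call. = FALSE)
  }
  min(1, length(p_values) * threshold / n_pos)
}

#' Bonferroni per-test significance threshold
#'
#' @param m Number of tests (positive integer).
#' @param alpha Family-wise error rate in (0, 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(17404, 0.05)
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  check_count_scalar(m, "m", minimum = 1)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  alpha / m
}
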