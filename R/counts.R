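#' Positive-test counts: the sufficient statistics of the FDR estimator
#'
#' Bundles the counts that fully determine the tail-area FDR estimate at a
#' fixed significance threshold: the total number of tests `m`, the observed
#' positive-test count `S`, and one positive-test count per permuted dataset.
#' Everything downstream (point estimate, pi0, variance, over-dispersion,
#' confidence interval) is a function of these counts alone, so the method
#' can be applied without storing per-test results.
#'
#' @param m Total number of tests conducted (positive integer).
#' @param S Observed count of positive tests at the working threshold
#'   (integer, `0 <= S <= m`).
#' @param s_star Integer vector of length `B >= 1`: the positive-test count
#'   in each of the `B` permuted datasets, each in `[0, m]`.
#'
#' @return An object of class `positive_counts`: a list with elements `m`,
#'   `S`, `s_star`, and the derived quantities `B`, `s_star_sum`,
#'   `s_star_mean`, and `p_hat = s_star_mean / m`.
#' @examples
#' positive_counts(m = 2000, S = 100, s_star = c(40, 45, 50, 55, 60))
#' @export
positive_counts <- function(m, S, s_star) {
  check_count_scalar(m, "m", minimum = 1)
  check_count_scalar(S, "S", minimum = 0)
  if (length(s_star) < 1L) {
    stop("`s_star` must contain at least one permutation count (B >= 1)",
         call. = FALSE)
  }
  if (anyNA(s_star) || !is.numeric(s_star) || any(s_star != floor(s_star))) {
    stop("`s_star` must be a vector of non-negative integers", call. = FALSE)
  }
  if (S > m) stop("invalid counts: S = ", S, " exceeds m = ", m, call. = FALSE)
  if (any(s_star < 0) || any(s_star > m)) {
    bad <- which(s_star < 0 | s_star > m)[1L]
    stop("invalid counts: s_star[", bad, "] = ", s_star[bad],
         " outside [0, m = ", m, "]", call. = FALSE)
  }
  B <- length(s_star)
  s_star_sum <- sum(as.numeric(s_star))
  structure(
    list(
      m = as.numeric(m), S = as.numeric(S), s_star = as.numeric(s_star),
      B = B, s_star_sum = s_star_sum, s_star_mean = s_star_sum / B,
      p_hat = s_star_sum / (B * m)
    ),
    class = "positive_counts"
  )
}

check_count_scalar <- function(x, name, minimum) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != floor(x) ||
      x < minimum) {
    stop("`", name, "` must be a single integer >= ", minimum, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.positive_counts <- function(x, ...) {
  cat("Positive-test counts: m =", format(x$m), " S =", format(x$S),
      " B =", x$B, "\n")
  cat("  permuted positives: sum =", format(x$s_star_sum),
      " mean =", format(x$s_star_mean, digits = 6),
      " p_hat =", format(x$p_hat, digits = 6), "\n")
  invisible(x)
}

#' Estimator configuration
#'
#' Settings shared by the closed-form estimators and the threshold-scan
#' pipeline.
#'
#' @param ci_level Two-sided confidence level in (0, 1); default 0.95, which
#'   uses the normal quantile z = 1.959964.
#' @param lambda Tuning parameter in `[0, 1)` for the fixed-lambda baseline
#'   estimator of the proportion of true nulls ([st_pi0_fixed_lambda()]);
#'   default 0.5.
#' @param phi_floor If `TRUE` (default), the over-dispersion estimate is
#'   floored at 1 so the dependence adjustment never shrinks the variance.
#' @param zero_substitute If `TRUE` (default), a permuted positive-count sum
#'   of zero is replaced by one for variance and confidence-interval
#'   estimation only (the reported point estimate stays 0).
#' @param clip_fdr If `TRUE`, reported FDR and CI bounds are clipped to
#'   `[0, 1]` for presentation; default `FALSE` (values above 1 are possible
#'   and are reported as-is with a warning).
#'
#' @return An object of class `fdr_config`.
#' @examples
#' fdr_config(ci_level = 0.9, phi_floor = FALSE)
#' @export
fdr_config <- function(ci_level = 0.95, lambda = 0.5, phi_floor = TRUE,
                       zero_substitute = TRUE, clip_fdr = FALSE) {
  if (length(ci_level) != 1L || is.na(ci_level) || ci_level <= 0 ||
      ci_level >= 1) {
    stop("`ci_level` must be a single number in (0, 1)", call. = FALSE)
  }
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda >= 1) {
    stop("`lambda` must be a single number in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      ci_level = ci_level, lambda = lambda,
      phi_floor = isTRUE(phi_floor),
      zero_substitute = isTRUE(zero_substitute),
      clip_fdr = isTRUE(clip_fdr)
    ),
    class = "fdr_config"
  )
}

as_positive_counts <- function(x) {
  if (inherits(x, "positive_counts")) return(x)
  if (is.list(x) && all(c("m", "S", "s_star") %in% names(x))) {
    return(positive_counts(x$m, x$S, x$s_star))
  }
  stop("cannot interpret input as positive-test counts", call. = FALSE)
}
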