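#' Count positive tests at a significance threshold
#'
#' Strict comparison `p < threshold` by default, matching the usual
#' "p < 0.0001" reading of a significance threshold; set `strict = FALSE`
#' for `<=`. Inputs may instead be statistics where larger means more
#' significant (`orientation = "statistic"`), in which case the comparison
#' is reversed (`x > threshold`, or `>=` when not strict).
#'
#' @param x Numeric vector of p-values (default orientation) or test
#'   statistics.
#' @param threshold Single positive cutoff.
#' @param strict Use a strict inequality (default `TRUE`).
#' @param orientation `"pvalue"` (smaller = more significant, default) or
#'   `"statistic"` (larger = more significant).
#' @return Integer count of positive tests; an empty input yields 0.
#' @examples
#' count_positives(c(0.001, 0.02, 0.5), 0.01)
#' @export
count_positives <- function(x, threshold, strict = TRUE,
                            orientation = c("pvalue", "statistic")) {
  orientation <- match.arg(orientation)
  if (length(threshold) != 1L || is.na(threshold)) {
    stop("`threshold` must be a single number", call. = FALSE)
  }
  if (orientation == "pvalue" && threshold <= 0) {
    stop("`threshold` must be positive for p-value input", call. = FALSE)
  }
  if (length(x) == 0L) return(0L)
  if (orientation == "pvalue") {
    if (strict) sum(x < threshold) else sum(x <= threshold)
  } else {
    if (strict) sum(x > threshold) else sum(x >= threshold)
  }
}

default_threshold_grid <- function(p_values) {
  p_min <- min(p_values[p_values > 0], 1)
  k_max <- max(4L, ceiling(-log10(p_min) * 4))
  sort(10^(-(seq_len(k_max)) / 4))
}

#' FDR table over a grid of significance thresholds
#'
#' Applies the count-based FDR estimator at each threshold of a grid,
#' producing one row per threshold with the observed positive count, the
#' mean permuted positive count, the FDR estimate with its
#' over-dispersion-adjusted confidence interval, and the pi0 estimate.
#' Rows where no observed test is positive (`S = 0`) are retained with an
#' undefined (NA) FDR so the table covers the full grid.
#'
#' @param observed Numeric vector of m observed p-values (or statistics;
#'   see `orientation`).
#' @param permuted Numeric matrix with m rows and B columns (one column per
#'   permuted dataset), or a list of B numeric vectors each of length m.
#' @param thresholds Increasing numeric vector of significance thresholds.
#'   If `NULL`, a logarithmic grid `10^(-k/4)` covering the observed
#'   p-value range is used and echoed in the result.
#' @param config An [fdr_config()].
#' @inheritParams count_positives
#' @return A data frame of class `fdr_table` with columns `threshold`, `S`,
#'   `s_star_mean`, `fdr`, `ci_low`, `ci_high`, `pi0`, `zero_substituted`,
#'   sorted by increasing threshold. The grid used is stored in
#'   `attr(, "thresholds")`.
#' @examples
#' obs <- c(0.001, 0.004, 0.2, 0.6, 0.9)
#' perm <- cbind(c(0.05, 0.3, 0.4, 0.7, 0.8), c(0.02, 0.1, 0.5, 0.6, 0.95))
#' build_fdr_table(obs, perm, thresholds = c(0.01, 0.5))
#' @export
build_fdr_table <- function(observed, permuted, thresholds = NULL,
                            config = fdr_config(), strict = TRUE,
                            orientation = c("pvalue", "statistic")) {
  orientation <- match.arg(orientation)
  m <- length(observed)
  if (m == 0L) stop("`observed` is empty", call. = FALSE)
  if (is.list(permuted) && !is.data.frame(permuted)) {
    lens <- lengths(permuted)
    bad <- which(lens != m)
    if (length(bad)) {
      stop("permutation replicate ", bad[1L], " has length ", lens[bad[1L]],
           " but `observed` has length ", m, call. = FALSE)
    }
    permuted <- matrix(unlist(permuted, use.names = FALSE), nrow = m)
  }
  permuted <- as.matrix(permuted)
  if (nrow(permuted) != m) {
    stop("`permuted` must have one row per test (", m, " rows), got ",
         nrow(permuted), call. = FALSE)
  }
  if (is.null(thresholds)) thresholds <- default_threshold_grid(observed)
  if (any(thresholds <= 0) && orientation == "pvalue") {
    stop("thresholds must be strictly positive", call. = FALSE)
  }
  thresholds <- sort(unique(thresholds))

  rows <- lapply(thresholds, function(t) {
    S <- count_positives(observed, t, strict = strict,
                         orientation = orientation)
    s_star <- apply(permuted, 2L, count_positives, threshold = t,
                    strict = strict, orientation = orientation)
    counts_ok <- S >= 1L
    if (counts_ok) {
      est <- suppressWarnings(
        estimate_full(positive_counts(m, S, s_star), config)
      )
      data.frame(
        threshold = t, S = S, s_star_mean = mean(s_star), fdr = est$fdr,
        ci_low = est$ci_low, ci_high = est$ci_high, pi0 = est$pi0,
        zero_substituted = est$zero_substituted
      )
    } else {
      pi0 <- suppressWarnings(estimate_pi0(positive_counts(m, S, s_star)))
      data.frame(
        threshold = t, S = 0L, s_star_mean = mean(s_star), fdr = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, pi0 = pi0,
        zero_substituted = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  attr(out, "config") <- config
  class(out) <- c("fdr_table", "data.frame")
  out
}

#' @export
print.fdr_table <- function(x, ...) {
  cat("FDR table over", nrow(x), "significance thresholds\n")
  shown <- as.data.frame(x)
  num <- vapply(shown, is.numeric, logical(1L))
  shown[num] <- lapply(shown[num], signif, digits = 6)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Data-driven significance-threshold selection
#'
#' Picks the table row minimizing either the FDR point estimate
#' (`"min_fdr"`) or the upper confidence limit (`"min_upper_cl"`) among
#' rows with a defined estimate. Ties are broken toward the larger
#' threshold, which yields more discoveries at the same estimated FDR.
#'
#' @param table An [build_fdr_table()] result.
#' @param criterion `"min_fdr"` or `"min_upper_cl"`.
#' @return The selected row as a one-row data frame.
#' @examples
#' obs <- c(0.001, 0.004, 0.2, 0.6, 0.9)
#' perm <- cbind(c(0.05, 0.3, 0.4, 0.7, 0.8), c(0.02, 0.1, 0.5, 0.6, 0.95))
#' tab <- build_fdr_table(obs, perm, thresholds = c(0.01, 0.5))
#' select_threshold(tab, "min_fdr")
#' @export
select_threshold <- function(table, criterion = c("min_fdr", "min_upper_cl")) {
  criterion <- match.arg(criterion)
  value <- if (criterion == "min_fdr") table$fdr else table$ci_high
  ok <- !is.na(table$fdr) & !is.na(value)
  if (!any(ok)) {
    stop("no threshold with a defined FDR estimate: nothing to select",
         call. = FALSE)
  }
  v <- value[ok]
  cand <- which(ok)[v == min(v)]
  # tie-break toward the largest threshold
  row <- cand[which.max(table$threshold[cand])]
  out <- as.data.frame(table)[row, , drop = FALSE]
  rownames(out) <- NULL
  out
}
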