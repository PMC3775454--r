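#' Permutation plan
#'
#' Describes how a permutation study is run: how many permuted datasets to
#' generate, the master seed, and which side of the data has its sample
#' labels permuted. Permutations are drawn uniformly at random with
#' replacement across replicates (a coincidental identity permutation is
#' allowed). The master seed spawns one substream per replicate, so results
#' do not depend on execution order.
#'
#' @param B Number of permutation replicates (>= 1).
#' @param seed Integer master seed.
#' @param unit Which table has its sample labels relabeled: `"outcomes"`
#'   (default; preserves the internal dependence structure of both tables)
#'   or `"predictors"`.
#' @param indices Optional precomputed list of `B` permutations of the
#'   sample indices, overriding random generation (used for forcing, e.g.,
#'   identity permutations).
#' @return An object of class `permutation_plan`.
#' @examples
#' permutation_plan(B = 10, seed = 1)
#' @export
permutation_plan <- function(B, seed = 1L,
                             unit = c("outcomes", "predictors"),
                             indices = NULL) {
  unit <- match.arg(unit)
  check_count_scalar(B, "B", minimum = 1)
  check_count_scalar(seed, "seed", minimum = 0)
  if (!is.null(indices)) {
    if (!is.list(indices) || length(indices) != B) {
      stop("`indices` must be a list of B permutations", call. = FALSE)
    }
  }
  structure(list(B = as.integer(B), seed = as.integer(seed), unit = unit,
                 indices = indices),
            class = "permutation_plan")
}

#' Reproducible stream of uniform random permutations
#'
#' Each permutation is generated from its own seed derived from the master
#' seed, so the i-th permutation is the same regardless of how many others
#' are generated or in what order.
#'
#' @param n Number of items to permute (>= 2).
#' @param B Number of permutations.
#' @param seed Integer master seed.
#' @return A `B x n` integer matrix; each row is a permutation of `1:n`.
#' @examples
#' permute_indices(5, 3, seed = 42)
#' @export
permute_indices <- function(n, B, seed = 1L) {
  check_count_scalar(n, "n", minimum = 2)
  check_count_scalar(B, "B", minimum = 1)
  sub_seeds <- derive_seeds(seed, B)
  out <- matrix(0L, nrow = B, ncol = n)
  for (i in seq_len(B)) {
    set.seed(sub_seeds[i])
    out[i, ] <- sample.int(n)
  }
  out
}

# Derive k sub-seeds (< 2^31) from one master seed, deterministically.
derive_seeds <- function(seed, k) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, k)
}

#' Run a permutation study for a user-supplied test function
#'
#' Computes the observed per-test p-values (or statistics) and `B` permuted
#' replicates by relabeling the samples of one side of the data. Relabeling
#' whole rows preserves the dependence structure within both tables, which
#' is what makes the replicate positive-test counts informative about
#' dependence-induced over-dispersion.
#'
#' @param predictors Matrix or data frame, n samples x q variables.
#' @param outcomes Matrix or data frame, n samples x r variables (same
#'   sample order as `predictors`).
#' @param test_fn Function `(predictors, outcomes) -> numeric vector` of m
#'   per-test p-values (or statistics). Must be deterministic and must
#'   return the same length on every call. See [test_fn_group_ttest()] and
#'   [test_fn_pairwise_lm()] for built-ins.
#' @param plan A [permutation_plan()].
#' @return A list with `observed` (length-m numeric vector), `permuted`
#'   (m x B matrix, one column per permuted dataset), and the `plan`.
#' @examples
#' x <- cbind(group = rep(0:1, each = 10))
#' y <- matrix(rnorm(20 * 5), 20, 5)
#' res <- run_permutation_study(x, y, test_fn_group_ttest(),
#'                              permutation_plan(B = 3, seed = 7))
#' dim(res$permuted)
#' @export
run_permutation_study <- function(predictors, outcomes, test_fn, plan) {
  predictors <- as.matrix(predictors)
  outcomes <- as.matrix(outcomes)
  if (nrow(predictors) != nrow(outcomes)) {
    stop("sample-axis mismatch: predictors have ", nrow(predictors),
         " rows, outcomes ", nrow(outcomes), call. = FALSE)
  }
  n <- nrow(outcomes)
  observed <- test_fn(predictors, outcomes)
  m <- length(observed)
  if (m == 0L) stop("`test_fn` returned no p-values", call. = FALSE)

  perms <- if (is.null(plan$indices)) {
    permute_indices(n, plan$B, plan$seed)
  } else {
    do.call(rbind, plan$indices)
  }
  permuted <- matrix(NA_real_, nrow = m, ncol = plan$B)
  for (i in seq_len(plan$B)) {
    idx <- perms[i, ]
    p_i <- if (plan$unit == "outcomes") {
      test_fn(predictors, outcomes[idx, , drop = FALSE])
    } else {
      test_fn(predictors[idx, , drop = FALSE], outcomes)
    }
    if (length(p_i) != m) {
      stop("`test_fn` contract violation: replicate ", i, " returned ",
           length(p_i), " values, expected ", m, call. = FALSE)
    }
    permuted[, i] <- p_i
  }
  list(observed = observed, permuted = permuted, plan = plan)
}

#' Built-in test function: two-sample pooled-variance t-tests by column
#'
#' Returns a test function for [run_permutation_study()] that treats the
#' first predictor column as a two-group label and performs an
#' equal-variance two-sample t-test of every outcome column against it,
#' vectorized over columns.
#'
#' @return A function `(predictors, outcomes) -> p-values` (two-sided).
#' @examples
#' f <- test_fn_group_ttest()
#' f(cbind(rep(0:1, each = 5)), matrix(rnorm(30), 10, 3))
#' @export
test_fn_group_ttest <- function() {
  function(predictors, outcomes) {
    labels <- as.numeric(predictors[, 1L])
    col_ttest_p(labels, as.matrix(outcomes))
  }
}

# Vectorized pooled two-sample t-test of each column of X between
# labels == max(labels) and the rest. Returns two-sided p-values.
col_ttest_p <- function(labels, X) {
  g1 <- labels == max(labels)
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two samples",
                             call. = FALSE)
  X1 <- X[g1, , drop = FALSE]
  X2 <- X[!g1, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  ss1 <- colSums(X1 * X1) - n1 * m1 * m1
  ss2 <- colSums(X2 * X2) - n2 * m2 * m2
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tstat), df)
}

#' Built-in test function: all-pairs simple-linear-regression F-tests
#'
#' Returns a test function that regresses every outcome column on every
#' predictor column (one simple linear model per pair) and reports the
#' F-test p-value of the slope, computed from the Pearson correlation.
#' The m = q x r p-values are returned in column-major pair order
#' (predictor index varying fastest).
#'
#' @return A function `(predictors, outcomes) -> p-values`.
#' @examples
#' f <- test_fn_pairwise_lm()
#' f(matrix(rnorm(40), 20, 2), matrix(rnorm(60), 20, 3))
#' @export
test_fn_pairwise_lm <- function() {
  function(predictors, outcomes) {
    G <- as.matrix(predictors)
    Y <- as.matrix(outcomes)
    n <- nrow(G)
    if (n < 3) stop("need at least three samples for regression F-tests",
                    call. = FALSE)
    r <- stats::cor(G, Y)
    r2 <- pmin(r * r, 1 - 1e-15)
    fstat <- r2 * (n - 2) / (1 - r2)
    as.vector(stats::pf(fstat, 1, n - 2, lower.tail = FALSE))
  }
}
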