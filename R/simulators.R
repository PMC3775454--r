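#' Configuration for the correlated case-control expression simulator
#'
#' Emulates the classic correlated z-score design: `m` genes observed on
#' cases and controls, organized in `n_blocks` equicorrelated blocks whose
#' common within-block correlation `rho` is solved in closed form so that
#' the root-mean-squared correlation over all gene pairs equals
#' `alpha_rms`. False null hypotheses are created by adding a constant
#' `shift` to the case observations of `m1` genes, spread evenly across
#' blocks. Defaults are the weak-effect scenario: 2000 genes, 100 cases and
#' 100 controls, 40 blocks, alpha_rms = 0.05, shift = 0.15, pi0 = 0.75
#' (m1 = 500).
#'
#' @param n_cases,n_controls Group sample sizes.
#' @param m Number of genes; must be divisible by `n_blocks`.
#' @param n_blocks Number of equicorrelated blocks.
#' @param alpha_rms Target root-mean-squared correlation over all gene
#'   pairs (>= 0). The implied within-block correlation must be < 1.
#' @param shift Constant added to case observations at false-null genes.
#' @param m1 Number of false null hypotheses (`0 <= m1 <= m`).
#' @param seed Optional integer seed consumed by [simulate_case_control()].
#' @return An object of class `case_control_config` (also records the
#'   derived within-block correlation `rho`).
#' @examples
#' case_control_config(alpha_rms = 0.1, shift = 0.3, m = 4000, m1 = 400)
#' @export
case_control_config <- function(n_cases = 100, n_controls = 100, m = 2000,
                                n_blocks = 40, alpha_rms = 0.05,
                                shift = 0.15, m1 = 500, seed = NULL) {
  check_count_scalar(n_cases, "n_cases", minimum = 2)
  check_count_scalar(n_controls, "n_controls", minimum = 2)
  check_count_scalar(m, "m", minimum = 2)
  check_count_scalar(n_blocks, "n_blocks", minimum = 1)
  check_count_scalar(m1, "m1", minimum = 0)
  if (m %% n_blocks != 0) {
    stop("`m` (", m, ") must be divisible by `n_blocks` (", n_blocks, ")",
         call. = FALSE)
  }
  if (m1 > m) stop("`m1` cannot exceed `m`", call. = FALSE)
  if (alpha_rms < 0) stop("`alpha_rms` must be >= 0", call. = FALSE)
  rho <- rho_from_alpha_rms(alpha_rms, m, n_blocks)
  structure(
    list(n_cases = n_cases, n_controls = n_controls, m = m,
         n_blocks = n_blocks, alpha_rms = alpha_rms, shift = shift,
         m1 = m1, rho = rho, seed = seed),
    class = "case_control_config"
  )
}

# Closed-form within-block correlation such that the population RMS
# correlation over all C(m, 2) gene pairs equals alpha_rms: only the
# n_blocks * C(b, 2) within-block pairs are nonzero, each equal to rho.
rho_from_alpha_rms <- function(alpha_rms, m, n_blocks) {
  b <- m / n_blocks
  if (b < 2) {
    if (alpha_rms > 0) {
      stop("blocks of size 1 cannot carry correlation; alpha_rms must be 0",
           call. = FALSE)
    }
    return(0)
  }
  rho <- alpha_rms * sqrt(choose(m, 2) / (n_blocks * choose(b, 2)))
  if (rho >= 1) {
    alpha_max <- sqrt(n_blocks * choose(b, 2) / choose(m, 2))
    stop("infeasible alpha_rms = ", alpha_rms,
         ": implied within-block correlation ", format(rho, digits = 4),
         " >= 1; maximal feasible alpha_rms is ",
         format(alpha_max, digits = 4), call. = FALSE)
  }
  rho
}

#' Simulate a correlated case-control expression study
#'
#' Rows are subjects (cases first), columns genes. Under the null every
#' gene is standard normal; genes within a block share the equicorrelation
#' `rho` implied by `alpha_rms`; case rows of the `m1` false-null genes are
#' shifted by `shift`.
#'
#' @param config A [case_control_config()].
#' @return A list with `data` (numeric matrix, `(n_cases + n_controls) x m`),
#'   `labels` (1 for cases, 0 for controls), `truth_mask` (logical, `TRUE`
#'   = false null), and the `config` echo.
#' @examples
#' sim <- simulate_case_control(case_control_config(m = 200, n_blocks = 10,
#'                                                  m1 = 50, seed = 1))
#' table(sim$truth_mask)
#' @export
simulate_case_control <- function(config) {
  stopifnot(inherits(config, "case_control_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  m <- config$m
  b <- m / config$n_blocks
  rho <- config$rho
  block_of <- rep(seq_len(config$n_blocks), each = b)
  E <- matrix(stats::rnorm(n * m), n, m)
  X <- if (rho > 0) {
    U <- matrix(stats::rnorm(n * config$n_blocks), n, config$n_blocks)
    sqrt(1 - rho) * E + sqrt(rho) * U[, block_of, drop = FALSE]
  } else {
    E
  }
  truth_mask <- logical(m)
  if (config$m1 > 0) {
    k <- seq_len(config$m1) - 1L
    cols <- (k %% config$n_blocks) * b + (k %/% config$n_blocks) + 1L
    truth_mask[cols] <- TRUE
    X[seq_len(config$n_cases), cols] <-
      X[seq_len(config$n_cases), cols] + config$shift
  }
  list(
    data = X,
    labels = rep(c(1, 0), c(config$n_cases, config$n_controls)),
    truth_mask = truth_mask,
    config = config
  )
}

#' Configuration for the LD-block SNP x trait-module simulator
#'
#' Emulates a genetic-association design: SNPs generated in LD blocks from
#' a latent-Gaussian (copula) haplotype model, quantitative traits in
#' equicorrelated modules, and every SNP-trait pair tested by a simple
#' linear regression F-test. Defaults follow the standard layout of 20 LD
#' blocks of 5 SNPs (composite LD targets uniform on 0.4-0.9 within each
#' block), 10 trait modules of 5 traits (correlations uniform on 0.4-0.9),
#' minor allele frequencies uniform on (0.2, 0.5), and 200 subjects,
#' giving 100 x 50 = 5000 tests.
#'
#' @param n_subjects Number of subjects.
#' @param n_ld_blocks,snps_per_block LD-block layout.
#' @param ld_range Length-2 range of target within-block composite LD
#'   (genotype-dosage correlation).
#' @param n_modules,traits_per_module Trait-module layout.
#' @param corr_range Length-2 range of within-module trait correlations.
#' @param maf_range Length-2 range of minor allele frequencies, inside
#'   (0, 0.5].
#' @param m1 Number of false-null SNP-trait pairs.
#' @param effect_size Per-allele slope added to the trait of each
#'   false-null pair. The default 0.35 gives per-pair power of roughly 0.5
#'   at a 1e-3 threshold with 200 subjects.
#' @param seed Optional integer seed consumed by [simulate_snp_traits()].
#' @return An object of class `snp_trait_config`.
#' @examples
#' snp_trait_config(m1 = 15)
#' @export
snp_trait_config <- function(n_subjects = 200, n_ld_blocks = 20,
                             snps_per_block = 5, ld_range = c(0.4, 0.9),
                             n_modules = 10, traits_per_module = 5,
                             corr_range = c(0.4, 0.9),
                             maf_range = c(0.2, 0.5), m1 = 15,
                             effect_size = 0.35, seed = NULL) {
  check_count_scalar(n_subjects, "n_subjects", minimum = 3)
  check_count_scalar(n_ld_blocks, "n_ld_blocks", minimum = 1)
  check_count_scalar(snps_per_block, "snps_per_block", minimum = 1)
  check_count_scalar(n_modules, "n_modules", minimum = 1)
  check_count_scalar(traits_per_module, "traits_per_module", minimum = 1)
  check_count_scalar(m1, "m1", minimum = 0)
  stopifnot(length(ld_range) == 2L, length(corr_range) == 2L,
            length(maf_range) == 2L)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  n_tests <- n_ld_blocks * snps_per_block * n_modules * traits_per_module
  if (m1 > n_tests) {
    stop("`m1` (", m1, ") exceeds the total number of SNP-trait pairs (",
         n_tests, ")", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, n_ld_blocks = n_ld_blocks,
         snps_per_block = snps_per_block, ld_range = ld_range,
         n_modules = n_modules, traits_per_module = traits_per_module,
         corr_range = corr_range, maf_range = maf_range, m1 = m1,
         effect_size = effect_size, seed = seed,
         n_snps = n_ld_blocks * snps_per_block,
         n_traits = n_modules * traits_per_module, n_tests = n_tests),
    class = "snp_trait_config"
  )
}

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation r,
# by one-dimensional numerical integration over z1.
bvn_lower_prob <- function(a, b, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  f <- function(z) {
    stats::pnorm((b - r * z) / sqrt(1 - r * r)) * stats::dnorm(z)
  }
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# Correlation between two Bernoulli allele indicators with success
# probabilities p and q whose latent normals have correlation r.
allele_corr_from_latent <- function(r, p, q) {
  p11 <- bvn_lower_prob(stats::qnorm(p), stats::qnorm(q), r)
  (p11 - p * q) / sqrt(p * (1 - p) * q * (1 - q))
}

# Latent correlation that produces a target allele (and hence genotype
# dosage) correlation at allele frequency p = q. The target must be
# achievable: as r -> 1 the allele correlation tends to 1 when p = q.
latent_from_target_ld <- function(target, p) {
  if (target <= 0) return(0)
  hi <- 1 - 1e-9
  f_hi <- allele_corr_from_latent(hi, p, p) - target
  if (f_hi < 0) {
    stop("infeasible composite-LD target ", format(target, digits = 4),
         " at allele frequency ", format(p, digits = 4),
         ": maximum achievable is ",
         format(allele_corr_from_latent(hi, p, p), digits = 4),
         call. = FALSE)
  }
  stats::uniroot(function(r) allele_corr_from_latent(r, p, p) - target,
                 lower = 0, upper = hi, tol = 1e-8)$root
}

# n x k matrix of correlated haplotype alleles: latent equicorrelated
# normals thresholded at qnorm(maf).
draw_haplotypes <- function(n, mafs, latent_rho) {
  k <- length(mafs)
  E <- matrix(stats::rnorm(n * k), n, k)
  Z <- if (latent_rho > 0) {
    sqrt(1 - latent_rho) * E + sqrt(latent_rho) * stats::rnorm(n)
  } else {
    E
  }
  sweep(Z, 2L, stats::qnorm(mafs), "<") * 1L
}

#' Simulate LD-block SNP genotypes and correlated trait modules
#'
#' Genotypes are sums of two independent haplotypes; each haplotype allele
#' is a thresholded latent Gaussian whose within-block latent correlation
#' is calibrated by root-finding so the genotype-dosage (composite-LD)
#' correlation at the block's mean allele frequency matches a target drawn
#' uniformly from `ld_range`. Traits are module-equicorrelated standard
#' normals with within-module correlation drawn uniformly from
#' `corr_range`. Each of the `m1` false-null SNP-trait pairs (chosen
#' uniformly at random) has `effect_size * genotype` added to its trait.
#'
#' @param config An [snp_trait_config()].
#' @return A list with `genotypes` (`n x n_snps` matrix of 0/1/2 dosages),
#'   `traits` (`n x n_traits` matrix), `truth_mask` (logical over SNP-trait
#'   pairs in column-major order, SNP index varying fastest), `block_ld`
#'   and `module_corr` (the drawn targets), `mafs`, and the `config` echo.
#' @examples
#' sim <- simulate_snp_traits(snp_trait_config(n_subjects = 50, seed = 1))
#' dim(sim$genotypes); sum(sim$truth_mask)
#' @export
simulate_snp_traits <- function(config) {
  stopifnot(inherits(config, "snp_trait_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  k <- config$snps_per_block

  block_ld <- stats::runif(config$n_ld_blocks, config$ld_range[1],
                           config$ld_range[2])
  mafs <- stats::runif(config$n_snps, config$maf_range[1],
                       config$maf_range[2])
  genotypes <- matrix(0L, n, config$n_snps)
  for (blk in seq_len(config$n_ld_blocks)) {
    cols <- (blk - 1L) * k + seq_len(k)
    latent <- latent_from_target_ld(block_ld[blk], mean(mafs[cols]))
    genotypes[, cols] <- draw_haplotypes(n, mafs[cols], latent) +
      draw_haplotypes(n, mafs[cols], latent)
  }

  module_corr <- stats::runif(config$n_modules, config$corr_range[1],
                              config$corr_range[2])
  traits <- matrix(NA_real_, n, config$n_traits)
  for (mod in seq_len(config$n_modules)) {
    cols <- (mod - 1L) * config$traits_per_module +
      seq_len(config$traits_per_module)
    rho <- module_corr[mod]
    E <- matrix(stats::rnorm(n * length(cols)), n, length(cols))
    traits[, cols] <- sqrt(1 - rho) * E + sqrt(rho) * stats::rnorm(n)
  }

  truth_mask <- logical(config$n_tests)
  if (config$m1 > 0) {
    pairs <- sample.int(config$n_tests, config$m1)
    truth_mask[pairs] <- TRUE
    snp_idx <- (pairs - 1L) %% config$n_snps + 1L
    trait_idx <- (pairs - 1L) %/% config$n_snps + 1L
    for (j in seq_along(pairs)) {
      traits[, trait_idx[j]] <- traits[, trait_idx[j]] +
        config$effect_size * genotypes[, snp_idx[j]]
    }
  }

  list(genotypes = genotypes, traits = traits, truth_mask = truth_mask,
       block_ld = block_ld, module_corr = module_corr, mafs = mafs,
       config = config)
}

#' Reconcile p-values with the simulation truth at a threshold
#'
#' Computes the outcome-table counts at a significance threshold: the total
#' positives `S`, the true discoveries `T` (positives among false nulls),
#' and the false discoveries `F = S - T`.
#'
#' @param p_values Numeric vector of per-test p-values.
#' @param truth_mask Logical vector of the same length; `TRUE` marks a
#'   false null hypothesis.
#' @param threshold Significance threshold.
#' @param strict Use strict `<` (default) or `<=`.
#' @return Named numeric vector `c(F = , T = , S = )`.
#' @examples
#' truth_counts(c(0.001, 0.02, 0.9), c(TRUE, FALSE, FALSE), 0.05)
#' @export
truth_counts <- function(p_values, truth_mask, threshold, strict = TRUE) {
  if (length(p_values) != length(truth_mask)) {
    stop("`p_values` (", length(p_values), ") and `truth_mask` (",
         length(truth_mask), ") lengths differ", call. = FALSE)
  }
  pos <- if (strict) p_values < threshold else p_values <= threshold
  S <- sum(pos)
  T_ <- sum(pos & truth_mask)
  c(F = S - T_, T = T_, S = S)
}
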