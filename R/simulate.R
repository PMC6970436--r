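# Synthetic genotype / expression / covariate data with known mediation
# structure, mirroring the generative form of the mediation model:
#   C = a1 + b1*G + loadings_C * H + e1
#   T = a3 + b3*C + b4*G + loadings_T * H + e3
# where H are hidden confounders shared by C and T. A truth table labels
# each trio as null (b3 = 0) or non-null, enabling calibration and power
# checks for every scheme and adjustment combination.

#' Simulation configuration
#'
#' @param n_samples Cohort size (default 300, a bulk-brain-cohort scale).
#' @param n_trios Number of trios to generate.
#' @param maf_range Minor-allele-frequency range, in (0, 0.5] (default
#'   0.05-0.5, matching the usual MAF >= 0.05 inclusion filter).
#' @param beta1 Cis eQTL effect of G on C (scalar or per-trio vector).
#' @param beta3 Mediation effect of C on T for non-null trios.
#' @param beta4 Direct effect of G on T.
#' @param fraction_null Fraction of trios with beta3 = 0.
#' @param n_hidden Number of hidden confounders shared by C and T.
#' @param loading_sd Standard deviation of hidden-confounder loadings
#'   (0 disables confounding).
#' @param noise_sd Residual standard deviation of C and T.
#' @param seed RNG seed.
#' @return A list of class \code{sim_config}.
#' @export
simulation_config <- function(n_samples = 300L, n_trios = 100L,
                              maf_range = c(0.05, 0.5), beta1 = 1,
                              beta3 = 0.5, beta4 = 0.3,
                              fraction_null = 0.5, n_hidden = 0L,
                              loading_sd = 0, noise_sd = 1, seed = 1L) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie in (0, 0.5]")
  }
  if (fraction_null < 0 || fraction_null > 1) {
    stop("fraction_null must be in [0, 1]")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_trios = as.integer(n_trios), maf_range = maf_range,
                 beta1 = beta1, beta3 = beta3, beta4 = beta4,
                 fraction_null = fraction_null,
                 n_hidden = as.integer(n_hidden), loading_sd = loading_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate additive genotypes under Hardy-Weinberg equilibrium
#'
#' Per variant, draws an allele frequency uniformly from \code{maf_range}
#' and genotypes as Binomial(2, f); monomorphic draws are regenerated.
#'
#' @param n_samples Number of samples.
#' @param n_variants Number of variants.
#' @param maf_range Allele-frequency range in (0, 0.5].
#' @return Integer matrix, samples x variants, dosages 0/1/2, with
#'   column names \code{v1..} and row names \code{s1..}.
#' @export
simulate_genotypes <- function(n_samples, n_variants,
                               maf_range = c(0.05, 0.5)) {
  g <- matrix(0L, n_samples, n_variants,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("v", seq_len(n_variants))))
  for (j in seq_len(n_variants)) {
    repeat {
      f <- stats::runif(1, maf_range[1], maf_range[2])
      gj <- stats::rbinom(n_samples, 2L, f)
      if (length(unique(gj)) >= 2L) break
    }
    g[, j] <- gj
  }
  g
}

#' Simulate trio data with known mediation structure
#'
#' Generates genotypes, cis and trans expression, optional hidden
#' confounders, and a truth table. Gene ids are \code{cisN} / \code{trnN}
#' and variant ids \code{vN} for trio N.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{genotypes} (samples x trios),
#'   \code{expression} (2*n_trios genes x samples), \code{covariates}
#'   (samples x n_hidden matrix of the true hidden factors; also the
#'   natural user-supplied pool), \code{trios} (data frame of ids), and
#'   \code{truth} (per-trio beta1/beta3/beta4 and \code{is_null}).
#' @export
simulate_trio_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  nt <- config$n_trios
  geno <- simulate_genotypes(n, nt, config$maf_range)
  b1 <- rep_len(config$beta1, nt)
  b3 <- rep_len(config$beta3, nt)
  b4 <- rep_len(config$beta4, nt)
  is_null <- seq_len(nt) <= round(config$fraction_null * nt)
  b3[is_null] <- 0
  H <- if (config$n_hidden > 0) {
    matrix(stats::rnorm(n * config$n_hidden), n, config$n_hidden,
           dimnames = list(rownames(geno),
                           paste0("H", seq_len(config$n_hidden))))
  } else {
    matrix(numeric(0), n, 0)
  }
  expr <- matrix(NA_real_, 2L * nt, n,
                 dimnames = list(c(paste0("cis", seq_len(nt)),
                                   paste0("trn", seq_len(nt))),
                                 rownames(geno)))
  lc <- lt <- matrix(0, nt, max(1L, config$n_hidden))
  if (config$n_hidden > 0 && config$loading_sd > 0) {
    lc <- matrix(stats::rnorm(nt * config$n_hidden, sd = config$loading_sd),
                 nt, config$n_hidden)
    lt <- matrix(stats::rnorm(nt * config$n_hidden, sd = config$loading_sd),
                 nt, config$n_hidden)
  }
  for (i in seq_len(nt)) {
    g <- geno[, i]
    hc <- if (config$n_hidden > 0) as.vector(H %*% lc[i, ]) else 0
    ht <- if (config$n_hidden > 0) as.vector(H %*% lt[i, ]) else 0
    C <- b1[i] * g + hc + stats::rnorm(n, sd = config$noise_sd)
    T_ <- b3[i] * C + b4[i] * g + ht + stats::rnorm(n, sd = config$noise_sd)
    expr[i, ] <- C
    expr[nt + i, ] <- T_
  }
  list(genotypes = geno,
       expression = expr,
       covariates = H,
       trios = data.frame(variant_id = colnames(geno),
                          cis_gene_id = paste0("cis", seq_len(nt)),
                          trans_gene_id = paste0("trn", seq_len(nt)),
                          stringsAsFactors = FALSE),
       truth = data.frame(variant_id = colnames(geno),
                          beta1 = b1, beta3 = b3, beta4 = b4,
                          is_null = is_null, stringsAsFactors = FALSE))
}
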