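# Within-genotype-group permutation schemes.
#
# Shuffling the cis-gene expression C only among samples that share a
# genotype class (AA/AB/BB, i.e. dosage 0/1/2) breaks any mediation effect
# of C on T while preserving the cis- and trans-eQTL associations with the
# variant. The resulting absolute statistics |z0| form the permutation null
# against which the nominal statistic is compared.

#' Permutation plan for one mediation run
#'
#' @param n_perm Maximum number of permutations N (positive integer).
#' @param alpha Pruning significance level in (0, 1); the adaptive scheme
#'   stops once K = floor(alpha * N) (at least 1) null statistics reach the
#'   nominal statistic.
#' @param scheme One of \code{"fixed"}, \code{"adaptive"}, \code{"gpd"},
#'   \code{"adaptive+gpd"}.
#' @param seed Base RNG seed for the run.
#' @return An object of class \code{permutation_plan} with fields
#'   \code{n_perm}, \code{alpha}, \code{K}, \code{scheme}, \code{seed}.
#' @export
permutation_plan <- function(n_perm = 10000L, alpha = 0.05,
                             scheme = c("adaptive+gpd", "fixed", "adaptive",
                                        "gpd"),
                             seed = 1L) {
  scheme <- match.arg(scheme)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  K <- max(1L, as.integer(floor(alpha * n_perm)))
  if (K >= n_perm) stop("pruning threshold K must be smaller than n_perm")
  structure(list(n_perm = n_perm, alpha = alpha, K = K, scheme = scheme,
                 seed = as.integer(seed)),
            class = "permutation_plan")
}

#' Shuffle expression values within each genotype group
#'
#' Independently permutes the values of \code{expr} within each genotype
#' stratum (dosage 0, 1, 2). The multiset of values per stratum is preserved
#' exactly; strata of size one are fixed points. Uses the current R RNG
#' state.
#'
#' @param expr Numeric expression vector.
#' @param g Genotype dosages aligned with \code{expr}.
#' @return Permuted expression vector.
#' @export
permute_within_genotype <- function(expr, g) {
  check_aligned(length(expr), g)
  out <- expr
  for (idx in split(seq_along(g), g)) {
    if (length(idx) > 1L) out[idx] <- expr[idx[sample.int(length(idx))]]
  }
  out
}

# Precomputed per-trio context for fast permutation statistics via the
# partialled-out (Frisch-Waugh) form of the mediation model: with
# X = [1, G, Cov] and M the residual maker of X, the t-statistic of C in
# T ~ 1 + C + G + Cov equals the slope t-statistic of (M T) ~ (M C) with
# n - ncol(X) - 1 degrees of freedom.
perm_context <- function(g, c_expr, t_expr, covariates = NULL) {
  n <- length(g)
  check_aligned(n, c_expr, t_expr)
  X <- cbind(1, as.numeric(g))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.matrix(covariates)
    check_aligned(n, covariates)
    sds <- apply(covariates, 2, stats::sd)
    X <- cbind(X, covariates[, sds > 0, drop = FALSE])
  }
  qrX <- qr(X)
  dof <- n - qrX$rank - 1L
  if (dof <= 0) stop("non-positive degrees of freedom in mediation model")
  mt <- qr.resid(qrX, as.numeric(t_expr))
  list(qrX = qrX, mt = mt, tt = sum(mt^2), dof = dof, n = n,
       strata = split(seq_len(n), g), c_expr = as.numeric(c_expr))
}

# Absolute mediation t-statistics for a matrix of (permuted) C columns.
perm_batch_stats <- function(ctx, cmat) {
  mc <- qr.resid(ctx$qrX, cmat)
  cc <- colSums(mc^2)
  bn <- colSums(mc * ctx$mt)
  rss <- ctx$tt - bn^2 / cc
  rss[rss < 0] <- 0
  z <- bn / sqrt(cc) / sqrt(rss / ctx$dof)
  z[cc <= 0] <- NaN
  abs(z)
}

# Draw one batch of within-stratum permutations of C as a matrix (n x b).
perm_batch_draw <- function(ctx, b) {
  cmat <- matrix(ctx$c_expr, nrow = ctx$n, ncol = b)
  for (idx in ctx$strata) {
    m <- length(idx)
    if (m > 1L) {
      for (j in seq_len(b)) cmat[idx, j] <- ctx$c_expr[idx[sample.int(m)]]
    }
  }
  cmat
}

#' Permutation null statistics for one trio
#'
#' Runs \code{n} independent within-genotype permutations of the cis
#' expression and records the absolute mediation statistic of each permuted
#' dataset (covariates and the trans expression are never permuted).
#' Permutations yielding a non-finite statistic are dropped as recorded
#' failures; more than 10 percent failures aborts the trio.
#'
#' @param g Genotype dosages (0/1/2), at least two classes.
#' @param c_expr Cis expression.
#' @param t_expr Trans expression.
#' @param covariates Optional covariate matrix.
#' @param n Number of permutations (>= 1).
#' @param batch_size Internal batch size (default 100).
#' @return An object of class \code{null_stats}: list with \code{values}
#'   (absolute statistics), \code{n_executed}, \code{n_failed}.
#' @export
null_statistics <- function(g, c_expr, t_expr, covariates = NULL, n,
                            batch_size = 100L) {
  if (n < 1L) stop("n must be at least 1")
  validate_genotype(g)
  ctx <- perm_context(g, c_expr, t_expr, covariates)
  vals <- numeric(0)
  failed <- 0L
  while (length(vals) < n) {
    b <- min(batch_size, n - length(vals))
    z <- perm_batch_stats(ctx, perm_batch_draw(ctx, b))
    bad <- !is.finite(z)
    failed <- failed + sum(bad)
    vals <- c(vals, z[!bad])
    if (failed > 0.1 * n) {
      stop("more than 10% of permutations failed for this trio")
    }
  }
  structure(list(values = vals[seq_len(n)], n_executed = as.integer(n),
                 n_failed = failed),
            class = "null_stats")
}

#' Fixed-scheme empirical p-value
#'
#' With M the number of null statistics at least as large as \code{|z|}
#' (ties counted as exceedances, the conservative choice), the empirical
#' p-value is (M + 1) / (N + 1); the pseudo-count keeps the estimate away
#' from zero and bounds it below by 1/(N + 1).
#'
#' @param z_abs Absolute nominal mediation statistic.
#' @param null_stats A \code{null_stats} object or numeric vector of
#'   absolute null statistics.
#' @return An object of class \code{empirical_p}: list with \code{p_value},
#'   \code{M}, \code{n_executed}, \code{scheme = "fixed"},
#'   \code{early_stopped = FALSE}.
#' @export
p_fixed <- function(z_abs, null_stats) {
  z0 <- as_null_values(null_stats)
  N <- length(z0)
  if (N < 1L) stop("need at least one null statistic")
  M <- sum(z0 >= z_abs)
  structure(list(p_value = (M + 1) / (N + 1), M = as.integer(M),
                 n_executed = as.integer(N), scheme = "fixed",
                 early_stopped = FALSE),
            class = "empirical_p")
}

#' @export
print.empirical_p <- function(x, ...) {
  cat(sprintf("empirical p = %.4g (%s scheme, M = %d, permutations = %d%s)\n",
              x$p_value, x$scheme, x$M, x$n_executed,
              if (isTRUE(x$early_stopped)) ", early-stopped" else ""))
  invisible(x)
}

#' Adaptive-scheme empirical p-value with early stopping
#'
#' Draws permutations sequentially (in internal batches, with the stopping
#' condition located element-wise inside the batch) and stops the first time
#' the exceedance count reaches the pruning threshold K or the permutation
#' budget N is exhausted. With Gamma permutations executed and M exceedances
#' observed, the p-value is min(K+1, M+1) / min(Gamma+1, N+1). When no early
#' stop occurs this reduces exactly to the fixed-scheme value on the same
#' null statistics.
#'
#' @param g,c_expr,t_expr,covariates As in \code{\link{null_statistics}}.
#' @param z_abs Absolute nominal mediation statistic.
#' @param plan A \code{\link{permutation_plan}} (supplies N, alpha, K).
#' @param batch_size Internal batch size (default 100).
#' @return List with \code{p} (an \code{empirical_p} with
#'   \code{scheme = "adaptive"}) and \code{null} (the \code{null_stats}
#'   actually collected, reusable for GPD tail modeling).
#' @export
p_adaptive <- function(z_abs, g, c_expr, t_expr, covariates = NULL, plan,
                       batch_size = 100L) {
  stopifnot(inherits(plan, "permutation_plan"))
  validate_genotype(g)
  N <- plan$n_perm
  K <- plan$K
  ctx <- perm_context(g, c_expr, t_expr, covariates)
  vals <- numeric(0)
  M <- 0L
  failed <- 0L
  early <- FALSE
  while (length(vals) < N) {
    b <- min(batch_size, N - length(vals))
    z <- perm_batch_stats(ctx, perm_batch_draw(ctx, b))
    bad <- !is.finite(z)
    failed <- failed + sum(bad)
    if (failed > 0.1 * N) {
      stop("more than 10% of permutations failed for this trio")
    }
    z <- z[!bad]
    cum_m <- M + cumsum(z >= z_abs)
    hit <- which(cum_m >= K)
    if (length(hit) > 0) {
      stop_at <- hit[1L]
      vals <- c(vals, z[seq_len(stop_at)])
      M <- cum_m[stop_at]
      early <- length(vals) < N
      break
    }
    vals <- c(vals, z)
    M <- if (length(cum_m)) cum_m[length(cum_m)] else M
  }
  gamma <- length(vals)
  p <- min(K + 1, M + 1) / min(gamma + 1, N + 1)
  list(
    p = structure(list(p_value = p, M = as.integer(M),
                       n_executed = as.integer(gamma), scheme = "adaptive",
                       early_stopped = early),
                  class = "empirical_p"),
    null = structure(list(values = vals, n_executed = as.integer(gamma),
                          n_failed = failed),
                     class = "null_stats"))
}

#' Hybrid fixed/GPD p-value with tail-routing
#'
#' Routing rule on a completed permutation null: when fewer than
#' \code{Gamma * alpha_gpd} null statistics reach the nominal statistic, the
#' statistic is far enough in the tail for the generalized Pareto
#' approximation (\code{\link{fit_tail}} + \code{\link{p_gpd}}), which can
#' report p-values below the empirical floor 1/(N+1); otherwise, or when the
#' tail fit fails, the fixed-scheme value is returned.
#'
#' @param z_abs Absolute nominal mediation statistic.
#' @param null_stats Completed \code{null_stats}.
#' @param alpha_gpd Tail-routing level (default 0.01).
#' @param gof_alpha Goodness-of-fit gate passed to \code{\link{fit_tail}}.
#' @return An \code{empirical_p} with extra fields: \code{p_source}
#'   (\code{"fixed"}, \code{"gpd"}, or \code{"gpd_failed"}), \code{gof_p},
#'   \code{beyond_support}, \code{p_upper_bound}.
#' @export
p_hybrid <- function(z_abs, null_stats, alpha_gpd = 0.01, gof_alpha = 0.05) {
  z0 <- as_null_values(null_stats)
  N <- length(z0)
  fixed <- p_fixed(z_abs, z0)
  M <- fixed$M
  out <- fixed
  out$p_source <- "fixed"
  out$gof_p <- NA_real_
  out$beyond_support <- FALSE
  out$p_upper_bound <- fixed$p_value
  if (M >= N * alpha_gpd || N < 20L) return(out)
  fit <- fit_tail(z0, gof_alpha = gof_alpha)
  if (!isTRUE(fit$converged) || z_abs <= fit$t) {
    out$p_source <- "gpd_failed"
    return(out)
  }
  gp <- p_gpd(z_abs, z0, fit)
  out$p_value <- gp$p_value
  out$scheme <- "gpd"
  out$p_source <- "gpd"
  out$gof_p <- fit$gof_p
  out$beyond_support <- gp$beyond_support
  out$p_upper_bound <- gp$p_upper_bound
  out
}
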