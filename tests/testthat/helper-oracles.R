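# Shared fixtures and independent oracles for the test suite.

# All permutations of a vector (recursive), for exhaustive enumeration
# oracles on tiny inputs.
perms_all <- function(v) {
  n <- length(v)
  if (n <= 1L) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- perms_all(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# Exhaustive within-stratum permutation p-value: the proportion of all
# distinct within-genotype rearrangements of C whose absolute mediation
# statistic reaches |z|. Independent of the package's Monte Carlo machinery
# apart from mediation_statistic itself.
exact_perm_p <- function(g, c_expr, t_expr, covariates = NULL) {
  z_obs <- abs(mediation_statistic(g, c_expr, t_expr, covariates)$z)
  strata <- split(seq_along(g), g)
  per_stratum <- lapply(strata, function(idx) perms_all(idx))
  combos <- Reduce(function(a, b) {
    out <- NULL
    for (i in seq_len(nrow(a))) {
      out <- rbind(out, cbind(matrix(a[i, ], nrow(b), ncol(a), byrow = TRUE), b))
    }
    out
  }, per_stratum)
  pos <- unlist(strata)
  hits <- 0L
  for (r in seq_len(nrow(combos))) {
    cp <- c_expr
    cp[pos] <- c_expr[combos[r, ]]
    z0 <- abs(mediation_statistic(g, cp, t_expr, covariates)$z)
    if (z0 >= z_obs) hits <- hits + 1L
  }
  hits / nrow(combos)
}

# Closed-form normal-equations OLS oracle (matrix inverse), independent of
# the package's QR path.
ols_oracle <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- as.vector(xtx_inv %*% t(X) %*% y)
  res <- y - X %*% beta
  dof <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / dof
  list(beta = beta, se = sqrt(sigma2 * diag(xtx_inv)), dof = dof)
}

# Small deterministic trio with a real mediation signal.
toy_trio <- function(n = 60, beta3 = 0.8, seed = 42) {
  set.seed(seed)
  g <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  c_expr <- 0.9 * g + rnorm(n)
  t_expr <- beta3 * c_expr + 0.3 * g + rnorm(n)
  list(g = g, c = c_expr, t = t_expr)
}

# Draw GPD samples in the bounded-support-positive-k convention.
rgpd <- function(n, a, k) gpd_quantile(runif(n), a, k)

# Per-trio deterministic seed, mirroring the pipeline's substream derivation.
trio_seed_for_test <- function(base_seed, index) {
  triomed:::trio_seed(base_seed, index)
}
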