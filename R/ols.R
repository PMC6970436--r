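# Least-squares machinery for the three mediation regressions:
#   C = a1 + b1*G           + Cov*g1 + e1   (cis association)
#   T = a2 + b2*G           + Cov*g2 + e2   (trans association)
#   T = a3 + b3*C + b4*G    + Cov*g3 + e3   (mediation model)
# The nominal mediation statistic is z = b3 / se(b3); H0: b3 = 0.

#' Ordinary least squares with intercept, collinearity pruning and t-statistics
#'
#' Shared QR-based solver behind the cis, trans and mediation regressions.
#' Zero-variance covariate columns are dropped with a warning; if the design
#' is still rank deficient, columns are pruned greedily left to right (first
#' occurrence kept) with a warning. A condition-number warning is emitted
#' above 1e10.
#'
#' @param response Numeric response vector.
#' @param design_columns Named list of numeric predictor vectors (the terms
#'   of scientific interest, e.g. genotype and/or cis expression).
#' @param covariates Optional numeric matrix (samples x covariates) of
#'   nuisance terms, or \code{NULL}.
#' @return An object of class \code{linear_fit}: list with
#'   \code{coefficients}, \code{standard_errors}, \code{t_statistics},
#'   \code{p_values} (two-sided, t with \code{dof} degrees of freedom),
#'   \code{residuals}, \code{n_samples}, \code{dof}, \code{dropped}
#'   (names of pruned columns).
#' @export
fit_ols <- function(response, design_columns, covariates = NULL) {
  y <- as.numeric(response)
  n <- length(y)
  if (is.null(names(design_columns)) || any(names(design_columns) == "")) {
    names(design_columns) <- paste0("x", seq_along(design_columns))
  }
  for (v in design_columns) check_aligned(n, v)
  X <- do.call(cbind, design_columns)
  colnames(X) <- names(design_columns)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.matrix(covariates)
    check_aligned(n, covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    sds <- apply(covariates, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance covariate column(s): ",
              paste(colnames(covariates)[sds == 0], collapse = ", "))
      covariates <- covariates[, sds > 0, drop = FALSE]
    }
    if (ncol(covariates) > 0) X <- cbind(X, covariates)
  }
  X <- cbind(`(Intercept)` = 1, X)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in model inputs; remove missing data first")
  }

  dropped <- character(0)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- 1L
    for (j in 2:ncol(X)) {
      cand <- c(keep, j)
      if (qr(X[, cand, drop = FALSE])$rank == length(cand)) {
        keep <- cand
      } else {
        dropped <- c(dropped, colnames(X)[j])
      }
    }
    warning("rank-deficient design; dropped collinear column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("unestimable model")
  }
  p <- ncol(X)
  dof <- n - p
  if (dof <= 0) stop("non-positive degrees of freedom: n = ", n, ", p = ", p)

  R <- qr.R(qrX)[, order(qrX$pivot), drop = FALSE]
  kap <- kappa(R, exact = FALSE)
  if (is.finite(kap) && kap > 1e10) {
    warning("ill-conditioned design (condition number ~ ",
            format(kap, digits = 3), ")")
  }
  beta <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  rss <- sum(res^2)
  sigma2 <- rss / dof
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(xtx_inv))[order(qrX$pivot)]
  names(se) <- names(beta)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), dof)

  structure(list(coefficients = beta, standard_errors = se,
                 t_statistics = tstat, p_values = pval, residuals = res,
                 n_samples = n, dof = dof, dropped = dropped,
                 sigma2 = sigma2),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear fit: n =", x$n_samples, ", dof =", x$dof, "\n")
  print(data.frame(estimate = x$coefficients, se = x$standard_errors,
                   t = x$t_statistics, p = x$p_values))
  invisible(x)
}

#' Cis association between an eQTL and its local gene
#'
#' Fits \code{C ~ 1 + G + Cov} and reports the genotype effect b1 with its
#' standard error and two-sided p-value.
#'
#' @param g Additive genotype dosages (0/1/2).
#' @param c_expr Cis-gene expression values, aligned with \code{g}.
#' @param covariates Optional covariate matrix.
#' @return A \code{linear_fit}; the genotype row is named \code{"G"}.
#' @export
cis_association <- function(g, c_expr, covariates = NULL) {
  validate_genotype(g)
  fit_ols(c_expr, list(G = as.numeric(g)), covariates)
}

#' Trans association between an eQTL and a distant gene
#'
#' Fits \code{T ~ 1 + G + Cov}; the genotype effect is b2.
#'
#' @param g Additive genotype dosages (0/1/2).
#' @param t_expr Trans-gene expression values.
#' @param covariates Optional covariate matrix.
#' @return A \code{linear_fit}.
#' @export
trans_association <- function(g, t_expr, covariates = NULL) {
  validate_genotype(g)
  fit_ols(t_expr, list(G = as.numeric(g)), covariates)
}

#' Nominal mediation statistic for one trio
#'
#' Fits the mediation model \code{T ~ 1 + C + G + Cov} and returns
#' \code{z = b3 / se(b3)}, the t-statistic of the cis-expression term after
#' conditioning on genotype and covariates. The sign of \code{z} is
#' preserved; schemes compare absolute values. A vanishing standard error
#' (perfectly collinear C and T) is flagged as degenerate and \code{|z|}
#' capped at 1e8 instead of returning infinity.
#'
#' @param g Additive genotype dosages (0/1/2), at least two classes.
#' @param c_expr Cis-gene expression.
#' @param t_expr Trans-gene expression.
#' @param covariates Optional covariate matrix.
#' @return List with \code{z}, \code{beta} (b3), \code{se}, \code{dof},
#'   \code{p_nominal} (two-sided), \code{degenerate}, and the full
#'   \code{fit}.
#' @export
mediation_statistic <- function(g, c_expr, t_expr, covariates = NULL) {
  validate_genotype(g)
  fit <- fit_ols(t_expr, list(C = as.numeric(c_expr), G = as.numeric(g)),
                 covariates)
  beta <- unname(fit$coefficients["C"])
  se <- unname(fit$standard_errors["C"])
  z <- beta / se
  degenerate <- !is.finite(z) || abs(z) > 1e8
  if (degenerate) z <- sign(beta) * 1e8
  list(z = z, beta = beta, se = se, dof = fit$dof,
       p_nominal = 2 * stats::pt(-min(abs(z), 1e8), fit$dof),
       degenerate = degenerate, fit = fit)
}
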