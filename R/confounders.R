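# Confounder adjustment: a pool of hidden-covariate candidates (expression
# principal components or user-supplied factors such as SVs or PEER
# factors), used either wholesale ("fixed" strategy) or selected per trio
# by their correlation with the two expression traits ("adaptive"
# strategy).

#' Build a hidden-covariate pool from expression principal components
#'
#' Column-centered PCA of the expression matrix over samples; the top
#' \code{n_pcs} score vectors become candidate hidden covariates, with a
#' deterministic sign convention (the largest-magnitude gene loading of each
#' component is made positive).
#'
#' @param expression_matrix Numeric matrix, genes x samples.
#' @param n_pcs Number of components to keep (default 30, capped at
#'   n_samples - 1).
#' @return An object of class \code{confounder_pool}: list with
#'   \code{components} (samples x n_pcs score matrix),
#'   \code{explained_variance} (fractions), \code{source = "pca_auto"}.
#' @export
build_pc_pool <- function(expression_matrix, n_pcs = 30L) {
  x <- t(as.matrix(expression_matrix))   # samples x genes
  n <- nrow(x)
  if (any(!is.finite(x))) stop("expression matrix must be complete-case")
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(components = scores,
                 explained_variance = ev[seq_len(k)],
                 source = "pca_auto"),
            class = "confounder_pool")
}

#' Wrap user-supplied hidden covariates as a pool
#'
#' @param components Numeric matrix, samples x factors (e.g. surrogate
#'   variables or PEER factors computed upstream).
#' @return A \code{confounder_pool} with \code{source = "user_supplied"}.
#' @export
as_confounder_pool <- function(components) {
  components <- as.matrix(components)
  if (is.null(colnames(components))) {
    colnames(components) <- paste0("H", seq_len(ncol(components)))
  }
  structure(list(components = components,
                 explained_variance = rep(NA_real_, ncol(components)),
                 source = "user_supplied"),
            class = "confounder_pool")
}

#' Per-trio adaptive selection of hidden covariates
#'
#' Tests the Pearson correlation of every pooled component against the cis
#' and the trans expression trait, adjusts the 2 * n_pcs p-values jointly by
#' Benjamini-Hochberg, and selects a component if it is significant for
#' either trait at the given FDR. Selection is deterministic (no RNG) and
#' returned in pool order.
#'
#' @param pool A \code{confounder_pool}.
#' @param c_expr Cis expression vector.
#' @param t_expr Trans expression vector.
#' @param fdr Selection FDR level (default 0.05).
#' @return Integer vector of selected column indices (possibly empty).
#' @export
select_confounders <- function(pool, c_expr, t_expr, fdr = 0.05) {
  stopifnot(inherits(pool, "confounder_pool"))
  comp <- pool$components
  check_aligned(nrow(comp), c_expr, t_expr)
  k <- ncol(comp)
  if (k == 0) return(integer(0))
  pvals <- numeric(2 * k)
  for (j in seq_len(k)) {
    pvals[j] <- stats::cor.test(comp[, j], c_expr)$p.value
    pvals[k + j] <- stats::cor.test(comp[, j], t_expr)$p.value
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  which(adj[seq_len(k)] <= fdr | adj[k + seq_len(k)] <= fdr)
}

#' Assemble the covariate matrix for one trio
#'
#' Fixed strategy: known covariates plus the whole pool. Adaptive strategy:
#' known covariates plus the components selected per trio by
#' \code{\link{select_confounders}}.
#'
#' @param known_covariates Numeric matrix (samples x covariates) or
#'   \code{NULL}.
#' @param pool Optional \code{confounder_pool} (required for adaptive mode).
#' @param mode \code{"fixed"} or \code{"adaptive"}.
#' @param c_expr,t_expr Trio expression vectors (adaptive mode only).
#' @param fdr Selection FDR for adaptive mode.
#' @return Numeric covariate matrix (possibly zero columns), with column
#'   names preserved; duplicate names raise an error.
#' @export
assemble_cov <- function(known_covariates = NULL, pool = NULL,
                         mode = c("fixed", "adaptive"),
                         c_expr = NULL, t_expr = NULL, fdr = 0.05) {
  mode <- match.arg(mode)
  parts <- list()
  if (!is.null(known_covariates) && NCOL(known_covariates) > 0) {
    kc <- as.matrix(known_covariates)
    if (is.null(colnames(kc))) colnames(kc) <- paste0("cov", seq_len(ncol(kc)))
    parts$known <- kc
  }
  if (!is.null(pool) && ncol(pool$components) > 0) {
    if (mode == "fixed") {
      parts$hidden <- pool$components
    } else {
      if (is.null(c_expr) || is.null(t_expr)) {
        stop("adaptive mode needs c_expr and t_expr for per-trio selection")
      }
      sel <- select_confounders(pool, c_expr, t_expr, fdr = fdr)
      if (length(sel) > 0) {
        parts$hidden <- pool$components[, sel, drop = FALSE]
      }
    }
  } else if (mode == "adaptive" && is.null(pool)) {
    stop("adaptive mode requires a confounder pool")
  }
  if (length(parts) == 0) {
    return(matrix(numeric(0), nrow = if (!is.null(c_expr)) length(c_expr) else 0,
                  ncol = 0))
  }
  out <- do.call(cbind, unname(parts))
  if (anyDuplicated(colnames(out))) {
    stop("duplicate covariate names after assembly: ",
         paste(unique(colnames(out)[duplicated(colnames(out))]),
               collapse = ", "))
  }
  out
}
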