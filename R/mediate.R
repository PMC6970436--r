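# End-to-end mediation run: per-trio nominal statistic, permutation scheme
# routing, and gene-pair-level q-values.

#' Run mediation analysis over a set of trios
#'
#' For every trio (variant L, cis-gene C, trans-gene T): aligns the inputs
#' on shared samples (complete-case per trio), assembles the covariate
#' matrix under the chosen adjustment strategy, computes the nominal
#' mediation statistic z = b3/se from T ~ 1 + C + G + Cov, and adjusts it
#' for the multiple correlated variants by the chosen permutation scheme:
#' \describe{
#'   \item{fixed}{exactly \code{n_perm} within-genotype permutations,
#'     p = (M+1)/(N+1).}
#'   \item{adaptive}{sequential permutations pruned once
#'     K = floor(alpha*N) exceedances are seen,
#'     p = min(K+1, M+1)/min(Gamma+1, N+1).}
#'   \item{gpd}{full \code{n_perm} permutations, then generalized Pareto
#'     tail approximation when the statistic is extreme
#'     (M < Gamma * alpha_gpd), else the fixed value.}
#'   \item{adaptive+gpd}{adaptive scheme first; trios that exhaust the
#'     budget without pruning are routed through the GPD tail gate.}
#' }
#' Per-trio RNG substreams are derived deterministically from \code{seed}
#' and the trio index, so results are reproducible and independent of
#' which other trios are in the run.
#'
#' @param genotypes Numeric matrix, samples x variants (dosage 0/1/2),
#'   with dimnames.
#' @param expression Numeric matrix, genes x samples, with dimnames.
#' @param trios Data frame with \code{variant_id}, \code{cis_gene_id},
#'   \code{trans_gene_id}.
#' @param covariates Optional known-covariate matrix, samples x covariates.
#' @param scheme Permutation scheme (see above).
#' @param n_perm Permutation budget N (default 10000).
#' @param alpha Adaptive pruning level (default 0.05).
#' @param alpha_gpd GPD tail-routing level (default 0.01).
#' @param adjust Confounder strategy, \code{"fixed"} (known covariates plus
#'   any supplied pool wholesale) or \code{"adaptive"} (per-trio selection
#'   from the pool).
#' @param pool Optional \code{confounder_pool}; for
#'   \code{adjust = "adaptive"} with no pool supplied, the first
#'   \code{n_pcs} expression PCs are used.
#' @param n_pcs Pool size when building the PC pool automatically.
#' @param select_fdr FDR level of the per-trio confounder selection.
#' @param seed Base RNG seed.
#' @param qvalues Append Storey-Tibshirani q-values across unique gene
#'   pairs (computed on the best trio per pair, minimum permutation p)?
#' @param verify Re-test the cis (b1) and trans (b2) associations and
#'   record their p-values per trio (off by default; candidate screening is
#'   normally trusted from the upstream association tables).
#' @param progress_every Emit a progress message every this many trios
#'   (0 disables).
#' @return Data frame with one row per trio: ids, \code{n_used}, \code{z},
#'   \code{p_nominal}, \code{scheme}, \code{n_perm_executed}, \code{M},
#'   \code{p_perm}, \code{p_source} (fixed / adaptive / gpd / gpd_failed),
#'   \code{gof_p}, \code{beyond_support}, \code{p_upper_bound},
#'   \code{q_value} (NA for trios not selected as best-per-pair when
#'   \code{qvalues = TRUE}), \code{error}.
#' @export
run_mediate <- function(genotypes, expression, trios, covariates = NULL,
                        scheme = c("adaptive+gpd", "fixed", "adaptive",
                                   "gpd"),
                        n_perm = 10000L, alpha = 0.05, alpha_gpd = 0.01,
                        adjust = c("fixed", "adaptive"), pool = NULL,
                        n_pcs = 30L, select_fdr = 0.05, seed = 1L,
                        qvalues = TRUE, verify = FALSE,
                        progress_every = 1000L) {
  scheme <- match.arg(scheme)
  adjust <- match.arg(adjust)
  trios <- as.data.frame(trios)
  plan <- permutation_plan(n_perm, alpha, scheme, seed)
  if (adjust == "adaptive" && is.null(pool)) {
    pool <- build_pc_pool(expression, n_pcs = min(n_pcs,
                                                  ncol(expression) - 1L))
  }

  nt <- nrow(trios)
  res <- data.frame(
    variant_id = trios$variant_id, cis_gene_id = trios$cis_gene_id,
    trans_gene_id = trios$trans_gene_id, n_used = NA_integer_,
    z = NA_real_, p_nominal = NA_real_,
    cis_p = NA_real_, trans_p = NA_real_,
    scheme = scheme, n_perm_executed = NA_integer_, M = NA_integer_,
    p_perm = NA_real_, p_source = NA_character_, gof_p = NA_real_,
    beyond_support = FALSE, p_upper_bound = NA_real_,
    q_value = NA_real_, error = NA_character_,
    stringsAsFactors = FALSE)
  if (!verify) res$cis_p <- res$trans_p <- NULL

  samples <- Reduce(intersect, list(rownames(genotypes), colnames(expression),
                                    if (!is.null(covariates)) rownames(covariates) else rownames(genotypes)))
  if (length(samples) == 0) stop("no shared samples across inputs")

  n_routed <- c(fixed = 0L, adaptive = 0L, gpd = 0L, gpd_failed = 0L)
  for (i in seq_len(nt)) {
    row <- trios[i, ]
    out <- tryCatch({
      if (!row$variant_id %in% colnames(genotypes)) {
        stop("variant '", row$variant_id, "' not in genotype matrix")
      }
      for (gid in c(row$cis_gene_id, row$trans_gene_id)) {
        if (!gid %in% rownames(expression)) {
          stop("gene '", gid, "' not in expression matrix")
        }
      }
      g <- genotypes[samples, row$variant_id]
      ce <- expression[row$cis_gene_id, samples]
      te <- expression[row$trans_gene_id, samples]
      kc <- if (!is.null(covariates)) {
        covariates[samples, , drop = FALSE]
      } else NULL
      pl <- if (!is.null(pool)) pool$components[samples, , drop = FALSE] else NULL
      keep <- is.finite(g) & is.finite(ce) & is.finite(te)
      if (!is.null(kc)) keep <- keep & apply(is.finite(kc), 1, all)
      g <- g[keep]; ce <- ce[keep]; te <- te[keep]
      kc <- if (!is.null(kc)) kc[keep, , drop = FALSE] else NULL
      sub_pool <- if (!is.null(pl)) {
        as_confounder_pool(pl[keep, , drop = FALSE])
      } else NULL
      validate_genotype(g)
      cov <- assemble_cov(kc, sub_pool, mode = adjust, c_expr = ce,
                          t_expr = te, fdr = select_fdr)

      set.seed(trio_seed(seed, i))
      med <- mediation_statistic(g, ce, te, cov)
      z_abs <- abs(med$z)
      ep <- switch(
        scheme,
        fixed = p_fixed(z_abs, null_statistics(g, ce, te, cov, n = n_perm)),
        adaptive = p_adaptive(z_abs, g, ce, te, cov, plan)$p,
        gpd = p_hybrid(z_abs, null_statistics(g, ce, te, cov, n = n_perm),
                       alpha_gpd = alpha_gpd),
        `adaptive+gpd` = {
          ad <- p_adaptive(z_abs, g, ce, te, cov, plan)
          if (ad$p$early_stopped) ad$p
          else p_hybrid(z_abs, ad$null, alpha_gpd = alpha_gpd)
        })
      src <- if (!is.null(ep$p_source)) ep$p_source else ep$scheme
      list(n_used = length(g), z = med$z, p_nominal = med$p_nominal,
           cis_p = if (verify) cis_association(g, ce, kc)$p_values[["G"]] else NA_real_,
           trans_p = if (verify) trans_association(g, te, kc)$p_values[["G"]] else NA_real_,
           n_exec = ep$n_executed, M = ep$M, p_perm = ep$p_value,
           p_source = src, gof_p = if (!is.null(ep$gof_p)) ep$gof_p else NA_real_,
           beyond = isTRUE(ep$beyond_support),
           p_ub = if (!is.null(ep$p_upper_bound)) ep$p_upper_bound else ep$p_value,
           error = NA_character_)
    }, error = function(e) list(error = conditionMessage(e)))

    if (is.null(out$error) || is.na(out$error)) {
      res$n_used[i] <- out$n_used
      res$z[i] <- out$z
      res$p_nominal[i] <- out$p_nominal
      if (verify) { res$cis_p[i] <- out$cis_p; res$trans_p[i] <- out$trans_p }
      res$n_perm_executed[i] <- out$n_exec
      res$M[i] <- out$M
      res$p_perm[i] <- out$p_perm
      res$p_source[i] <- out$p_source
      res$gof_p[i] <- out$gof_p
      res$beyond_support[i] <- out$beyond
      res$p_upper_bound[i] <- out$p_ub
      n_routed[out$p_source] <- n_routed[out$p_source] + 1L
    } else {
      res$error[i] <- out$error
    }
    if (progress_every > 0 && i %% progress_every == 0) {
      message("processed ", i, "/", nt, " trios")
    }
  }

  if (qvalues) {
    ok <- !is.na(res$p_perm)
    if (any(ok)) {
      # GPD zeros are replaced by their recorded upper bounds; a floor at
      # the smallest normalized double guards against survival underflow
      res$.p_for_q <- pmax(ifelse(res$p_perm > 0, res$p_perm,
                                  res$p_upper_bound), 2.3e-308)
      best <- best_trio_per_gene_pair(res[ok, , drop = FALSE],
                                      p_col = ".p_for_q")
      qv <- storey_qvalues(best$.p_for_q)
      key <- paste(res$variant_id, res$cis_gene_id, res$trans_gene_id)
      bkey <- paste(best$variant_id, best$cis_gene_id, best$trans_gene_id)
      res$q_value[match(bkey, key)] <- qv$q_values
      res$.p_for_q <- NULL
    }
  }
  message("scheme routing: ",
          paste(names(n_routed), n_routed, sep = "=", collapse = ", "))
  res
}
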