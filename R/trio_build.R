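# Candidate-trio construction from cis- and trans-association summary
# tables, and per-gene-pair trio selection.

#' Build candidate mediation trios from association tables
#'
#' Joins cis and trans association tables on the shared variant and keeps
#' one trio (variant, cis-gene, trans-gene) per pair of rows passing both
#' significance thresholds: cis FDR at most \code{cis_fdr_threshold} and
#' trans p-value below \code{trans_p_threshold}. If the cis table carries no
#' \code{fdr} column it is computed with \code{\link{bh_fdr}} from the
#' \code{p} column.
#'
#' @param cis_table Data frame with columns \code{variant_id},
#'   \code{gene_id}, \code{p} (and optionally \code{fdr}).
#' @param trans_table Data frame with columns \code{variant_id},
#'   \code{gene_id}, \code{p}.
#' @param cis_fdr_threshold Cis significance level on FDR (default 0.05).
#' @param trans_p_threshold Trans significance level on raw p (default 1e-8).
#' @return Data frame with columns \code{variant_id}, \code{cis_gene_id},
#'   \code{trans_gene_id}, \code{cis_assoc_p}, \code{cis_fdr},
#'   \code{trans_assoc_p}, ordered by (variant_id, cis_gene_id,
#'   trans_gene_id). Self-pairs (cis gene == trans gene) are excluded.
#' @export
build_candidate_trios <- function(cis_table, trans_table,
                                  cis_fdr_threshold = 0.05,
                                  trans_p_threshold = 1e-8) {
  need <- c("variant_id", "gene_id", "p")
  for (tab in list(cis_table, trans_table)) {
    if (!all(need %in% names(tab))) {
      stop("association tables need columns: ", paste(need, collapse = ", "))
    }
  }
  cis <- as.data.frame(cis_table)
  if (!"fdr" %in% names(cis)) cis$fdr <- bh_fdr(cis$p)
  cis <- cis[cis$fdr <= cis_fdr_threshold, , drop = FALSE]
  trans <- as.data.frame(trans_table)
  trans <- trans[trans$p < trans_p_threshold, , drop = FALSE]
  m <- merge(
    data.frame(variant_id = cis$variant_id, cis_gene_id = cis$gene_id,
               cis_assoc_p = cis$p, cis_fdr = cis$fdr,
               stringsAsFactors = FALSE),
    data.frame(variant_id = trans$variant_id, trans_gene_id = trans$gene_id,
               trans_assoc_p = trans$p, stringsAsFactors = FALSE),
    by = "variant_id")
  m <- m[m$cis_gene_id != m$trans_gene_id, , drop = FALSE]
  if (nrow(m) == 0) {
    warning("no candidate trios pass both thresholds")
  }
  m <- m[order(m$variant_id, m$cis_gene_id, m$trans_gene_id), ,
         drop = FALSE]
  rownames(m) <- NULL
  m[, c("variant_id", "cis_gene_id", "trans_gene_id", "cis_assoc_p",
        "cis_fdr", "trans_assoc_p")]
}

#' Select the best trio per unique gene pair
#'
#' Among all candidate trios sharing a (cis-gene, trans-gene) pair (multiple
#' variants in linkage disequilibrium typically tag the same pair), keeps
#' the trio minimizing the chosen selection p-value; exact ties are broken
#' by the lexicographically smallest variant id.
#'
#' @param trios Data frame containing \code{variant_id}, \code{cis_gene_id},
#'   \code{trans_gene_id} and the selection column.
#' @param p_col Name of the p-value column used for selection (e.g.
#'   \code{"cis_assoc_p"} or a nominal mediation p-value).
#' @return One row per unique gene pair, ordered by (cis_gene_id,
#'   trans_gene_id).
#' @export
best_trio_per_gene_pair <- function(trios, p_col = "cis_assoc_p") {
  trios <- as.data.frame(trios)
  if (!p_col %in% names(trios)) stop("no column '", p_col, "' in trios")
  if (nrow(trios) == 0) return(trios)
  o <- order(trios$cis_gene_id, trios$trans_gene_id, trios[[p_col]],
             trios$variant_id)
  t2 <- trios[o, , drop = FALSE]
  pair <- paste(t2$cis_gene_id, t2$trans_gene_id, sep = "\r")
  out <- t2[!duplicated(pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}
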