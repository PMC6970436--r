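# File readers and writers for the standard exchange formats:
#   genotype TSV:   header "sample_id" then variant ids, one row per sample
#   genotype VCF:   VCF 4.x, GT field only, biallelic records
#   expression TSV: genes x samples, first column gene_id
#   covariate TSV:  samples x covariates, first column sample_id
#   trio TSV:       variant_id, cis_gene_id, trans_gene_id
#   association TSV: variant_id, gene_id, beta, se, p (fdr optional)

#' Read a genotype matrix from TSV or VCF
#'
#' TSV: one row per sample, first column \code{sample_id}, remaining columns
#' additive dosages per variant. VCF: standard VCF 4.x parsed with the vcfR
#' package; only the GT field is used, \code{0/0 -> 0}, \code{0/1 or 1/0 ->
#' 1}, \code{1/1 -> 2} (phased separators accepted), \code{./.} and half
#' calls become \code{NA}. Multi-allelic records are rejected.
#'
#' @param path File path.
#' @param format \code{"tsv"} or \code{"vcf"}; guessed from the extension
#'   by default.
#' @return Numeric matrix, samples x variants, with dimnames.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (names(d)[1] != "sample_id") {
      stop("genotype TSV must start with a 'sample_id' column (line 1)")
    }
    m <- as.matrix(d[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- d$sample_id
    return(m)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop("multi-allelic VCF record(s) at: ",
         paste(vcfR::getID(vcf)[multi], collapse = ", "),
         "; split or drop them first")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% "1/1"] <- 2
    out
  }
  m <- apply(gt, 2, dose)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
  ids <- vcfR::getID(vcf)
  miss <- is.na(ids) | ids == "."
  ids[miss] <- paste0(vcfR::getCHROM(vcf), ":", vcfR::getPOS(vcf))[miss]
  rownames(m) <- ids
  t(m)   # samples x variants
}

#' Read an expression matrix (genes x samples) from TSV
#'
#' @param path File path; first column \code{gene_id}.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "gene_id") {
    stop("expression TSV must start with a 'gene_id' column (line 1)")
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$gene_id
  m
}

#' Read a covariate matrix (samples x covariates) from TSV
#'
#' @param path File path; first column \code{sample_id}.
#' @return Numeric matrix, samples x covariates.
#' @export
read_covariates <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "sample_id") {
    stop("covariate TSV must start with a 'sample_id' column (line 1)")
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$sample_id
  m
}

#' Read an explicit trio list from TSV
#'
#' @param path File path with columns \code{variant_id}, \code{cis_gene_id},
#'   \code{trans_gene_id}.
#' @return Data frame of trios.
#' @export
read_trios <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "cis_gene_id", "trans_gene_id")
  if (!all(need %in% names(d))) {
    stop("trio TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (any(d$cis_gene_id == d$trans_gene_id)) {
    stop("trio list contains self-pairs (cis_gene_id == trans_gene_id)")
  }
  d
}

#' Write genotype, expression, covariate or result tables as TSV
#'
#' Inverse of the corresponding readers; round-trips exactly through
#' \code{\link{read_genotypes}} / \code{\link{read_expression}} /
#' \code{\link{read_covariates}}.
#'
#' @param x Matrix or data frame to write.
#' @param path Output path.
#' @param what One of \code{"genotypes"}, \code{"expression"},
#'   \code{"covariates"}, \code{"table"}.
#' @return Invisibly, \code{path}.
#' @export
write_tsv <- function(x, path,
                      what = c("table", "genotypes", "expression",
                               "covariates")) {
  what <- match.arg(what)
  if (what == "table") {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  key <- switch(what, genotypes = "sample_id", expression = "gene_id",
                covariates = "sample_id")
  d <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- key
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
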