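# Genome-wide FDR across unique gene pairs.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (delegates to \code{stats::p.adjust}); used
#' for the cis-table FDR in \code{\link{build_candidate_trios}} and as the
#' fallback when the Storey-Tibshirani pi0 estimate is unusable.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  stats::p.adjust(p, method = "BH")
}

# Storey-Tibshirani pi0: pi0(lambda) = #{p > lambda} / (m * (1 - lambda))
# over a lambda grid, smoothed with a cubic spline and read off at the
# largest lambda.
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 100) {
    warning("fewer than 100 p-values; using conservative pi0 = min(1, 2*mean(p))")
    return(min(1, 2 * mean(p)))
  }
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(sp, x = max(lambda))$y
  }, error = function(e) NA_real_)
  if (!is.finite(pi0) || pi0 <= 0) {
    warning("spline pi0 estimate unusable; using conservative pi0 = min(1, 2*mean(p))")
    pi0 <- min(1, 2 * mean(p))
  }
  min(pi0, 1)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the proportion of true nulls pi0 on a lambda grid
#' (0.05 to 0.95, step 0.05) with cubic-spline smoothing evaluated at the
#' largest lambda, then computes
#' q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j), which is monotone
#' non-decreasing in p. With pi0 = 1 this reduces exactly to
#' Benjamini-Hochberg. Exact zeros (a GPD beyond-support report) must be
#' replaced by their recorded upper bounds by the caller first.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param lambda Grid for pi0 estimation.
#' @param pi0 Optional fixed pi0 overriding estimation.
#' @return List with \code{q_values} (aligned with \code{p}) and \code{pi0}.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]; replace GPD zeros by their upper bounds")
  }
  m <- length(p)
  if (is.null(pi0)) pi0 <- estimate_pi0(p, lambda)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)[ro]
  list(q_values = q, pi0 = pi0)
}
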