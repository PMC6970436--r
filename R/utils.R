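# Internal helpers shared across modules.

# Accept either a null_stats object or a bare numeric vector of |z0| values.
as_null_values <- function(x) {
  if (inherits(x, "null_stats")) return(x$values)
  v <- as.numeric(x)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("null statistics must be finite and non-negative (absolute values)")
  }
  v
}

# Deterministic per-trio seed derived from (base_seed, index) so that serial
# runs, reruns of single trios, and subsetted runs all see the same stream.
# LCG-style hash folded into [1, 2^31 - 2], valid for set.seed().
trio_seed <- function(base_seed, index) {
  m <- 2147483647
  h <- (as.numeric(base_seed) %% m) * 48271 %% m
  h <- (h + (as.numeric(index) %% m) * 1664525 + 1013904223) %% m
  as.integer(h %% (m - 1) + 1)
}

# Align a set of named vectors/matrices on their common samples, preserving
# the order of the first argument's names. Objects without names are assumed
# already aligned.
check_aligned <- function(n, ...) {
  lens <- vapply(list(...), function(x) {
    if (is.matrix(x) || is.data.frame(x)) nrow(x) else length(x)
  }, integer(1))
  if (any(lens != n)) {
    stop("inputs are not aligned: expected ", n, " samples, got ",
         paste(lens, collapse = ", "))
  }
  invisible(TRUE)
}

# Validate an additive genotype vector: dosages in {0,1,2} after missing-data
# removal, at least two distinct genotype classes.
validate_genotype <- function(g, what = "genotype") {
  if (any(!g %in% c(0, 1, 2))) {
    stop(what, " must be additive dosages in {0, 1, 2}")
  }
  if (length(unique(g)) < 2L) {
    stop(what, " is monomorphic: at least two genotype classes are required")
  }
  invisible(TRUE)
}
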