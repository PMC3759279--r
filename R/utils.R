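# internal helpers shared across modules

# classed error so callers can test for specific failure modes
rb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rotboost_error", "error", "condition")))
}

# set.seed only when the caller supplied one; otherwise leave the RNG stream
# alone so callers can manage reproducibility themselves
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

# derive a reproducible vector of sub-seeds (< 2^31) from the current RNG
draw_subseeds <- function(k) {
  sample.int(.Machine$integer.max - 1L, k)
}

# argmax over rows with lowest-index tie-break
argmax_row <- function(scores) {
  max.col(scores, ties.method = "first")
}

# Shannon entropy (bits) of a count vector
entropy_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

# standardize a matrix by precomputed per-gene center/scale; constant genes
# (scale 0) map to zero columns
apply_norm_matrix <- function(x, stats) {
  x <- sweep(x, 2, stats$center, "-")
  keep <- stats$scale > 0
  if (any(keep)) x[, keep] <- sweep(x[, keep, drop = FALSE], 2, stats$scale[keep], "/")
  if (any(!keep)) x[, !keep] <- 0
  x
}

# extract (X, y) from an ExpressionDataset or pass matrices through
resolve_xy <- function(x, y = NULL) {
  if (inherits(x, "ExpressionDataset")) {
    list(x = x$values, y = x$labels)
  } else {
    if (is.null(y)) rb_stop("labels `y` required when `x` is a matrix", "rb_missing_labels")
    if (length(y) != nrow(x)) rb_stop("length(y) must equal nrow(x)", "rb_dim_mismatch")
    list(x = as.matrix(x), y = factor(y))
  }
}
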