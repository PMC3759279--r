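#' Class-aware MDL discretization of one gene
#'
#' Discretizes a continuous expression vector with the Fayyad-Irani recursive
#' scheme: at each step the candidate binary cut minimizing the
#' class-entropy of the two halves is accepted only if its information gain
#' passes the minimum-description-length criterion, then both halves are
#' searched recursively. A vector in which no cut passes the criterion (e.g.
#' a constant gene, or pure noise) collapses to a single bin, which is what
#' makes downstream symmetric-uncertainty scores of uninformative genes
#' exactly zero.
#'
#' @param x numeric vector of expression values for one gene.
#' @param y class labels (factor or vector) of the same length.
#' @return Integer vector of bin codes (1-based); `attr(, "cuts")` holds the
#'   accepted cut thresholds (empty for a single bin).
#' @references Fayyad & Irani (1993), Multi-interval discretization of
#'   continuous-valued attributes for classification learning.
#' @export
discretize_feature <- function(x, y) {
  if (length(x) != length(y)) rb_stop("x and y lengths differ", "rb_dim_mismatch")
  if (length(x) < 2) rb_stop("need at least 2 samples", "rb_invalid_input")
  y <- as.integer(factor(y))
  cuts <- .mdl_cut_points(as.numeric(x), y, max(y))
  codes <- if (length(cuts) == 0) rep(1L, length(x)) else findInterval(x, cuts) + 1L
  attr(codes, "cuts") <- cuts
  codes
}

#' Symmetric uncertainty between two discrete vectors
#'
#' `SU(a, b) = 2 * IG(a; b) / (H(a) + H(b))`, the normalized mutual
#' information used as the C-correlation measure of FCBF. Ranges over
#' \[0, 1\]: 0 when the empirical joint distribution factorizes, 1 when the
#' two vectors determine each other (identical up to relabeling). When both
#' vectors are constant the value is 0 by convention.
#'
#' @param a,b equal-length vectors coerced to discrete codes.
#' @return A number in \[0, 1\].
#' @export
symmetric_uncertainty <- function(a, b) {
  if (length(a) != length(b)) rb_stop("a and b lengths differ", "rb_dim_mismatch")
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  na <- max(a); nb <- max(b)
  ha <- entropy_counts(tabulate(a, na))
  hb <- entropy_counts(tabulate(b, nb))
  if (ha + hb == 0) return(0)
  hab <- entropy_counts(tabulate(a + na * (b - 1L), na * nb))
  ig <- ha + hb - hab
  max(0, min(1, 2 * ig / (ha + hb)))
}

new_selection_result <- function(selected, scores, threshold, gene_ids = NULL, method = "fcbf") {
  structure(list(selected = as.integer(selected), scores = scores,
                 threshold = threshold, gene_ids = gene_ids, method = method),
            class = "SelectionResult")
}

#' @exportS3Method base::print
print.SelectionResult <- function(x, ...) {
  cat(sprintf("SelectionResult (%s): %d genes selected (threshold %s)\n",
              x$method, length(x$selected), format(x$threshold)))
  if (length(x$selected) > 0) {
    ids <- if (!is.null(x$gene_ids)) x$gene_ids[x$selected] else x$selected
    cat("  top:", paste(head(ids, 8), collapse = ", "),
        if (length(x$selected) > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.SelectionResult <- function(x, ...) {
  data.frame(index = x$selected,
             gene_id = if (!is.null(x$gene_ids)) x$gene_ids[x$selected] else as.character(x$selected),
             score = x$scores[x$selected])
}

#' FCBF gene selection
#'
#' Fast correlation-based filter: (1) each gene is MDL-discretized against
#' the class and scored by its symmetric uncertainty with the class (the
#' C-correlation); genes with score above `threshold` are kept; (2) the kept
#' genes are sorted by descending score (ties broken by original index); (3)
#' walking the sorted list, a gene is eliminated as redundant when some
#' earlier surviving gene correlates with it at least as strongly as the
#' class does (`SU(g_i, g_j) >= SU(g_j, class)`). Exact duplicates of a
#' selected gene are therefore always removed.
#'
#' @param x samples-by-genes numeric matrix or an [expression_dataset()]
#'   (imputed; standardization is not required, the method is rank-based
#'   through discretization).
#' @param y class labels (ignored when `x` is an `ExpressionDataset`).
#' @param threshold relevance cutoff on the gene-class symmetric uncertainty;
#'   the default 0 keeps every gene with positive score, leaving the
#'   dimensionality reduction to the redundancy step.
#' @return A `SelectionResult` with `selected` (surviving gene indices in
#'   descending relevance order) and `scores` (gene-class symmetric
#'   uncertainty for all genes).
#' @examples
#' sim <- generate_synthetic(synthetic_spec(N = 40, n = 50, n_informative = 2,
#'                                          n_redundant = 1, missing_rate = 0,
#'                                          seed = 1))
#' fcbf_select(sim$dataset)
#' @export
fcbf_select <- function(x, y = NULL, threshold = 0) {
  d <- resolve_xy(x, y)
  gene_ids <- if (inherits(x, "ExpressionDataset")) x$gene_ids else colnames(d$x)
  if (anyNA(d$x)) rb_stop("impute missing values before feature selection", "rb_missing_values")
  n <- ncol(d$x)
  ycode <- as.integer(d$y)
  disc <- vector("list", n)
  su_class <- numeric(n)
  for (j in seq_len(n)) {
    disc[[j]] <- discretize_feature(d$x[, j], ycode)
    su_class[j] <- symmetric_uncertainty(disc[[j]], ycode)
  }
  relevant <- which(su_class > threshold)
  if (length(relevant) == 0) {
    warning("no gene exceeds the relevance threshold; empty selection")
    return(new_selection_result(integer(0), su_class, threshold, gene_ids))
  }
  ord <- relevant[order(-su_class[relevant], relevant)]
  alive <- rep(TRUE, length(ord))
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    if (i == length(ord)) break
    for (j in seq((i + 1), length(ord))) {
      if (!alive[j]) next
      if (symmetric_uncertainty(disc[[ord[i]]], disc[[ord[j]]]) >= su_class[ord[j]]) {
        alive[j] <- FALSE
      }
    }
  }
  new_selection_result(ord[alive], su_class, threshold, gene_ids)
}

#' Generalized signal-to-noise-ratio gene ranking
#'
#' Scores each gene by the ratio of between-class to within-class variation,
#' `sum_c p_c (mu_gc - mu_g)^2 / sum_c p_c sigma2_gc`, with class priors
#' `p_c` and population within-class variances. Higher scores indicate more
#' discriminative genes. Genes with zero within-class variation but separated
#' class means get an `Inf` score and rank first; constant genes score 0.
#'
#' @inheritParams fcbf_select
#' @return A `SelectionResult` with all genes ranked in descending score
#'   order (ties broken by gene index).
#' @export
gsnr_rank <- function(x, y = NULL) {
  d <- resolve_xy(x, y)
  gene_ids <- if (inherits(x, "ExpressionDataset")) x$gene_ids else colnames(d$x)
  if (anyNA(d$x)) rb_stop("impute missing values before feature selection", "rb_missing_values")
  y <- droplevels(d$y)
  if (nlevels(y) < 2) rb_stop("need at least 2 classes", "rb_invalid_input")
  n_tot <- nrow(d$x)
  p <- as.numeric(table(y)) / n_tot
  mu_all <- colMeans(d$x)
  between <- numeric(ncol(d$x))
  within <- numeric(ncol(d$x))
  for (c_idx in seq_len(nlevels(y))) {
    rows <- which(as.integer(y) == c_idx)
    xc <- d$x[rows, , drop = FALSE]
    mu_c <- colMeans(xc)
    var_c <- colMeans(xc^2) - mu_c^2   # population variance
    between <- between + p[c_idx] * (mu_c - mu_all)^2
    within <- within + p[c_idx] * var_c
  }
  eps <- .Machine$double.eps
  score <- ifelse(between <= eps, 0, ifelse(within <= eps, Inf, between / within))
  ord <- order(-score, seq_along(score))
  new_selection_result(ord, score, threshold = NA_real_, gene_ids, method = "gsnr")
}

#' Keep the top fraction of a ranked selection
#'
#' Truncates a descending-ordered selection to its leading
#' `ceiling(fraction * length)` genes, the "top 10 percent" retention rule
#' commonly applied to ranked gene lists.
#'
#' @param result a `SelectionResult` (sorted descending by score).
#' @param fraction fraction in (0, 1\] of the list to keep.
#' @return The truncated `SelectionResult`.
#' @export
retain_top_fraction <- function(result, fraction = 0.1) {
  stopifnot(inherits(result, "SelectionResult"))
  if (!(fraction > 0 && fraction <= 1)) rb_stop("fraction must lie in (0, 1]", "rb_invalid_input")
  k <- ceiling(fraction * length(result$selected))
  result$selected <- head(result$selected, k)
  result
}
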