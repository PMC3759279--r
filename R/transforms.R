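#' Randomly partition features into disjoint subsets
#'
#' Shuffles the feature indices and chunks them into `K = ceiling(n / M)`
#' disjoint subsets of `M` features each (the last subset takes the
#' remainder). With `balanced = TRUE` subset sizes are evened out to
#' `floor(n/K)` or `ceiling(n/K)` instead. Uses the session RNG; call
#' `set.seed()` beforehand for a reproducible draw.
#'
#' @param n total feature count.
#' @param M target features per subset.
#' @param balanced spread the remainder over all subsets instead of leaving
#'   one short subset.
#' @return A `FeaturePartition`: list with `subsets` (list of integer index
#'   vectors), `M`, `K`, `n`.
#' @export
partition_features <- function(n, M, balanced = FALSE) {
  if (M < 1) rb_stop("M must be >= 1", "rb_invalid_input")
  if (M > n) {
    warning("M exceeds the feature count; using a single subset of all features")
    M <- n
  }
  perm <- sample.int(n)
  K <- ceiling(n / M)
  sizes <- if (balanced) {
    base <- n %/% K
    c(rep(base + 1L, n %% K), rep(base, K - n %% K))
  } else {
    c(rep(M, K - 1L), n - M * (K - 1L))
  }
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  subsets <- lapply(seq_len(K), function(j) sort(perm[starts[j]:ends[j]]))
  structure(list(subsets = subsets, M = M, K = K, n = n), class = "FeaturePartition")
}

#' Class-subset and bootstrap subsampling for one feature subset
#'
#' Implements the per-subset subsampling of the Rotation Forest recipe: a
#' nonempty subset of the classes is drawn uniformly at random, rows are
#' restricted to samples of those classes, and a bootstrap sample (with
#' replacement) of `frac` of the remaining rows is drawn. If the class
#' restriction leaves fewer than 2 rows, the bootstrap falls back to all
#' rows. The subsample is only used to fit the subset transform; the
#' transform itself is applied to every sample.
#'
#' @param x samples-by-M_j numeric matrix (columns of one feature subset).
#' @param labels class labels for the rows of `x`.
#' @param frac bootstrap fraction of the class-restricted rows (default
#'   0.75, the original Rotation Forest convention).
#' @return The subsampled matrix.
#' @export
subsample_for_subset <- function(x, labels, frac = 0.75) {
  x <- as.matrix(x)
  labels <- factor(labels)
  classes <- levels(droplevels(labels))
  m <- length(classes)
  keep <- classes
  if (m > 1) {
    repeat {  # uniform over the 2^m - 1 nonempty class subsets
      pick <- runif(m) < 0.5
      if (any(pick)) break
    }
    keep <- classes[pick]
  }
  rows <- which(labels %in% keep)
  if (length(rows) < 2) rows <- seq_len(nrow(x))
  ndraw <- max(1L, round(frac * length(rows)))
  idx <- rows[sample.int(length(rows), ndraw, replace = TRUE)]
  x[idx, , drop = FALSE]
}

# deflation-mode FastICA with tanh contrast on pre-centered data.
# Returns NULL when whitening is impossible (rank-deficient covariance) or
# any component fails to converge; the caller then falls back to PCA.
fastica_unmixing <- function(xc, max_iter = 400, tol = 1e-4) {
  M <- ncol(xc)
  cv <- cov(xc)
  e <- eigen(cv, symmetric = TRUE)
  if (any(e$values <= max(e$values) * 1e-10) || any(e$values <= 0)) return(NULL)
  Kw <- e$vectors %*% diag(1 / sqrt(e$values), M)
  Z <- xc %*% Kw
  W <- matrix(0, M, M)
  for (p in seq_len(M)) {
    w <- rnorm(M)
    if (p > 1) {
      w <- w - crossprod(W[seq_len(p - 1), , drop = FALSE],
                         W[seq_len(p - 1), , drop = FALSE] %*% w)
    }
    w <- w / sqrt(sum(w^2))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      wx <- as.vector(Z %*% w)
      g <- tanh(wx)
      w1 <- colMeans(Z * g) - mean(1 - g^2) * w
      if (p > 1) {
        w1 <- w1 - as.vector(crossprod(W[seq_len(p - 1), , drop = FALSE],
                                       W[seq_len(p - 1), , drop = FALSE] %*% w1))
      }
      nrm <- sqrt(sum(w1^2))
      if (nrm < 1e-12) break
      w1 <- w1 / nrm
      if (abs(abs(sum(w1 * w)) - 1) < tol) {
        w <- w1
        ok <- TRUE
        break
      }
      w <- w1
    }
    if (!ok) return(NULL)
    W[p, ] <- w
  }
  Kw %*% t(W)  # composed whitening x unmixing: xc %*% Q gives the sources
}

#' Fit a per-subset linear transform (PCA or FastICA)
#'
#' Fits an `M_j x M_j` coefficient matrix on a (sub)sample of one feature
#' subset, keeping all components (no dimensionality reduction). PCA columns
#' are the eigenvectors of the column covariance in descending eigenvalue
#' order; ICA uses deflation-mode FastICA with a tanh contrast (max 400
#' iterations, tolerance 1e-4), with whitening folded into the returned
#' matrix so application stays a single matrix product. The fit is on
#' column-centered data; the centering offsets are returned and later folded
#' into the rotation. Component signs are fixed by making the
#' largest-absolute loading of each column positive.
#'
#' @param x subsample matrix (rows = sampled instances, columns = the
#'   subset's features).
#' @param method `"pca"` or `"ica"`. ICA falls back to PCA for blocks where
#'   FastICA does not converge or the covariance is rank-deficient.
#' @return List with `Q` (coefficients), `center`, `method` (the method
#'   actually used), `converged`.
#' @export
fit_subset_transform <- function(x, method = c("pca", "ica")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  M <- ncol(x)
  if (M < 1) rb_stop("need at least one feature column", "rb_invalid_input")
  center <- colMeans(x)
  if (nrow(x) < 2) {
    return(list(Q = diag(M), center = center, method = "identity", converged = FALSE))
  }
  xc <- sweep(x, 2, center)
  Q <- NULL
  used <- method
  converged <- TRUE
  if (method == "ica" && M >= 2) {
    Q <- fastica_unmixing(xc)
    if (is.null(Q)) {
      used <- "pca"
      converged <- FALSE
    }
  } else if (method == "ica") {
    used <- "pca"  # 1-D block: ICA is vacuous
  }
  if (is.null(Q)) {
    e <- eigen(cov(xc), symmetric = TRUE)
    Q <- e$vectors
  }
  # sign convention: largest-absolute loading positive
  for (k in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, k]))
    if (Q[i, k] < 0) Q[, k] <- -Q[, k]
  }
  list(Q = Q, center = center, method = used, converged = converged)
}

#' Assemble a sparse block rotation matrix
#'
#' Places each subset's coefficient matrix into an `n x n` sparse matrix
#' whose rows and columns are arranged so the product `X %*% R_a` applies
#' each block to its own subset's columns in the original feature order:
#' column block `j` of `X %*% R_a` equals `X[, F_j] %*% Q_j`.
#'
#' @param partition a `FeaturePartition`.
#' @param blocks list of square coefficient matrices, one per subset, block
#'   `j` of size `length(partition$subsets[[j]])`.
#' @param centers optional list of per-subset centering offsets (folded into
#'   a per-feature offset applied by [apply_rotation()] before the product).
#' @return A `RotationMatrixSpec`: list with sparse `R_a`
#'   (`Matrix::dgCMatrix`), `center` (length-n offset), `partition`,
#'   `blocks`.
#' @export
assemble_rotation <- function(partition, blocks, centers = NULL) {
  stopifnot(inherits(partition, "FeaturePartition"))
  K <- partition$K
  n <- partition$n
  if (length(blocks) != K) rb_stop("one block required per subset", "rb_block_mismatch")
  sizes <- lengths(partition$subsets)
  center <- numeric(n)
  ii <- vector("list", K)
  jj <- vector("list", K)
  xx <- vector("list", K)
  offset <- 0L
  for (j in seq_len(K)) {
    Q <- as.matrix(blocks[[j]])
    Mj <- sizes[j]
    if (!all(dim(Q) == c(Mj, Mj))) {
      rb_stop(sprintf("block %d is %dx%d but subset has %d features",
                      j, nrow(Q), ncol(Q), Mj), "rb_block_mismatch")
    }
    feats <- partition$subsets[[j]]
    ii[[j]] <- rep(feats, times = Mj)
    jj[[j]] <- rep(offset + seq_len(Mj), each = Mj)
    xx[[j]] <- as.vector(Q)
    if (!is.null(centers)) center[feats] <- centers[[j]]
    offset <- offset + Mj
  }
  R_a <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n, n))
  structure(list(R_a = R_a, center = center, partition = partition, blocks = blocks),
            class = "RotationMatrixSpec")
}

#' Apply a rotation to a data matrix
#'
#' Subtracts the rotation's per-feature centering offsets and multiplies by
#' the sparse rearranged rotation matrix.
#'
#' @param x samples-by-n matrix in the original feature order.
#' @param spec a `RotationMatrixSpec` from [assemble_rotation()].
#' @return The rotated matrix, same shape as `x`.
#' @export
apply_rotation <- function(x, spec) {
  stopifnot(inherits(spec, "RotationMatrixSpec"))
  x <- as.matrix(x)
  if (ncol(x) != nrow(spec$R_a)) {
    rb_stop(sprintf("x has %d columns but the rotation expects %d",
                    ncol(x), nrow(spec$R_a)), "rb_dim_mismatch")
  }
  out <- as.matrix(sweep(x, 2, spec$center) %*% spec$R_a)
  colnames(out) <- paste0("rc", seq_len(ncol(out)))
  out
}

# one full rotation draw: partition -> per-subset subsample -> transform ->
# assembled sparse matrix. Uses the session RNG.
build_rotation <- function(x, y, M, method = c("pca", "ica", "identity"),
                           boot_frac = 0.75) {
  method <- match.arg(method)
  n <- ncol(x)
  if (method == "identity") {
    part <- structure(list(subsets = list(seq_len(n)), M = n, K = 1L, n = n),
                      class = "FeaturePartition")
    return(assemble_rotation(part, list(diag(n))))
  }
  part <- partition_features(n, min(M, n))  # small selected panels: one subset
  blocks <- vector("list", part$K)
  centers <- vector("list", part$K)
  fallbacks <- 0L
  for (j in seq_len(part$K)) {
    xs <- x[, part$subsets[[j]], drop = FALSE]
    xsub <- subsample_for_subset(xs, y, frac = boot_frac)
    fit <- fit_subset_transform(xsub, method = method)
    if (method == "ica" && fit$method != "ica") fallbacks <- fallbacks + 1L
    blocks[[j]] <- fit$Q
    centers[[j]] <- fit$center
  }
  spec <- assemble_rotation(part, blocks, centers)
  spec$ica_fallbacks <- fallbacks
  spec
}
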