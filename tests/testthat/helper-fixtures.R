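# fixtures and independent oracles used across the test files

# tiny dataset with known structure: gene A predicts the class perfectly,
# gene B is an exact copy of A, gene C is class-independent noise
make_abc_dataset <- function() {
  a <- c(0, 0, 0, 0, 9, 9, 9, 9)
  noise <- c(0.3, -1.2, 0.7, 0.1, -0.5, 1.4, -0.9, 0.2)
  expression_dataset(cbind(A = a, B = a, C = noise),
                     labels = rep(c("neg", "pos"), each = 4))
}

# write an ExpressionDataset to temp files, returning the two paths
write_temp_dataset <- function(ds, sep = "\t") {
  mp <- tempfile(fileext = ".tsv")
  lp <- tempfile(fileext = ".tsv")
  write_dataset(ds, mp, lp, sep = sep)
  list(matrix = mp, labels = lp)
}

# independent entropy/SU oracle built on base::table (no shared code with
# the package internals)
oracle_entropy <- function(v) {
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log2(p))
}
oracle_su <- function(a, b) {
  ha <- oracle_entropy(a)
  hb <- oracle_entropy(b)
  if (ha + hb == 0) return(0)
  hab <- oracle_entropy(paste(a, b))
  2 * (ha + hb - hab) / (ha + hb)
}

# brute-force transcription of the FCBF definition: discretize every gene,
# relevance-filter, sort descending (ties by index), then keep gene j iff no
# earlier KEPT gene i has SU(i, j) >= SU(j, class)
oracle_fcbf <- function(x, y, threshold = 0) {
  n <- ncol(x)
  disc <- lapply(seq_len(n), function(j) discretize_feature(x[, j], y))
  su_c <- vapply(seq_len(n), function(j) oracle_su(disc[[j]], as.integer(factor(y))),
                 numeric(1))
  rel <- which(su_c > threshold)
  ord <- rel[order(-su_c[rel], rel)]
  kept <- integer(0)
  for (j in ord) {
    redundant <- FALSE
    for (i in kept) {
      if (oracle_su(disc[[i]], disc[[j]]) >= su_c[j]) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, j)
  }
  kept
}

# kappa directly from the printed definition, via independent arithmetic
oracle_kappa <- function(pred_a, pred_b, labelset) {
  c_ <- length(labelset)
  m <- matrix(0, c_, c_)
  for (t in seq_along(pred_a)) {
    k <- match(pred_a[t], labelset)
    s <- match(pred_b[t], labelset)
    m[k, s] <- m[k, s] + 1
  }
  m <- m / length(pred_a)
  obs <- sum(diag(m))
  abc <- sum(sapply(seq_len(c_), function(k) sum(m[k, ]) * sum(m[, k])))
  (obs - abc) / (1 - abc)
}

# small separable two-class continuous dataset (distinct rows, pure leaves)
make_separable <- function(N = 60, p = 5, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = N)
  x <- matrix(rnorm(N * p), N, p)
  x[, 1] <- x[, 1] + ifelse(y == "a", 4, -4)
  list(x = x, y = factor(y))
}
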