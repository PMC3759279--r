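#' Balanced bootstrap train/test split
#'
#' Draws a class-stratified bootstrap training set (each class contributes
#' draws with replacement in proportion to its frequency, i.e. `n_c` draws
#' from class `c`), and uses the samples never drawn (out-of-bag) as the
#' test set. The split is redrawn (at most `max_tries` times) when the
#' out-of-bag set is empty or misses a class, so that test error is always
#' computable; if the out-of-bag set is still degenerate after the retries,
#' a nonempty one is accepted with a warning and an empty one is an error.
#'
#' @param y class labels (or an [expression_dataset()], whose labels are
#'   used).
#' @param max_tries redraw attempts for degenerate out-of-bag sets.
#' @return List with `train` (indices drawn with replacement, length `N`)
#'   and `test` (out-of-bag indices).
#' @export
balanced_bootstrap_split <- function(y, max_tries = 10) {
  if (inherits(y, "ExpressionDataset")) y <- y$labels
  y <- factor(y)
  N <- length(y)
  if (N < 2) rb_stop("need at least 2 samples", "rb_invalid_input")
  classes <- levels(droplevels(y))
  draw <- function() {
    tr <- unlist(lapply(classes, function(cl) {
      rows <- which(y == cl)
      rows[sample.int(length(rows), length(rows), replace = TRUE)]
    }), use.names = FALSE)
    list(train = tr, test = setdiff(seq_len(N), tr))
  }
  last <- NULL
  for (i in seq_len(max_tries)) {
    sp <- draw()
    last <- sp
    if (length(sp$test) > 0 && all(classes %in% y[sp$test])) return(sp)
  }
  if (length(last$test) == 0) {
    rb_stop("out-of-bag set empty after repeated redraws", "rb_degenerate_split")
  }
  warning("out-of-bag set misses a class after repeated redraws; using it anyway")
  last
}

#' Combine bootstrap replicate errors with the 0.632 rule
#'
#' `E = mean(0.368 * alpha_i + 0.632 * beta_i)` over the replicates, where
#' `alpha_i` is the training (resubstitution) error and `beta_i` the
#' out-of-bag test error of replicate `i`. The fixed 0.368/0.632 weights are
#' the classic bootstrap error estimator; `adaptive = TRUE` switches to the
#' 0.632+ variant, which shrinks the test-error weight toward 0.632 as the
#' no-information rate is approached (useful for heavily overfit learners).
#'
#' @param replicates two-column matrix or data frame (alpha, beta), or a
#'   list of length-2 vectors; one row per bootstrap replicate.
#' @param adaptive use the adaptive 0.632+ weighting; requires `gamma`.
#' @param gamma no-information error rate (needed when `adaptive = TRUE`).
#' @return The combined error estimate.
#' @export
bootstrap_632 <- function(replicates, adaptive = FALSE, gamma = NULL) {
  if (is.list(replicates) && !is.data.frame(replicates)) {
    replicates <- do.call(rbind, replicates)
  }
  replicates <- as.matrix(replicates)
  if (nrow(replicates) < 1) rb_stop("need at least one replicate", "rb_invalid_input")
  if (ncol(replicates) < 2) rb_stop("replicates must be (alpha, beta) pairs", "rb_invalid_input")
  a <- replicates[, 1]
  b <- replicates[, 2]
  if (any(a < 0 | a > 1 | b < 0 | b > 1)) rb_stop("errors must lie in [0, 1]", "rb_invalid_input")
  if (!adaptive) return(mean(0.368 * a + 0.632 * b))
  if (is.null(gamma)) rb_stop("gamma required for the adaptive 0.632+ variant", "rb_invalid_input")
  # per-replicate relative overfitting rate and adaptive weight
  bq <- pmin(b, gamma)
  rr <- ifelse(bq > a & gamma > a, (bq - a) / (gamma - a), 0)
  wt <- 0.632 / (1 - 0.368 * rr)
  mean((1 - wt) * a + wt * bq)
}

#' Estimate a learner's error with the balanced 0.632 bootstrap
#'
#' Runs `n_reps` balanced bootstrap replicates: in each, the data are split
#' with [balanced_bootstrap_split()], gene standardization statistics and
#' the optional feature selection are computed on the training samples only
#' (avoiding selection bias), the learner is fitted, and the training error
#' `alpha_i` and out-of-bag error `beta_i` are recorded. The replicate
#' errors are combined by [bootstrap_632()], and per-replicate out-of-bag
#' accuracies are summarized as mean and standard deviation.
#'
#' @param ds an [expression_dataset()] with no missing cells (run
#'   [impute_missing()] first).
#' @param trainer function `(x, y) -> model`, where the model has a
#'   `predict(model, x)` method returning labels; e.g.
#'   `function(x, y) train_rotboost(x, y)`.
#' @param n_reps bootstrap replicates (default 15).
#' @param selector optional function `(x, y) -> SelectionResult` (or integer
#'   index vector) applied to the training samples of each replicate.
#' @param normalize `"split"` fits standardization on the training samples
#'   of each replicate and applies it to both halves (default); `"global"`
#'   standardizes the full dataset once up front; `"none"` skips it.
#' @param seed optional seed for the whole evaluation.
#' @param keep_models keep fitted models and per-replicate splits in the
#'   result (needed for kappa-error analysis of the members).
#' @return A `BootstrapEstimate`: list with `replicates` (data frame of
#'   alpha, beta, accuracy), `E` (the 0.632 estimate), `mean_accuracy`,
#'   `sd_accuracy`, `n_reps`, and optionally `models` / `splits`.
#' @export
evaluate_method <- function(ds, trainer, n_reps = 15, selector = NULL,
                            normalize = c("split", "global", "none"),
                            seed = NULL, keep_models = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  normalize <- match.arg(normalize)
  if (anyNA(ds$values)) rb_stop("impute missing values before evaluation", "rb_missing_values")
  if (n_reps < 1) rb_stop("n_reps must be >= 1", "rb_invalid_input")
  maybe_set_seed(seed)
  if (normalize == "global") ds <- normalize_genes(ds)
  y <- ds$labels
  reps <- data.frame(replicate = seq_len(n_reps), alpha = NA_real_,
                     beta = NA_real_, accuracy = NA_real_)
  models <- if (keep_models) vector("list", n_reps) else NULL
  splits <- if (keep_models) vector("list", n_reps) else NULL
  for (r in seq_len(n_reps)) {
    sp <- balanced_bootstrap_split(y)
    x_tr <- ds$values[sp$train, , drop = FALSE]
    x_te <- ds$values[sp$test, , drop = FALSE]
    y_tr <- y[sp$train]
    y_te <- y[sp$test]
    if (normalize == "split") {
      center <- colMeans(x_tr)
      scale_ <- sqrt(pmax(colMeans(x_tr^2) - center^2, 0))
      stats <- list(center = center, scale = scale_)
      x_tr <- apply_norm_matrix(x_tr, stats)
      x_te <- apply_norm_matrix(x_te, stats)
    }
    if (!is.null(selector)) {
      sel <- selector(x_tr, y_tr)
      idx <- if (inherits(sel, "SelectionResult")) sel$selected else as.integer(sel)
      if (length(idx) == 0) idx <- seq_len(ncol(x_tr))  # degenerate selection: keep all
      x_tr <- x_tr[, idx, drop = FALSE]
      x_te <- x_te[, idx, drop = FALSE]
    }
    model <- trainer(x_tr, y_tr)
    reps$alpha[r] <- mean(predict(model, x_tr) != as.character(y_tr))
    beta <- mean(predict(model, x_te) != as.character(y_te))
    reps$beta[r] <- beta
    reps$accuracy[r] <- 1 - beta
    if (keep_models) {
      models[[r]] <- model
      splits[[r]] <- c(sp, list(x_test = x_te, y_test = y_te))
    }
  }
  structure(list(replicates = reps,
                 E = bootstrap_632(reps[, c("alpha", "beta")]),
                 mean_accuracy = mean(reps$accuracy),
                 sd_accuracy = sd(reps$accuracy),
                 n_reps = n_reps, models = models, splits = splits),
            class = "BootstrapEstimate")
}

#' @exportS3Method base::print
print.BootstrapEstimate <- function(x, ...) {
  cat(sprintf("0.632 bootstrap over %d replicates: E = %.4f, accuracy %.2f%% +/- %.2f%%\n",
              x$n_reps, x$E, 100 * x$mean_accuracy, 100 * x$sd_accuracy))
  invisible(x)
}

#' Coincidence matrix of two classifiers
#'
#' Entry `(k, s)` is the proportion of evaluation samples labeled class `k`
#' by the first classifier and class `s` by the second; entries sum to 1.
#'
#' @param pred_a,pred_b equal-length label vectors.
#' @param labelset class labels indexing the matrix; defaults to the sorted
#'   union of the two prediction vectors.
#' @return A `c x c` matrix of proportions.
#' @export
coincidence_matrix <- function(pred_a, pred_b, labelset = NULL) {
  if (length(pred_a) != length(pred_b)) rb_stop("prediction lengths differ", "rb_dim_mismatch")
  if (is.null(labelset)) labelset <- sort(unique(c(as.character(pred_a), as.character(pred_b))))
  a <- match(as.character(pred_a), labelset)
  b <- match(as.character(pred_b), labelset)
  if (anyNA(a) || anyNA(b)) rb_stop("prediction label outside labelset", "rb_invalid_input")
  c_ <- length(labelset)
  m <- matrix(tabulate(a + c_ * (b - 1L), c_ * c_), c_, c_,
              dimnames = list(labelset, labelset)) / length(a)
  m
}

#' Chance-corrected pairwise agreement (kappa)
#'
#' `kappa = (observed agreement - ABC) / (1 - ABC)` where the observed
#' agreement is the trace of the coincidence matrix and the
#' agreement-by-chance is `ABC = sum_k (row_k sum) * (column_k sum)`.
#' Identical decisions give 1; statistically independent decisions give 0.
#' When both marginals are degenerate (`ABC = 1`), the value is 1 if the
#' classifiers fully agree and `NaN` otherwise.
#'
#' @param m a coincidence matrix from [coincidence_matrix()].
#' @return Kappa, a number `<= 1`.
#' @export
kappa_statistic <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || any(m < 0) || abs(sum(m) - 1) > 1e-8) {
    rb_stop("m must be a square matrix of proportions summing to 1", "rb_invalid_input")
  }
  obs <- sum(diag(m))
  abc <- sum(rowSums(m) * colSums(m))
  if (abs(1 - abc) < 1e-12) {
    return(if (obs >= 1 - 1e-12) 1 else NaN)
  }
  (obs - abc) / (1 - abc)
}

#' Kappa-error points for all classifier pairs
#'
#' For every unordered pair of ensemble members, computes the kappa
#' agreement of their predictions and the averaged individual error
#' `E_ab = (E_a + E_b) / 2` against the true labels. The resulting point
#' cloud (one point per pair; low kappa = diverse, low error = accurate) is
#' the kappa-error diagram; [kappa_error_centroid()] summarizes it.
#'
#' @param members a fitted ensemble (anything with a [member_predictions()]
#'   method), or a matrix of member label predictions (one column per
#'   member).
#' @param x evaluation feature matrix (ignored when `members` is already a
#'   prediction matrix).
#' @param y true labels of the evaluation samples.
#' @return Data frame with columns `a`, `b` (member indices), `kappa`,
#'   `avg_error`.
#' @export
kappa_error_points <- function(members, x = NULL, y) {
  preds <- if (is.matrix(members)) members else member_predictions(members, x)
  preds <- as.matrix(preds)
  P <- ncol(preds)
  if (P < 2) rb_stop("need at least 2 ensemble members", "rb_invalid_input")
  if (nrow(preds) != length(y)) rb_stop("prediction/label lengths differ", "rb_dim_mismatch")
  y <- as.character(y)
  labelset <- sort(unique(c(as.character(preds), y)))
  errs <- colMeans(preds != y)
  pairs <- utils::combn(P, 2)
  kap <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    kap[q] <- kappa_statistic(coincidence_matrix(preds[, pairs[1, q]],
                                                 preds[, pairs[2, q]], labelset))
  }
  data.frame(a = pairs[1, ], b = pairs[2, ], kappa = kap,
             avg_error = (errs[pairs[1, ]] + errs[pairs[2, ]]) / 2)
}

#' Centroid of a kappa-error point cloud
#'
#' @param points data frame from [kappa_error_points()].
#' @return Named numeric vector `c(kappa = ..., error = ...)` of coordinate
#'   means (`NaN` kappas from fully degenerate pairs are dropped).
#' @export
kappa_error_centroid <- function(points) {
  if (NROW(points) < 1) rb_stop("need at least one point", "rb_invalid_input")
  c(kappa = mean(points$kappa, na.rm = TRUE), error = mean(points$avg_error))
}

#' Compare two methods with a one-tailed paired t-test
#'
#' Declares `"win"` when method A's per-replicate accuracies are
#' significantly higher than method B's (one-tailed paired t-test at level
#' `alpha`), `"loss"` when significantly lower, and `"tie"` otherwise.
#' Zero-variance differences are decided by sign (all-zero gives a tie).
#'
#' @param acc_a,acc_b equal-length paired accuracy vectors (same
#'   replicates/splits for both methods).
#' @param alpha significance level (default 0.05).
#' @return `"win"`, `"tie"`, or `"loss"` (from A's perspective).
#' @export
compare_methods <- function(acc_a, acc_b, alpha = 0.05) {
  if (length(acc_a) != length(acc_b)) rb_stop("paired vectors must have equal length", "rb_dim_mismatch")
  if (length(acc_a) < 2) rb_stop("need at least 2 paired replicates", "rb_invalid_input")
  d <- acc_a - acc_b
  if (sd(d) == 0) {
    if (d[1] > 0) return("win")
    if (d[1] < 0) return("loss")
    return("tie")
  }
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  if (pt(t_stat, df = n - 1, lower.tail = FALSE) < alpha) return("win")
  if (pt(t_stat, df = n - 1, lower.tail = TRUE) < alpha) return("loss")
  "tie"
}
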