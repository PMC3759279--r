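#' Configuration for a benchmark experiment
#'
#' Bundles the choices of an end-to-end run: which learners to compare,
#' transform, ensemble sizes, selection method, bootstrap replicates, and
#' the master seed. Defaults are the tuned operating point for microarray
#' benchmarks: `S = T = 10` (100 trees in RotBoost), `M = 3` features per
#' rotation subset, 100 trees in the flat ensembles, 15 bootstrap
#' replicates, and a 0.05 significance level.
#'
#' @param methods subset of `"rotboost"`, `"rotation_forest"`, `"adaboost"`,
#'   `"bagging"`, `"tree"`.
#' @param transform `"ica"` or `"pca"` rotation transform for the
#'   rotation-based learners.
#' @param S,T RotBoost outer/inner iteration counts.
#' @param M features per rotation subset.
#' @param trees ensemble size of Rotation Forest, AdaBoost, and bagging.
#' @param n_reps bootstrap replicates.
#' @param select `"fcbf"`, `"gsnr"`, or `"none"`; selection always runs on
#'   each replicate's training samples only unless `select_once = TRUE`.
#' @param threshold FCBF relevance threshold.
#' @param fraction top fraction kept after GSNR ranking.
#' @param alpha significance level of the paired t-test.
#' @param select_once compatibility switch: run feature selection once on
#'   the full data before splitting (biases accuracy upward; off by
#'   default).
#' @param kappa compute kappa-error centroids per method (averaged over the
#'   replicates' out-of-bag sets).
#' @param seed master seed; every random stage derives its stream from it.
#' @return A `RunConfig` list.
#' @export
run_config <- function(methods = c("rotboost", "rotation_forest", "adaboost",
                                   "bagging", "tree"),
                       transform = c("ica", "pca"), S = 10, T = 10, M = 3,
                       trees = 100, n_reps = 15, select = c("fcbf", "gsnr", "none"),
                       threshold = 0, fraction = 0.1, alpha = 0.05,
                       select_once = FALSE, kappa = TRUE, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(methods = methods, transform = match.arg(transform),
                 S = S, T = T, M = M, trees = trees, n_reps = n_reps,
                 select = match.arg(select), threshold = threshold,
                 fraction = fraction, alpha = alpha,
                 select_once = select_once, kappa = kappa, seed = seed),
            class = "RunConfig")
}

# trainers consume the session RNG; run_experiment seeds it per method and
# replicate so the design stays paired and reproducible
make_trainer <- function(method, config) {
  switch(method,
    rotboost = function(x, y) {
      train_rotboost(x, y, S = config$S, n_rounds = config$T, M = config$M,
                     method = config$transform)
    },
    rotation_forest = function(x, y) {
      train_rotation_forest(x, y, L = config$trees, M = config$M,
                            method = config$transform)
    },
    adaboost = function(x, y) train_adaboost(x, y, n_rounds = config$trees),
    bagging = function(x, y) train_bagging(x, y, L = config$trees),
    tree = function(x, y) train_tree(x, y))
}

#' Run the full benchmarking experiment on one dataset
#'
#' Composes the pipeline: impute missing values, then for each of `n_reps`
#' balanced bootstrap replicates draw one shared split, standardize genes on
#' the training half, run the configured feature selection on the training
#' half only, and fit every requested method on the identical selected
#' training data (the paired design the t-test comparison requires).
#' Reports each method's 0.632 bootstrap error and accuracy (mean and
#' standard deviation over replicates), Win-Tie-Loss of RotBoost against
#' each other method, and (optionally) kappa-error centroids of the ensemble
#' members on the out-of-bag samples.
#'
#' @param ds an [expression_dataset()], or a list with `matrix_path` and
#'   `labels_path` to load one from disk.
#' @param config a [run_config()].
#' @param verbose log per-stage progress to stderr.
#' @return A `BenchmarkReport`: list with `table` (per-method summary data
#'   frame), `win_tie_loss` (RotBoost vs each other method), `centroids`
#'   (per-method kappa-error centroid), `accuracy` (replicates x methods
#'   matrix), and `config`.
#' @export
run_experiment <- function(ds, config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  if (!inherits(ds, "ExpressionDataset")) {
    ds <- load_dataset(ds$matrix_path, ds$labels_path)
  }
  log_msg <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  ds <- impute_missing(ds)
  log_msg("imputation done (%.1fs)", proc.time()[3] - t0)

  set.seed(config$seed)
  split_seeds <- draw_subseeds(config$n_reps)
  method_seeds <- matrix(draw_subseeds(config$n_reps * length(config$methods)),
                         nrow = config$n_reps)
  select_fun <- switch(config$select,
    none = NULL,
    fcbf = function(x, y) fcbf_select(x, y, threshold = config$threshold),
    gsnr = function(x, y) retain_top_fraction(gsnr_rank(x, y), config$fraction))
  global_sel <- NULL
  if (config$select_once && !is.null(select_fun)) {
    global_sel <- select_fun(ds$values, ds$labels)$selected
    select_fun <- NULL
  }

  y <- ds$labels
  n_m <- length(config$methods)
  acc <- matrix(NA_real_, config$n_reps, n_m, dimnames = list(NULL, config$methods))
  alpha_err <- beta_err <- acc
  cent_sum <- matrix(0, n_m, 2, dimnames = list(config$methods, c("kappa", "error")))
  cent_n <- setNames(numeric(n_m), config$methods)
  trainers <- lapply(config$methods, make_trainer, config = config)

  for (r in seq_len(config$n_reps)) {
    set.seed(split_seeds[r])
    sp <- balanced_bootstrap_split(y)
    x_tr <- ds$values[sp$train, , drop = FALSE]
    x_te <- ds$values[sp$test, , drop = FALSE]
    y_tr <- y[sp$train]
    y_te <- y[sp$test]
    center <- colMeans(x_tr)
    stats <- list(center = center,
                  scale = sqrt(pmax(colMeans(x_tr^2) - center^2, 0)))
    x_tr <- apply_norm_matrix(x_tr, stats)
    x_te <- apply_norm_matrix(x_te, stats)
    idx <- if (!is.null(global_sel)) {
      global_sel
    } else if (!is.null(select_fun)) {
      set.seed(split_seeds[r] %% 1000000L + 7L)
      s <- select_fun(x_tr, y_tr)
      if (inherits(s, "SelectionResult")) s$selected else as.integer(s)
    } else {
      seq_len(ncol(x_tr))
    }
    if (length(idx) == 0) idx <- seq_len(ncol(x_tr))
    x_tr_s <- x_tr[, idx, drop = FALSE]
    x_te_s <- x_te[, idx, drop = FALSE]
    for (k in seq_len(n_m)) {
      method <- config$methods[k]
      set.seed(method_seeds[r, k])
      model <- trainers[[k]](x_tr_s, y_tr)
      alpha_err[r, k] <- mean(predict(model, x_tr_s) != as.character(y_tr))
      beta_err[r, k] <- mean(predict(model, x_te_s) != as.character(y_te))
      acc[r, k] <- 1 - beta_err[r, k]
      if (config$kappa && method != "tree") {
        mp <- member_predictions(model, x_te_s)
        if (NCOL(mp) >= 2) {  # an early-stopped ensemble may have one member
          pts <- kappa_error_points(as.matrix(mp), y = y_te)
          cen <- kappa_error_centroid(pts)
          if (is.finite(cen["kappa"])) {
            cent_sum[method, ] <- cent_sum[method, ] + cen
            cent_n[method] <- cent_n[method] + 1
          }
        }
      }
    }
    log_msg("replicate %d/%d done (%.1fs, %d genes selected)",
            r, config$n_reps, proc.time()[3] - t0, length(idx))
  }

  table <- data.frame(
    method = config$methods,
    E632 = vapply(seq_len(n_m), function(k) {
      bootstrap_632(cbind(alpha_err[, k], beta_err[, k]))
    }, numeric(1)),
    mean_accuracy = colMeans(acc),
    sd_accuracy = apply(acc, 2, sd),
    row.names = NULL)

  wtl <- NULL
  if ("rotboost" %in% config$methods && n_m > 1) {
    others <- setdiff(config$methods, "rotboost")
    wtl <- setNames(vapply(others, function(mth) {
      compare_methods(acc[, "rotboost"], acc[, mth], alpha = config$alpha)
    }, character(1)), others)
  }
  centroids <- sweep(cent_sum, 1, pmax(cent_n, 1), "/")
  centroids[cent_n == 0, ] <- NA_real_
  structure(list(table = table, win_tie_loss = wtl, centroids = centroids,
                 accuracy = acc, alpha_error = alpha_err, beta_error = beta_err,
                 config = config),
            class = "BenchmarkReport")
}

#' @exportS3Method base::print
print.BenchmarkReport <- function(x, ...) {
  cat("Benchmark report (", x$config$n_reps, " bootstrap replicates)\n", sep = "")
  tab <- x$table
  tab$accuracy <- sprintf("%.2f%% +/- %.2f%%", 100 * tab$mean_accuracy,
                          100 * tab$sd_accuracy)
  print(tab[, c("method", "E632", "accuracy")], row.names = FALSE)
  if (!is.null(x$win_tie_loss)) {
    cat("RotBoost vs others:",
        paste(names(x$win_tie_loss), x$win_tie_loss, sep = "=", collapse = ", "), "\n")
  }
  if (any(is.finite(x$centroids))) {
    cat("kappa-error centroids:\n")
    print(round(x$centroids, 3))
  }
  invisible(x)
}
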