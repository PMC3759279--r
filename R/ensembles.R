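# base learner: unpruned CART tree (Gini, minimum leaf size 1), chosen for
# its sensitivity to training-set perturbations, which is what gives the
# surrounding ensembles their diversity.

tree_control <- function() {
  rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0, xval = 0,
                       maxcompete = 0, maxsurrogate = 0, usesurrogate = 0)
}

#' Train a single classification tree
#'
#' Fits an unpruned CART tree (Gini impurity, minimum leaf size 1) with
#' optional per-sample weights. Single-class inputs yield a constant
#' classifier rather than an error.
#'
#' @param x samples-by-features numeric matrix or an [expression_dataset()].
#' @param y class labels (ignored when `x` is an `ExpressionDataset`).
#' @param weights optional nonnegative per-sample weights.
#' @return An object of class `cart_tree` with a [predict][predict.cart_tree]
#'   method.
#' @export
train_tree <- function(x, y = NULL, weights = NULL) {
  d <- resolve_xy(x, y)
  y <- droplevels(d$y)
  classes <- levels(y)
  if (length(classes) < 2) {
    return(structure(list(constant = classes[1], classes = classes),
                     class = "cart_tree"))
  }
  if (!is.null(weights)) {
    if (any(weights < 0)) rb_stop("weights must be nonnegative", "rb_invalid_input")
    pos <- weights > 0
    if (sum(pos) < nrow(d$x)) {
      # rpart mishandles exact-zero weights; drop those rows instead
      d$x <- d$x[pos, , drop = FALSE]
      y <- y[pos]
      weights <- weights[pos]
      if (nlevels(droplevels(y)) < 2) {
        return(structure(list(constant = as.character(droplevels(y))[1], classes = classes),
                         class = "cart_tree"))
      }
    }
  }
  df <- as.data.frame(d$x)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- droplevels(y)
  fit <- rpart::rpart(.y ~ ., data = df, weights = weights, method = "class",
                      parms = list(split = "gini"), control = tree_control())
  structure(list(fit = fit, classes = classes, p = ncol(d$x)), class = "cart_tree")
}

#' Predict from a single classification tree
#'
#' @param object a `cart_tree`.
#' @param newdata matrix with the training feature count.
#' @param type `"class"` for labels, `"prob"` for a class-probability matrix
#'   (columns named by class).
#' @param ... unused.
#' @return Character vector of labels or a probability matrix.
#' @export
predict.cart_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  if (!is.null(object$constant)) {
    if (type == "class") return(rep(object$constant, n))
    pr <- matrix(0, n, length(object$classes), dimnames = list(NULL, object$classes))
    pr[, object$constant] <- 1
    return(pr)
  }
  df <- as.data.frame(newdata)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  pr_fit <- predict(object$fit, newdata = df, type = "prob")
  pr <- matrix(0, n, length(object$classes), dimnames = list(NULL, object$classes))
  pr[, colnames(pr_fit)] <- pr_fit
  if (type == "prob") return(pr)
  object$classes[argmax_row(pr)]
}

#' Train an AdaBoost.M1 ensemble of trees
#'
#' Boosts unpruned CART trees with the multiclass AdaBoost.M1 rule: fit a
#' tree under the current sample weights, compute its weighted error
#' `eps_t`, set the vote weight `alpha_t = log((1 - eps_t) / eps_t)`,
#' multiply the weights of misclassified samples by `exp(alpha_t)` and
#' renormalize. A round with `eps_t = 0` keeps the tree with a capped alpha
#' and stops early; a round with `eps_t >= 0.5` resets the weights to
#' uniform and retries (at most 3 times) before stopping.
#'
#' @inheritParams train_tree
#' @param n_rounds boosting rounds `T`.
#' @param resample if `TRUE`, each round trains on a weight-proportional
#'   bootstrap resample instead of passing weights to the tree fitter.
#' @return An object of class `adaboost`: list with `trees`, `alphas`,
#'   `classes`.
#' @export
train_adaboost <- function(x, y = NULL, n_rounds = 10, resample = FALSE) {
  d <- resolve_xy(x, y)
  y <- droplevels(d$y)
  if (n_rounds < 1) rb_stop("n_rounds must be >= 1", "rb_invalid_input")
  N <- nrow(d$x)
  classes <- levels(y)
  w <- rep(1 / N, N)
  trees <- list()
  alphas <- numeric(0)
  retries <- 0L
  alpha_cap <- log(1e10)
  while (length(trees) < n_rounds) {
    if (resample) {
      idx <- sample.int(N, N, replace = TRUE, prob = w)
      tree <- train_tree(d$x[idx, , drop = FALSE], y[idx])
    } else {
      tree <- train_tree(d$x, y, weights = w)
    }
    pred <- predict(tree, d$x, type = "class")
    mis <- pred != as.character(y)
    eps <- sum(w[mis])
    if (eps >= 0.5) {
      if (retries < 3L) {
        w <- rep(1 / N, N)
        retries <- retries + 1L
        next
      }
      break
    }
    if (eps <= 0) {
      trees[[length(trees) + 1L]] <- tree
      alphas <- c(alphas, alpha_cap)
      break
    }
    alpha <- log((1 - eps) / eps)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w[mis] <- w[mis] * exp(alpha)
    w <- w / sum(w)
  }
  if (length(trees) == 0) {  # every attempt hit eps >= 0.5: keep one tree
    tree <- train_tree(d$x, y)
    trees <- list(tree)
    alphas <- 1e-10
  }
  structure(list(trees = trees, alphas = alphas, classes = classes),
            class = "adaboost")
}

# alpha-weighted hard votes of an adaboost ensemble, normalized to a
# per-sample class distribution over `classes` (a superset of the model's)
adaboost_scores <- function(model, x, classes = model$classes) {
  n <- nrow(as.matrix(x))
  scores <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (t in seq_along(model$trees)) {
    pred <- predict(model$trees[[t]], x, type = "class")
    scores[cbind(seq_len(n), match(pred, classes))] <-
      scores[cbind(seq_len(n), match(pred, classes))] + model$alphas[t]
  }
  rs <- rowSums(scores)
  zero <- rs <= 0
  if (any(zero)) {
    scores[zero, ] <- 1 / length(classes)
    rs[zero] <- 1
  }
  scores / rs
}

#' Predict from an AdaBoost ensemble
#'
#' @param object an `adaboost` model.
#' @param newdata feature matrix.
#' @param type `"class"` or `"prob"` (normalized alpha-weighted votes).
#' @param ... unused.
#' @export
predict.adaboost <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  scores <- adaboost_scores(object, newdata)
  if (type == "prob") return(scores)
  object$classes[argmax_row(scores)]
}

#' Train a RotBoost ensemble
#'
#' The package's core learner: for each of `S` outer iterations a sparse
#' block rotation of the gene space is built (random disjoint feature
#' subsets of size `M`, per-subset class subsampling and 75% bootstrap, PCA
#' or FastICA fitted per subset with all components kept), the full training
#' set is rotated, and an AdaBoost.M1 ensemble of `n_rounds` trees is
#' trained on the rotated data. The `S` inner ensembles are mutually
#' independent given their seeds. With `S * n_rounds` trees in total, the
#' defaults `S = n_rounds = 10`, `M = 3` give the usual 100-tree ensemble.
#'
#' @inheritParams train_tree
#' @param S outer rotation iterations.
#' @param n_rounds inner AdaBoost rounds `T` per rotation.
#' @param M features per rotation subset.
#' @param method subset transform: `"ica"` (default), `"pca"`, or
#'   `"identity"` (no rotation; useful for reductions and debugging).
#' @param boot_frac bootstrap fraction inside each subset transform fit.
#' @param resample passed to [train_adaboost()].
#' @param seed optional integer seed for the whole training run.
#' @return An object of class `rotboost`: list with `rotations`, `inner`
#'   (the AdaBoost ensembles), `classes`, and the run parameters.
#' @examples
#' sim <- generate_synthetic(synthetic_spec(N = 40, n = 20, n_informative = 4,
#'                                          missing_rate = 0, seed = 1))
#' fit <- train_rotboost(sim$dataset, S = 2, n_rounds = 2, seed = 1)
#' table(predict(fit, sim$dataset$values), sim$dataset$labels)
#' @export
train_rotboost <- function(x, y = NULL, S = 10, n_rounds = 10, M = 3,
                           method = c("ica", "pca", "identity"),
                           boot_frac = 0.75, resample = FALSE, seed = NULL) {
  method <- match.arg(method)
  d <- resolve_xy(x, y)
  y <- droplevels(d$y)
  if (S < 1 || n_rounds < 1) rb_stop("S and n_rounds must be >= 1", "rb_invalid_input")
  maybe_set_seed(seed)
  rotations <- vector("list", S)
  inner <- vector("list", S)
  for (s in seq_len(S)) {
    rotations[[s]] <- build_rotation(d$x, y, M = M, method = method,
                                     boot_frac = boot_frac)
    xr <- apply_rotation(d$x, rotations[[s]])
    inner[[s]] <- train_adaboost(xr, y, n_rounds = n_rounds, resample = resample)
  }
  structure(list(rotations = rotations, inner = inner, classes = levels(y),
                 S = S, T = n_rounds, M = M, method = method),
            class = "rotboost")
}

#' Predict from a RotBoost model
#'
#' Each rotation's inner AdaBoost ensemble produces a class distribution
#' from its normalized alpha-weighted votes on the rotated input; the
#' per-class confidences are averaged over the `S` rotations and the class
#' with the largest confidence wins (ties to the lowest class index).
#'
#' @param object a `rotboost` model.
#' @param newdata matrix with the training feature count.
#' @param type `"class"` or `"prob"` (the averaged confidence vector; rows
#'   sum to 1).
#' @param ... unused.
#' @export
predict.rotboost <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  phi <- matrix(0, nrow(newdata), length(object$classes),
                dimnames = list(NULL, object$classes))
  for (s in seq_along(object$rotations)) {
    xr <- apply_rotation(newdata, object$rotations[[s]])
    phi <- phi + adaboost_scores(object$inner[[s]], xr, object$classes)
  }
  phi <- phi / length(object$rotations)
  if (type == "prob") return(phi)
  object$classes[argmax_row(phi)]
}

#' Train a Rotation Forest
#'
#' `L` unweighted trees, each trained on the full training set rotated by
#' its own sparse block rotation (same rotation construction as
#' [train_rotboost()]). Prediction averages the trees' class-probability
#' distributions on their rotated inputs and takes the class with the
#' largest average confidence.
#'
#' @inheritParams train_rotboost
#' @param L ensemble size (number of trees/rotations).
#' @return An object of class `rotation_forest`.
#' @export
train_rotation_forest <- function(x, y = NULL, L = 100, M = 3,
                                  method = c("pca", "ica", "identity"),
                                  boot_frac = 0.75, seed = NULL) {
  method <- match.arg(method)
  d <- resolve_xy(x, y)
  y <- droplevels(d$y)
  if (L < 1) rb_stop("L must be >= 1", "rb_invalid_input")
  maybe_set_seed(seed)
  rotations <- vector("list", L)
  trees <- vector("list", L)
  for (i in seq_len(L)) {
    rotations[[i]] <- build_rotation(d$x, y, M = M, method = method,
                                     boot_frac = boot_frac)
    xr <- apply_rotation(d$x, rotations[[i]])
    trees[[i]] <- train_tree(xr, y)
  }
  structure(list(rotations = rotations, trees = trees, classes = levels(y),
                 L = L, M = M, method = method),
            class = "rotation_forest")
}

#' Predict from a Rotation Forest
#'
#' @param object a `rotation_forest`.
#' @param newdata feature matrix.
#' @param type `"class"` or `"prob"` (average of per-tree class
#'   probabilities; rows sum to 1).
#' @param ... unused.
#' @export
predict.rotation_forest <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  phi <- matrix(0, nrow(newdata), length(object$classes),
                dimnames = list(NULL, object$classes))
  for (i in seq_along(object$trees)) {
    xr <- apply_rotation(newdata, object$rotations[[i]])
    pr <- predict(object$trees[[i]], xr, type = "prob")
    phi[, colnames(pr)] <- phi[, colnames(pr)] + pr
  }
  phi <- phi / length(object$trees)
  if (type == "prob") return(phi)
  object$classes[argmax_row(phi)]
}

#' Train a bagged tree ensemble
#'
#' `L` unpruned trees, each on a bootstrap resample of the full training set
#' of the same size `N`. Prediction is by plurality vote (ties to the lowest
#' class index).
#'
#' @inheritParams train_rotation_forest
#' @return An object of class `bagging`.
#' @export
train_bagging <- function(x, y = NULL, L = 100, seed = NULL) {
  d <- resolve_xy(x, y)
  y <- droplevels(d$y)
  if (L < 1) rb_stop("L must be >= 1", "rb_invalid_input")
  maybe_set_seed(seed)
  N <- nrow(d$x)
  trees <- vector("list", L)
  for (i in seq_len(L)) {
    idx <- sample.int(N, N, replace = TRUE)
    trees[[i]] <- train_tree(d$x[idx, , drop = FALSE], y[idx])
  }
  structure(list(trees = trees, classes = levels(y), L = L), class = "bagging")
}

#' Predict from a bagged ensemble by majority vote
#'
#' @param object a `bagging` model.
#' @param newdata feature matrix.
#' @param type `"class"` or `"prob"` (vote fractions).
#' @param ... unused.
#' @export
predict.bagging <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  votes <- matrix(0, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (i in seq_along(object$trees)) {
    pred <- predict(object$trees[[i]], newdata, type = "class")
    votes[cbind(seq_len(n), match(pred, object$classes))] <-
      votes[cbind(seq_len(n), match(pred, object$classes))] + 1
  }
  votes <- votes / length(object$trees)
  if (type == "prob") return(votes)
  object$classes[argmax_row(votes)]
}

#' Per-member predictions of an ensemble
#'
#' Returns the individual base classifiers' label predictions, one column
#' per member, for diversity analyses such as [kappa_error_points()]. For
#' `rotboost` the members are all `S x T` trees, each seeing the input under
#' its own rotation.
#'
#' @param model a fitted `rotboost`, `rotation_forest`, `bagging`, or
#'   `adaboost` object.
#' @param x evaluation feature matrix.
#' @return Character matrix, `nrow(x)` rows by one column per member.
#' @export
member_predictions <- function(model, x) {
  UseMethod("member_predictions")
}

#' @export
member_predictions.adaboost <- function(model, x) {
  sapply(model$trees, function(tr) predict(tr, x, type = "class"))
}

#' @export
member_predictions.bagging <- member_predictions.adaboost

#' @export
member_predictions.rotation_forest <- function(model, x) {
  sapply(seq_along(model$trees), function(i) {
    predict(model$trees[[i]], apply_rotation(x, model$rotations[[i]]), type = "class")
  })
}

#' @export
member_predictions.rotboost <- function(model, x) {
  cols <- list()
  for (s in seq_along(model$rotations)) {
    xr <- apply_rotation(x, model$rotations[[s]])
    for (tr in model$inner[[s]]$trees) {
      cols[[length(cols) + 1L]] <- predict(tr, xr, type = "class")
    }
  }
  do.call(cbind, cols)
}
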