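test_that("a single tree fits separable data perfectly and handles edge inputs", {
  d <- make_separable(60, 5, seed = 1)
  tr <- train_tree(d$x, d$y)
  expect_equal(predict(tr, d$x), as.character(d$y))
  pr <- predict(tr, d$x, type = "prob")
  expect_equal(dim(pr), c(60, 2))
  expect_equal(rowSums(pr), rep(1, 60))
  # single-class input -> constant classifier
  const <- train_tree(d$x[d$y == "a", ], d$y[d$y == "a"])
  expect_equal(unique(predict(const, d$x)), "a")
  # weights: zero-weight rows are ignored in the fit
  w <- ifelse(d$y == "a", 1, 0)
  wa <- train_tree(d$x, d$y, weights = w)
  expect_equal(unique(predict(wa, d$x)), "a")
  expect_error(train_tree(d$x, d$y, weights = rep(-1, 60)), class = "rb_invalid_input")
})

test_that("AdaBoost weighted training error is non-increasing in rounds", {
  # on a noisy but learnable problem, more rounds never hurt the training fit
  violations <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    N <- 80
    y <- factor(rep(c("a", "b"), each = N / 2))
    x <- matrix(rnorm(N * 4), N, 4)
    x[, 1] <- x[, 1] + ifelse(y == "a", 1, -1)
    errs <- sapply(c(1, 5, 10), function(Tn) {
      set.seed(1000 + s)
      fit <- train_adaboost(x, y, n_rounds = Tn)
      mean(predict(fit, x) != as.character(y))
    })
    if (errs[2] > errs[1] + 1e-12 || errs[3] > errs[2] + 1e-12) violations <- violations + 1
  }
  expect_equal(violations, 0)
})

test_that("AdaBoost stops early on a perfect first tree and caps its vote", {
  d <- make_separable(40, 3, seed = 2)
  fit <- train_adaboost(d$x, d$y, n_rounds = 10)
  expect_equal(length(fit$trees), 1)       # eps = 0 stop
  expect_equal(fit$alphas, log(1e10))
  expect_equal(predict(fit, d$x), as.character(d$y))
})

test_that("RotBoost structure, determinism, and probability outputs are sound", {
  d <- make_separable(40, 9, seed = 3)
  f1 <- train_rotboost(d$x, d$y, S = 3, n_rounds = 2, M = 3, method = "pca", seed = 7)
  f2 <- train_rotboost(d$x, d$y, S = 3, n_rounds = 2, M = 3, method = "pca", seed = 7)
  expect_identical(predict(f1, d$x), predict(f2, d$x))
  expect_equal(length(f1$rotations), 3)
  pr <- predict(f1, d$x, type = "prob")
  expect_equal(rowSums(pr), rep(1, 40))
  expect_true(all(pr >= 0))
  # prediction = argmax of the averaged confidences, ties to lowest index
  expect_identical(predict(f1, d$x), f1$classes[max.col(pr, ties.method = "first")])
  # member predictions expose every inner tree (early stopping on clean
  # data can shorten the inner ensembles, so S <= members <= S * T)
  mp <- member_predictions(f1, d$x)
  expect_equal(nrow(mp), 40)
  expect_equal(ncol(mp), sum(lengths(lapply(f1$inner, `[[`, "trees"))))
  expect_gte(ncol(mp), 3); expect_lte(ncol(mp), 6)
})

test_that("RotBoost with T = 1 reduces to a Rotation Forest under a shared seed", {
  d <- make_separable(50, 9, seed = 4)
  rb <- train_rotboost(d$x, d$y, S = 5, n_rounds = 1, M = 3, method = "pca", seed = 11)
  rf <- train_rotation_forest(d$x, d$y, L = 5, M = 3, method = "pca", seed = 11)
  xt <- matrix(rnorm(30 * 9), 30, 9)
  expect_identical(predict(rb, xt), predict(rf, xt))
})

test_that("RotBoost with S = 1 and identity rotation reduces to AdaBoost", {
  set.seed(5)
  N <- 60
  y <- factor(rep(c("a", "b"), each = 30))
  x <- matrix(rnorm(N * 6), N, 6)
  x[, 2] <- x[, 2] + ifelse(y == "a", 1.2, -1.2)
  rb <- train_rotboost(x, y, S = 1, n_rounds = 5, method = "identity", seed = 13)
  set.seed(13)
  ab <- train_adaboost(x, y, n_rounds = 5)
  xt <- matrix(rnorm(25 * 6), 25, 6)
  expect_identical(predict(rb, xt), predict(ab, xt))
})

test_that("baseline ensembles train, predict, and expose members", {
  d <- make_separable(50, 6, seed = 6)
  xt <- d$x + matrix(rnorm(300, sd = 0.1), 50, 6)
  for (fit in list(train_bagging(d$x, d$y, L = 7, seed = 1),
                   train_rotation_forest(d$x, d$y, L = 7, M = 2, seed = 1))) {
    pred <- predict(fit, xt)
    expect_length(pred, 50)
    expect_true(all(pred %in% c("a", "b")))
    expect_gt(mean(pred == as.character(d$y)), 0.9)
    mp <- member_predictions(fit, xt)
    expect_equal(dim(mp), c(50, 7))
    pr <- predict(fit, xt, type = "prob")
    expect_equal(rowSums(pr), rep(1, 50))
  }
})

test_that("multiclass prediction works end to end", {
  set.seed(8)
  N <- 90
  y <- factor(rep(c("a", "b", "c"), each = 30))
  x <- matrix(rnorm(N * 6), N, 6)
  x[, 1] <- x[, 1] + c(a = 3, b = 0, c = -3)[as.character(y)]
  x[, 2] <- x[, 2] + c(a = 0, b = 3, c = -3)[as.character(y)]
  fit <- train_rotboost(x, y, S = 3, n_rounds = 3, M = 2, method = "pca", seed = 2)
  expect_gt(mean(predict(fit, x) == as.character(y)), 0.95)
  pr <- predict(fit, x, type = "prob")
  expect_equal(ncol(pr), 3)
  expect_equal(rowSums(pr), rep(1, N))
})
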