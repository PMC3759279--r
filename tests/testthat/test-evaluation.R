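test_that("balanced bootstrap split is class-stratified with out-of-bag test set", {
  for (s in 1:10) {
    set.seed(500 + s)
    y <- factor(rep(c("a", "b", "c"), times = c(20, 15, 10)))
    sp <- balanced_bootstrap_split(y)
    expect_length(sp$train, length(y))
    # per-class draw counts match the class sizes exactly
    expect_equal(as.numeric(table(y[sp$train])), c(20, 15, 10))
    # test set = samples never drawn, and every class is represented
    expect_identical(sp$test, setdiff(seq_along(y), sp$train))
    expect_true(all(levels(y) %in% y[sp$test]))
  }
  expect_error(balanced_bootstrap_split(factor("a")), class = "rb_invalid_input")
})

test_that("bootstrap_632 applies the fixed weights and validates input", {
  reps <- cbind(alpha = c(0.1, 0.2, 0), beta = c(0.3, 0.25, 0.5))
  expect_equal(bootstrap_632(reps),
               mean(0.368 * reps[, 1] + 0.632 * reps[, 2]), tolerance = 1e-15)
  # list-of-pairs input
  expect_equal(bootstrap_632(list(c(0.1, 0.3), c(0.2, 0.25), c(0, 0.5))),
               bootstrap_632(reps))
  expect_error(bootstrap_632(cbind(1.2, 0.1)), class = "rb_invalid_input")
  expect_error(bootstrap_632(matrix(0, 0, 2)), class = "rb_invalid_input")
  # adaptive variant: gamma required; with beta = alpha it matches a
  # plain 0.632-weighted combination (no overfitting -> weight 0.632)
  expect_error(bootstrap_632(reps, adaptive = TRUE), class = "rb_invalid_input")
  same <- cbind(0.2, 0.2)
  expect_equal(bootstrap_632(same, adaptive = TRUE, gamma = 0.5),
               0.368 * 0.2 + 0.632 * 0.2, tolerance = 1e-12)
})

test_that("evaluate_method is deterministic and measures a perfect learner as ~0", {
  d <- make_separable(40, 4, seed = 7)
  ds <- expression_dataset(d$x, labels = d$y)
  trainer <- function(x, y) train_tree(x, y)
  e1 <- evaluate_method(ds, trainer, n_reps = 5, seed = 3)
  e2 <- evaluate_method(ds, trainer, n_reps = 5, seed = 3)
  expect_equal(e1$replicates, e2$replicates)
  expect_lt(e1$E, 0.05)        # 4-sd separated classes: near-zero error
  expect_gt(e1$mean_accuracy, 0.95)
  expect_equal(e1$E, bootstrap_632(e1$replicates[, c("alpha", "beta")]))
  expect_equal(e1$mean_accuracy, mean(1 - e1$replicates$beta))
})

test_that("split-level selection uses only training rows", {
  d <- make_separable(40, 6, seed = 8)
  ds <- expression_dataset(d$x, labels = d$y)
  seen_rows <- integer(0)
  selector <- function(x, y) {
    seen_rows <<- c(seen_rows, nrow(x))
    1:2
  }
  ev <- evaluate_method(ds, function(x, y) train_tree(x, y),
                        n_reps = 3, selector = selector, seed = 5)
  expect_equal(seen_rows, rep(40, 3))  # bootstrap training sets, never the full + test data
  expect_s3_class(ev, "BootstrapEstimate")
})

test_that("coincidence matrix and kappa match the independent oracle", {
  set.seed(21)
  labelset <- c("a", "b", "c")
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    pa <- sample(labelset, n, replace = TRUE)
    pb <- sample(labelset, n, replace = TRUE)
    m <- coincidence_matrix(pa, pb, labelset)
    expect_equal(sum(m), 1, tolerance = 1e-12)
    k <- kappa_statistic(m)
    ko <- oracle_kappa(pa, pb, labelset)
    if (is.nan(ko)) expect_true(is.nan(k)) else expect_equal(k, ko, tolerance = 1e-12)
    # symmetry
    expect_equal(k, kappa_statistic(coincidence_matrix(pb, pa, labelset)))
  }
})

test_that("kappa hits its documented anchor values", {
  expect_equal(kappa_statistic(matrix(c(0.5, 0, 0, 0.5), 2, 2)), 1)
  # factorizing joint -> 0
  p <- c(0.6, 0.4)
  expect_equal(kappa_statistic(outer(p, p)), 0, tolerance = 1e-12)
  expect_equal(kappa_statistic(matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)), 0.6,
               tolerance = 1e-12)
  # degenerate marginals (both classifiers constant): full agreement -> 1
  expect_equal(kappa_statistic(matrix(c(1, 0, 0, 0), 2, 2)), 1)
  # one constant classifier disagreeing with a varying one: ABC = 0, kappa = obs
  expect_equal(kappa_statistic(matrix(c(0, 1, 0, 0), 2, 2)), 0)
  expect_error(kappa_statistic(matrix(c(0.5, 0.4), 1, 2)), class = "rb_invalid_input")
})

test_that("kappa-error points cover all pairs and the centroid averages them", {
  d <- make_separable(40, 6, seed = 9)
  fit <- train_bagging(d$x, d$y, L = 6, seed = 2)
  pts <- kappa_error_points(fit, d$x, d$y)
  expect_equal(nrow(pts), choose(6, 2))
  expect_true(all(pts$kappa <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(pts$avg_error >= 0 & pts$avg_error <= 1))
  cen <- kappa_error_centroid(pts)
  expect_equal(unname(cen["error"]), mean(pts$avg_error))
  # prediction-matrix input agrees with the model input
  pts2 <- kappa_error_points(member_predictions(fit, d$x), y = d$y)
  expect_equal(pts, pts2)
})

test_that("paired t-test comparison decides win/tie/loss correctly", {
  set.seed(33)
  base <- runif(15, 0.7, 0.9)
  expect_equal(compare_methods(base + 0.1, base), "win")
  expect_equal(compare_methods(base, base + 0.1), "loss")
  # exactly mean-zero noise: t statistic is 0 -> tie
  expect_equal(compare_methods(base + rep(c(0.001, -0.001), length.out = 15) -
                                 mean(rep(c(0.001, -0.001), length.out = 15)), base), "tie")
  # zero-variance differences are decided by sign
  expect_equal(compare_methods(rep(0.9, 5), rep(0.8, 5)), "win")
  expect_equal(compare_methods(rep(0.8, 5), rep(0.9, 5)), "loss")
  expect_equal(compare_methods(rep(0.8, 5), rep(0.8, 5)), "tie")
  expect_error(compare_methods(1:3 / 3, 1:4 / 4), class = "rb_dim_mismatch")
})
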