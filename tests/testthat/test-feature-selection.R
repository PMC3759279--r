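test_that("MDL discretization splits a perfectly separating gene and not pure noise", {
  ds <- make_abc_dataset()
  dA <- discretize_feature(ds$values[, "A"], ds$labels)
  expect_equal(length(unique(dA)), 2)
  expect_equal(length(unique(paste(dA, ds$labels))), 2)  # codes align with classes
  # a class-independent constant-ish noise gene collapses to one bin
  set.seed(42)
  noise <- rnorm(100)
  y <- factor(rep(c("a", "b"), 50))
  dn <- discretize_feature(noise, y)
  expect_equal(length(unique(dn)), 1)
  # cut points attribute respects the midpoint convention
  cuts <- attr(dA, "cuts")
  expect_equal(cuts, 4.5)  # midpoint of the 0/9 boundary
})

test_that("symmetric uncertainty matches the table-based oracle and its bounds", {
  set.seed(7)
  for (rep in 1:25) {
    a <- sample.int(3, 40, replace = TRUE)
    b <- sample.int(4, 40, replace = TRUE)
    expect_equal(symmetric_uncertainty(a, b), oracle_su(a, b), tolerance = 1e-12)
  }
  a <- sample.int(3, 40, replace = TRUE)
  expect_equal(symmetric_uncertainty(a, a), 1)               # identical -> 1
  expect_equal(symmetric_uncertainty(a, rep(1L, 40)), 0)     # constant -> 0
  expect_equal(symmetric_uncertainty(rep(1L, 40), rep(2L, 40)), 0)
  b <- sample.int(4, 40, replace = TRUE)
  expect_equal(symmetric_uncertainty(a, b), symmetric_uncertainty(b, a))
  su <- symmetric_uncertainty(a, b)
  expect_gte(su, 0); expect_lte(su, 1)
})

test_that("FCBF drops an exact duplicate of a relevant gene and keeps the noise out", {
  ds <- make_abc_dataset()
  sel <- fcbf_select(ds)
  expect_equal(sel$selected, 1L)      # gene A kept, its copy B eliminated, C irrelevant
  expect_length(sel$scores, 3)
  expect_equal(sel$scores[1], sel$scores[2])  # exact copy scores identically
})

test_that("FCBF agrees with the brute-force oracle on random small panels", {
  for (s in 1:10) {
    set.seed(100 + s)
    N <- 40
    p <- sample(5:12, 1)
    y <- factor(rep(c("a", "b"), length.out = N))
    x <- matrix(rnorm(N * p), N, p)
    # plant a few informative genes with varying strength
    k <- sample(2:4, 1)
    for (j in seq_len(k)) x[, j] <- x[, j] + ifelse(y == "a", 1, -1) * runif(1, 0.8, 2.5)
    sel <- fcbf_select(x, y)
    expect_identical(sel$selected, as.integer(oracle_fcbf(x, y)))
  }
})

test_that("FCBF relevance threshold and empty-selection warning behave as documented", {
  set.seed(3)
  x <- matrix(rnorm(60 * 8), 60, 8)
  y <- factor(rep(c("a", "b"), 30))
  expect_warning(sel <- fcbf_select(x, y, threshold = 0.99), "relevance threshold")
  expect_length(sel$selected, 0)
  expect_s3_class(as.data.frame(fcbf_select(make_abc_dataset())), "data.frame")
})

test_that("FCBF selects almost nothing from pure noise at a small positive threshold", {
  # empirically calibrated null behavior: the per-gene null SU distribution
  # puts ~1% of 200 noise genes above threshold 0.05 at N = 60, so the mean
  # selection count over seeds stays tiny (but is not exactly zero)
  counts <- integer(20)
  for (s in 1:20) {
    set.seed(1300 + s)
    x <- matrix(rnorm(60 * 200), 60, 200)
    y <- factor(rep(c("a", "b"), 30))
    counts[s] <- length(suppressWarnings(fcbf_select(x, y, threshold = 0.05))$selected)
  }
  # expected ~1.8/seed; 3 leaves > 4 standard errors of slack for the mean
  expect_lte(mean(counts), 3)
  expect_lte(max(counts), 15)
})

test_that("GSNR ranking orders genes by discriminative power with documented edge cases", {
  set.seed(11)
  N <- 80
  y <- factor(rep(c("a", "b"), each = 40))
  strong <- rnorm(N, ifelse(y == "a", 3, -3), 1)
  weak <- rnorm(N, ifelse(y == "a", 0.3, -0.3), 1)
  noise <- rnorm(N)
  const <- rep(2, N)                       # between = 0 -> score 0
  pure <- ifelse(y == "a", 1, -1)          # within = 0, between > 0 -> Inf
  x <- cbind(strong, weak, noise, const, pure)
  r <- gsnr_rank(x, y)
  sc <- unname(r$scores)
  expect_equal(sc[4], 0)
  expect_true(is.infinite(sc[5]))
  expect_gt(sc[1], sc[2])
  expect_gt(sc[2], sc[3])
  # hand-checked value on a tiny case: x = (0,2,4,6), y = (a,a,b,b)
  # means 1 and 5, grand 3, between = .5*4 + .5*4 = 4; within = .5*1 + .5*1 = 1
  tiny <- gsnr_rank(cbind(g = c(0, 2, 4, 6)), factor(c("a", "a", "b", "b")))
  expect_equal(unname(tiny$scores), 4, tolerance = 1e-12)
})

test_that("retain_top_fraction keeps ceiling(fraction * n) genes in rank order", {
  set.seed(5)
  y <- factor(rep(c("a", "b"), each = 20))
  x <- matrix(rnorm(40 * 25), 40, 25)
  x[, 7] <- x[, 7] + ifelse(y == "a", 4, -4)
  r <- gsnr_rank(x, y)
  top <- retain_top_fraction(r, 0.1)
  expect_length(top$selected, ceiling(0.1 * 25))
  expect_equal(top$selected[1], 7L)
  expect_length(retain_top_fraction(r, 1)$selected, 25)
})
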