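test_that("spearman_rs matches the brute-force rank oracle to 1e-12", {
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- if (i %% 3 == 0) sample(x) + rnorm(n, 0, 0.1) else rnorm(n)
    if (i %% 5 == 0) { x <- round(x); y <- round(y) }   # force ties
    if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) next
    worst <- max(worst, abs(spearman_rs(x, y)$rs - oracle_spearman(x, y)))
  }
  expect_lt(worst, 1e-12)
})

test_that("spearman_rs agrees with cor.test and handles canonical cases", {
  x <- 1:5
  expect_equal(spearman_rs(x, x)$rs, 1)
  expect_equal(spearman_rs(x, rev(x))$rs, -1)

  # frozen from the rank oracle: d^2 sum = 4 -> 1 - 6*4/(5*24) = 0.8
  y <- c(1, 3, 2, 5, 4)
  expect_equal(oracle_spearman(x, y), 0.8, tolerance = 1e-12)
  expect_equal(spearman_rs(x, y)$rs, 0.8, tolerance = 1e-12)

  set.seed(4)
  a <- rnorm(30); b <- a + rnorm(30)
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  expect_equal(spearman_rs(a, b)$rs, unname(ct$estimate), tolerance = 1e-12)

  expect_error(spearman_rs(rep(1, 5), 1:5), "zero rank variance")
  expect_error(spearman_rs(1:4, 1:5), "equal length")
  expect_error(spearman_rs(1:2, 2:1), "at least 3")
})

test_that("exact permutation p agrees with the t approximation in direction", {
  set.seed(7)
  x <- rnorm(6); y <- x + rnorm(6, 0, 0.3)
  ex <- spearman_rs(x, y, exact = TRUE)
  ap <- spearman_rs(x, y)
  expect_equal(ex$rs, ap$rs)
  expect_lt(ex$p, 0.2)
  expect_error(spearman_rs(rnorm(9), rnorm(9), exact = TRUE), "n <= 8")
})

test_that("profile correlation drops the null column leaving n = 200", {
  set.seed(12)
  pa <- matrix(rnorm(220), 20, 11); pa[, 1] <- 0
  pb <- matrix(rnorm(220), 20, 11); pb[, 1] <- 0
  r <- profile_correlation(pa, pb)
  expect_equal(r$n, 200)
  expect_equal(profile_correlation(pa, pa)$rs, 1)
  # rank invariance under positive scaling
  expect_equal(profile_correlation(pa, 2 * pa)$rs, 1)
  r_all <- profile_correlation(pa, pb, exclude_null = FALSE)
  expect_equal(r_all$n, 220)
  expect_error(profile_correlation(pa, pb[, 1:10]), "shape")
})

test_that("per-expression correlations apply the Bonferroni rule at m = 7", {
  set.seed(2)
  a <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  pa <- structure(list(responses = a, n_runs = 1, normalization = "raw",
                       group = "A"), class = "tuning_profiles")
  tab <- per_expression_correlations(pa, pa)
  expect_equal(tab$rs, rep(1, 7))
  expect_identical(tab$expression, EXPRESSIONS)

  # a p of 0.0090 is not significant under Bonferroni at alpha = 0.05 / 7
  expect_false(0.0090 < 0.05 / 7)
  expect_true(0.0001 < 0.05 / 7)
})

test_that("cross-correlation matrix covers all 49 pairs and transposes cleanly", {
  set.seed(3)
  a <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  b <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  pa <- structure(list(responses = a, n_runs = 1, normalization = "raw",
                       group = "A"), class = "tuning_profiles")
  pb <- structure(list(responses = b, n_runs = 1, normalization = "raw",
                       group = "B"), class = "tuning_profiles")
  mA <- cross_correlation_matrix(pa, pb, "A")
  mB <- cross_correlation_matrix(pa, pb, "B")
  expect_identical(dim(unclass(mA)), c(7L, 7L))
  expect_equal(unclass(mB), t(unclass(mA)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(mA, "row_group"), "A")
  expect_identical(attr(mB, "row_group"), "B")
  expect_equal(attr(mA, "n"), 200)
  self <- cross_correlation_matrix(pa, pa, "A")
  expect_equal(unname(diag(unclass(self))), rep(1, 7))
})

test_that("correlation-vs-confusion respects monotone invariance and axis rules", {
  set.seed(6)
  a <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  b <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  pa <- structure(list(responses = a, n_runs = 1, normalization = "raw",
                       group = "A"), class = "tuning_profiles")
  pb <- structure(list(responses = b, n_runs = 1, normalization = "raw",
                       group = "B"), class = "tuning_profiles")
  corr_ba <- cross_correlation_matrix(pa, pb, "B")  # rows = B profiles
  # confusion: true labels from B's database, nets trained on A
  conf <- structure(plogis(3 * unclass(corr_ba)),
                    class = c("confusion_matrix", "matrix"),
                    condition = "swapped", train_db = "A", test_db = "B")
  r <- correlate_with_confusion(corr_ba, conf)
  expect_equal(r$rs, 1)                           # monotone transform
  expect_equal(r$n, 49)
  # flipped orientation is refused
  corr_ab <- cross_correlation_matrix(pa, pb, "A")
  expect_error(correlate_with_confusion(corr_ab, conf), "axis convention")
})

test_that("profile reduction keeps the signed extremum with high-intensity ties", {
  m <- matrix(0, 20, 11, dimnames = list(paste0("AU", AU_IDS), NULL))
  expect_true(all(reduce_profile(m) == 0))
  m[1, ] <- seq(0, 1, 0.1)
  expect_equal(unname(reduce_profile(m)["AU1"]), 1)
  m[2, 1:3] <- c(0, -0.5, 0.3)
  expect_equal(unname(reduce_profile(m)["AU2"]), -0.5)   # trough, sign kept
  m[3, ] <- c(0, 0.4, rep(0, 7), 0.4, 0)                 # tie
  expect_equal(unname(reduce_profile(m)["AU4"]), 0.4)
  expect_equal(max(which(abs(m[3, ]) == 0.4)), 10)       # taken at higher step
})

test_that("the feature matrix is 20 x 14 in database-major column order", {
  set.seed(10)
  a <- array(rnorm(7 * 20 * 11), c(7, 20, 11),
             dimnames = list(EXPRESSIONS, paste0("AU", AU_IDS), NULL))
  pa <- structure(list(responses = a, n_runs = 1, normalization = "raw",
                       group = "A"), class = "tuning_profiles")
  pb <- structure(list(responses = -a, n_runs = 1, normalization = "raw",
                       group = "B"), class = "tuning_profiles")
  ra <- reduce_profile(pa); rb <- reduce_profile(pb)
  fm <- build_feature_matrix(ra, rb)
  expect_identical(dim(fm), c(20L, 14L))
  expect_identical(colnames(fm)[1:7], paste("A", EXPRESSIONS, sep = "."))
  expect_equal(unname(fm[, "A.happy"]), unname(ra[, "happy"]))
  # permuting input column order does not change content under labels
  fm2 <- build_feature_matrix(ra[, sample(EXPRESSIONS)], rb)
  expect_equal(fm2, fm)
  expect_error(build_feature_matrix(ra[, 1:6], rb), "20 x 7")
})

test_that("PCA centers variables and accounts for all variance", {
  set.seed(13)
  fm <- matrix(rnorm(280), 20, 14,
               dimnames = list(paste0("AU", AU_IDS),
                               paste(rep(c("A", "B"), each = 7),
                                     EXPRESSIONS, sep = ".")))
  p <- run_pca(fm, 3)
  expect_identical(dim(p$scores), c(14L, 3L))
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  expect_true(all(diff(p$explained) < 1e-9))      # sorted descending
  expect_error(run_pca(fm, 14), "<= 13")

  # a rank-1 outer product loads entirely on the first component
  r1 <- outer(rnorm(20), rnorm(14))
  dimnames(r1) <- dimnames(fm)
  expect_gt(run_pca(r1, 2)$explained[1], 0.999)

  # score geometry is reproducible up to per-component sign flips
  d1 <- dist(p$scores)
  flip <- p$scores %*% diag(c(-1, 1, -1))
  expect_equal(as.matrix(dist(flip)), as.matrix(d1), tolerance = 1e-12)
})
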