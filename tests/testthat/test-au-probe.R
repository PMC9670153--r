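# Probe features shared across the tests in this file.
probe_setup <- function() {
  cached("probes48", function() {
    ts <- tiny_setup()
    ps <- generate_probe_set(size = 64, steps = 11)
    list(ps = ps, pp = prepare_probes(ps, ts$net, ts$cfg$prep))
  })
}

test_that("probe responses are deterministic with a consistent null column", {
  ts <- tiny_setup()
  pr <- probe_setup()
  tf <- tiny_fit()
  raw <- probe_responses(tf$fit, pr$pp)
  expect_identical(dim(raw), c(7L, 20L, 11L))
  # intensity-0 responses identical across the 20 AU series, per unit
  for (u in 1:7) expect_equal(diff(range(raw[u, , 1])), 0, tolerance = 1e-12)
  expect_identical(probe_responses(tf$fit, pr$pp), raw)
})

test_that("baseline subtraction zeroes the null response and is idempotent", {
  pr <- probe_setup()
  tf <- tiny_fit()
  raw <- probe_responses(tf$fit, pr$pp)
  sub <- subtract_baseline(raw)
  expect_true(all(sub[, , 1] == 0))
  expect_equal(subtract_baseline(sub), sub, tolerance = 1e-12)
  # arithmetic: response minus the unit's null response
  expect_equal(sub[3, 5, 7], raw[3, 5, 7] - raw[3, 1, 1], tolerance = 1e-12)
  # corrupted probe set is rejected
  bad <- raw; bad[2, 4, 1] <- bad[2, 4, 1] + 1
  expect_error(subtract_baseline(bad), "differ across AU series")
})

test_that("zeroed FC weights give flat all-zero profiles", {
  ts <- tiny_setup()
  pr <- probe_setup()
  net <- ts$net
  net$fc$W1[] <- 0; net$fc$W2[] <- 0; net$fc$W3[] <- 0
  net$fc$b1[] <- 0; net$fc$b2[] <- 0; net$fc$b3 <- rep(0.3, 7)
  raw <- probe_responses(net, pr$pp)
  expect_true(all(raw == 0.3))
  expect_true(all(subtract_baseline(raw) == 0))
})

test_that("run averaging is the element-wise mean with run accounting", {
  a <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  expect_equal(average_runs(list(a))$responses, a)
  z <- average_runs(list(a, -a))
  expect_true(all(z$responses == 0))
  expect_equal(z$n_runs, 2)
  expect_error(average_runs(list(a, array(0, c(7, 20, 10)))), "shape")

  set.seed(8)
  runs <- lapply(1:40, function(i) a + array(rnorm(7 * 20 * 11, 0, 0.5),
                                             c(7, 20, 11)))
  expect_lt(max(abs(average_runs(runs)$responses - a)), 0.5)
})

test_that("normalization scales to a unit extremum in the stated scope", {
  a <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  a[2, 3, 4] <- -4                 # global extremum
  prof <- structure(list(responses = a, n_runs = 1, normalization = "raw",
                         group = "A"), class = "tuning_profiles")
  up <- normalize_profile(prof, "unit")
  expect_equal(apply(abs(up$responses), 1, max), rep(1, 7))
  gp <- normalize_profile(prof, "group")
  expect_equal(max(abs(gp$responses)), 1)
  expect_equal(sum(abs(gp$responses) == 1), 1)    # exactly one cell at |1|
  expect_equal(gp$responses[2, 3, 4], -1)         # trough keeps its sign
  expect_equal(gp$responses, a / 4)
  # already normalized input is unchanged
  expect_equal(normalize_profile(gp, "group")$responses, gp$responses)
  zero <- prof; zero$responses[] <- 0
  expect_error(normalize_profile(zero, "group"), "all-zero")
})

test_that("profile addition and subtraction follow the sign conventions", {
  a <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  pa <- structure(list(responses = a, n_runs = 1, normalization = "raw",
                       group = "A"), class = "tuning_profiles")
  pn <- pa; pn$responses <- -a; pn$group <- "B"
  expect_true(all(combine_profiles(pa, pn, "add")$responses == 0))
  expect_true(all(combine_profiles(pa, pa, "subtract")$responses == 0))
  both <- combine_profiles(pa, pa, "add")
  expect_equal(both$responses, 2 * a)
  misnorm <- pn; misnorm$normalization <- "unit-normalized"
  expect_error(combine_profiles(pa, misnorm, "add"), "normalization tags")
})

test_that("Spearman statistics are invariant to profile normalization", {
  set.seed(5)
  a <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  b <- array(rnorm(7 * 20 * 11), c(7, 20, 11))
  pa <- structure(list(responses = a, n_runs = 1, normalization = "raw",
                       group = "A"), class = "tuning_profiles")
  pb <- structure(list(responses = b, n_runs = 1, normalization = "raw",
                       group = "B"), class = "tuning_profiles")
  before <- per_expression_correlations(pa, pb)
  after <- per_expression_correlations(normalize_profile(pa, "group"),
                                       normalize_profile(pb, "unit"))
  expect_equal(before$rs, after$rs, tolerance = 1e-12)
  expect_equal(before$p, after$p, tolerance = 1e-12)
})
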