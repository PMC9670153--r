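test_that("identity splits are proportional, disjoint and reproducible", {
  ids <- sprintf("id%02d", 1:60)
  sp <- split_identities(ids, c(40, 8, 12), seed = 1)
  expect_length(sp$train, 40)
  expect_length(sp$validation, 8)
  expect_length(sp$test, 12)
  expect_length(intersect(sp$train, c(sp$validation, sp$test)), 0)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_identical(split_identities(ids, c(40, 8, 12), seed = 1), sp)
  expect_false(identical(split_identities(ids, c(40, 8, 12), seed = 2), sp))

  sp2 <- split_identities(sprintf("x%d", 1:15), c(10, 2, 3), seed = 5)
  expect_equal(lengths(sp2[1:3]), c(train = 10, validation = 2, test = 3))
  expect_error(split_identities(sprintf("x%d", 1:13), c(10, 2, 3)),
               "cannot be divided")
})

test_that("mini-batches cover shuffled samples with a remainder batch", {
  b <- batch_iterator(seq_len(14000), 32, seed = 1)
  expect_length(b, 438)                       # ceiling(14000 / 32)
  expect_true(all(lengths(b[1:437]) == 32))
  expect_length(b[[438]], 16)                 # 14000 mod 32
  expect_setequal(unlist(b), seq_len(14000))

  expect_equal(lengths(batch_iterator(1:64, 32, seed = 2)), c(32L, 32L))
  expect_equal(lengths(batch_iterator(1:10, 32, seed = 3)), 10L)
  expect_identical(batch_iterator(1:100, 32, 9), batch_iterator(1:100, 32, 9))
})

test_that("the learning rate schedule steps at its breakpoints", {
  sched <- data.frame(iteration = c(0, 4000, 8000), rate = c(1e-4, 1e-5, 1e-6))
  expect_equal(learning_rate_at(0, sched), 1e-4)
  expect_equal(learning_rate_at(3999, sched), 1e-4)
  expect_equal(learning_rate_at(4000, sched), 1e-5)
  expect_equal(learning_rate_at(5000, sched), 1e-5)
  expect_equal(learning_rate_at(8000, sched), 1e-6)
  expect_equal(learning_rate_at(12000, sched), 1e-6)
  expect_error(learning_rate_at(-1, sched), ">= 0")
  expect_error(train_config(lr_schedule = data.frame(
    iteration = c(0, 500, 500), rate = c(1, 1, 1))), "strictly increasing")
})

test_that("a zero learning rate leaves the head untouched", {
  ts <- tiny_setup()
  sp <- split_identities(ts$data$identities, c(8, 2, 2), seed = 3)
  tc <- train_config(iterations = 20,
                     lr_schedule = data.frame(iteration = 0, rate = 0),
                     runs = 1, proportions = c(8, 2, 2))
  net <- init_fc_weights(ts$net, 21)
  fit <- train_run(net, ts$data, sp, tc, run_seed = 5)
  expect_identical(fit$network$fc, net$fc)
})

test_that("initial loss sits near ln(7) under near-uniform outputs", {
  ts <- tiny_setup()
  sp <- split_identities(ts$data$identities, c(8, 2, 2), seed = 4)
  losses <- vapply(1:5, function(i) {
    tc <- train_config(iterations = 1,
                       lr_schedule = data.frame(iteration = 0, rate = 0),
                       runs = 1, proportions = c(8, 2, 2))
    fit <- train_run(init_fc_weights(ts$net, 100 + i), ts$data, sp, tc,
                     run_seed = i)
    fit$loss[1]
  }, numeric(1))
  expect_lt(abs(mean(losses) - log(7)), 0.2)
})

test_that("training learns the expression mapping well above chance", {
  tf <- tiny_fit()
  ne <- nrow(tf$fit$epochs)
  expect_gt(tf$fit$epochs$train_acc[ne], 0.5)       # chance is 1/7
  expect_gt(tf$fit$epochs$val_acc[ne], 0.4)
  # the loss decreased substantially
  expect_lt(mean(utils::tail(tf$fit$loss, 20)), 1.0)
  expect_gt(mean(utils::head(tf$fit$loss, 5)), 1.6)
  # validation plateaus: last-3-epoch mean within 0.05 of the maximum
  va <- tf$fit$epochs$val_acc
  expect_lt(max(va) - mean(utils::tail(va, 3)), 0.05 + 1e-9)
})

test_that("training is deterministic given its seeds", {
  ts <- tiny_setup()
  sp <- split_identities(ts$data$identities, c(8, 2, 2), seed = 6)
  tc <- train_config(iterations = 40,
                     lr_schedule = data.frame(iteration = 0, rate = 0.05),
                     runs = 1, proportions = c(8, 2, 2))
  f1 <- train_run(init_fc_weights(ts$net, 31), ts$data, sp, tc, run_seed = 8)
  f2 <- train_run(init_fc_weights(ts$net, 31), ts$data, sp, tc, run_seed = 8)
  expect_identical(f1$network$fc, f2$network$fc)
  expect_identical(f1$loss, f2$loss)
  f3 <- train_run(init_fc_weights(ts$net, 31), ts$data, sp, tc, run_seed = 9)
  expect_false(identical(f3$loss, f1$loss))
})

test_that("run_experiment keeps one complete record per run", {
  ts <- tiny_setup()
  tc <- train_config(iterations = 30,
                     lr_schedule = data.frame(iteration = 0, rate = 0.05),
                     runs = 2, proportions = c(8, 2, 2), master_seed = 12)
  fits <- run_experiment(ts$data, ts$net, tc)
  expect_length(fits, 2)
  expect_false(identical(fits[[1]]$split, fits[[2]]$split))
  expect_false(identical(fits[[1]]$network$fc, fits[[2]]$network$fc))
  # identical master seed reproduces the records
  fits2 <- run_experiment(ts$data, ts$net, tc)
  expect_identical(lapply(fits, `[[`, "loss"), lapply(fits2, `[[`, "loss"))
})

test_that("the canonical protocol yields the stated epoch structure", {
  cfg <- experiment_config(preset = "canonical")
  v <- dry_run(cfg)
  expect_equal(v$split, c(40L, 8L, 12L))
  expect_equal(v$variants_per_image, 50)
  expect_equal(v$train_samples_per_epoch, 14000)
  expect_equal(v$val_samples_per_epoch, 2800)
  expect_equal(v$batches_per_epoch, 438)
  expect_equal(v$final_batch_size, 16L)
  expect_equal(v$iterations, 12000L)
  expect_equal(v$runs, 40L)
  expect_equal(v$fc_sizes, c(4096L, 4096L, 7L))
  expect_equal(v$input_size, 224L)
})
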