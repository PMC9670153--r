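test_that("the fixture registry rejects unknown names and lists itself", {
  expect_error(fixture_suite("twin-peaks"), "unknown fixture.*default-twin")
  cfg <- fixture_suite("default-twin", preset = "mini")
  expect_s3_class(cfg, "experiment_config")
  expect_identical(cfg$cultures$A$name, "culture-A")
  # identical-cultures control really is identical
  ic <- fixture_suite("identical-cultures", preset = "mini")
  expect_equal(ic$cultures$A$mean, ic$cultures$B$mean, ignore_attr = TRUE)
  # disjoint control shares no AU within any non-neutral expression
  dc <- fixture_suite("disjoint-cultures", preset = "mini")
  for (lab in setdiff(EXPRESSIONS, "neutral")) {
    on_a <- dc$cultures$A$mean[lab, ] > 0
    on_b <- dc$cultures$B$mean[lab, ] > 0
    expect_equal(sum(on_a & on_b), 0)
  }
})

test_that("presets validate structurally without execution", {
  for (p in c("canonical", "desk", "mini")) {
    v <- dry_run(experiment_config(preset = p))
    expect_true(v$train_samples_per_epoch ==
                  v$split[1] * 7 * v$variants_per_image)
    expect_true(v$val_samples_per_epoch ==
                  v$split[2] * 7 * v$variants_per_image)
  }
  bad <- experiment_config(preset = "mini", n_identities = 13L)
  expect_error(dry_run(bad), "not divisible")
})

test_that("the experiment report has the complete documented schema", {
  rep <- mini_experiment(1)
  expect_s3_class(rep, "au_experiment")
  expect_identical(names(rep),
                   c("config", "confusion", "comparison", "profiles",
                     "per_expression", "corr_matrix", "corr_vs_confusion",
                     "feature_matrix", "pca", "fits", "seeds"))
  expect_identical(names(rep$confusion),
                   c("matched_a", "matched_b", "swapped_ab", "swapped_ba"))
  expect_equal(nrow(rep$per_expression), 7)
  expect_identical(dim(rep$feature_matrix), c(20L, 14L))
  expect_identical(dim(rep$pca$scores), c(14L, 3L))
  expect_identical(dim(unclass(rep$corr_matrix$A_rows)), c(7L, 7L))
  expect_length(rep$fits$A, rep$config$train$runs)
  expect_length(rep$fits$B, rep$config$train$runs)
  # every confusion matrix row is normalized
  for (cm in rep$confusion)
    expect_equal(unname(rowSums(cm)), rep(1, 7), tolerance = 1e-9)
  # orientation flip transposes the correlation matrix without changing values
  expect_equal(unclass(rep$corr_matrix$B_rows),
               t(unclass(rep$corr_matrix$A_rows)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("reports export to CSV with stable files", {
  rep <- mini_experiment(1)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  files <- list.files(dir)
  expect_true(all(c("confusion_matched_a.csv", "confusion_swapped_ab.csv",
                    "per_expression_correlations.csv", "feature_matrix.csv",
                    "pca_scores.csv", "profiles_A.csv") %in% files))
  prof <- utils::read.csv(file.path(dir, "profiles_A.csv"))
  expect_equal(nrow(prof), 7 * 20 * 11)
})

test_that("culture maps round-trip through YAML", {
  cu <- default_cultures("default-twin")$B
  path <- withr::local_tempfile(fileext = ".yaml")
  write_culture_map(cu, path)
  back <- read_culture_map(path)
  expect_equal(back$mean, cu$mean, ignore_attr = TRUE)
})

test_that("PC space places shared expressions closer than divergent ones", {
  rep <- mini_experiment(1)
  s <- rep$pca$scores
  d_pair <- function(lab) sqrt(sum((s[paste0("A.", lab), ] -
                                    s[paste0("B.", lab), ])^2))
  shared <- mean(c(d_pair("happy"), d_pair("surprised")))
  divergent <- mean(c(d_pair("angry"), d_pair("sad")))
  expect_lt(shared, divergent)
})

test_that("the full pipeline is deterministic per master seed", {
  rep1 <- mini_experiment(1)
  rep2 <- run_full_experiment(fixture_suite("default-twin", preset = "mini",
                                            master_seed = 1))
  expect_identical(unclass(rep2$confusion$matched_a),
                   unclass(rep1$confusion$matched_a))
  expect_identical(unclass(rep2$confusion$swapped_ba),
                   unclass(rep1$confusion$swapped_ba))
  expect_identical(rep2$per_expression$rs, rep1$per_expression$rs)
  expect_identical(rep2$feature_matrix, rep1$feature_matrix)
})
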