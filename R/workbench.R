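#' Configure the full twin-database experiment
#'
#' Bundles the database, preprocessing, augmentation, network and
#' training configurations plus a master seed from which every stream
#' of randomness is derived. Three scale presets are provided:
#'
#' * `"canonical"` — the full-scale protocol: 60 identities per database,
#'   224-px input, 5 x 5 x 2 = 50 augmentation variants, FC
#'   4096/4096/7, 12,000 iterations (LR 1e-4 / 1e-5 / 1e-6 stepping at
#'   4,000 / 8,000), 40 runs. Intended for validation (`dry_run`) and
#'   for users with matching compute; not executed by the test suite.
#' * `"desk"` — 24 identities (16/4/4 split), 64-px input, 3 x 3 x 2 =
#'   18 variants, FC 128/128/7, 1,500 iterations (LR steps at 500 /
#'   1,000), 5 runs: minutes of CPU while preserving every structural
#'   element of the protocol.
#' * `"mini"` — 12 identities (8/2/2), 48-px input, 18 variants, FC
#'   64/64/7, 800 iterations (steps at 267 / 533), 3 runs: the
#'   multi-seed replication scale.
#'
#' @param preset `"desk"` (default), `"mini"` or `"canonical"`.
#' @param cultures A [default_cultures()] pair (or any list `A`/`B` of
#'   culture maps sharing the label vocabulary).
#' @param master_seed Master seed.
#' @param noise_sd AU intensity noise of both databases.
#' @param ... Named overrides for individual fields (`n_identities`,
#'   `image_size`, `input_size`, `fc_sizes`, `iterations`, `runs`,
#'   `scales`, `proportions`, `dropout`, `lr_schedule`, `batch_size`).
#' @return Object of class `"experiment_config"`.
#' @export
experiment_config <- function(preset = c("desk", "mini", "canonical"),
                              cultures = default_cultures("default-twin"),
                              master_seed = 1L, noise_sd = 0.1, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    canonical = list(
      n_identities = 60L, image_size = 280L, input_size = 224L,
      fc_sizes = c(4096L, 4096L, 7L), iterations = 12000L,
      runs = 40L, scales = c(0.90, 0.95, 1.00, 1.05, 1.10),
      n_offsets = 5L, proportions = c(40L, 8L, 12L),
      lr_schedule = data.frame(iteration = c(0L, 4000L, 8000L),
                               rate = c(1e-4, 1e-5, 1e-6))),
    desk = list(n_identities = 24L, image_size = 80L, input_size = 64L,
                fc_sizes = c(128L, 128L, 7L), iterations = 1500L,
                runs = 5L, scales = c(0.95, 1.00, 1.05), n_offsets = 3L,
                proportions = c(16L, 4L, 4L),
                lr_schedule = data.frame(iteration = c(0L, 500L, 1000L),
                                         rate = c(0.3, 0.03, 0.003))),
    mini = list(n_identities = 12L, image_size = 64L, input_size = 48L,
                fc_sizes = c(64L, 64L, 7L), iterations = 800L,
                runs = 3L, scales = c(0.95, 1.00, 1.05), n_offsets = 3L,
                proportions = c(8L, 2L, 2L),
                lr_schedule = data.frame(iteration = c(0L, 267L, 533L),
                                         rate = c(0.3, 0.03, 0.003))))
  ov <- list(...)
  for (nm in names(ov)) base[[nm]] <- ov[[nm]]
  off <- max(1L, round(0.05 * base$input_size))
  offsets <- if (base$n_offsets >= 5)
    list(c(0L, 0L), c(-off, 0L), c(off, 0L), c(0L, -off), c(0L, off))
  else list(c(0L, 0L), c(-off, 0L), c(off, 0L))[seq_len(base$n_offsets)]
  structure(list(
    preset = preset, master_seed = as.integer(master_seed),
    cultures = cultures, noise_sd = noise_sd,
    n_identities = base$n_identities, image_size = base$image_size,
    prep = preprocess_config(),
    aug = augment_config(scales = base$scales, offsets = offsets,
                         reflections = "both",
                         input_size = base$input_size),
    net = net_config(input_size = base$input_size, fc_sizes = base$fc_sizes,
                     dropout = base$dropout %||% 0.1,
                     backbone_seed = derive_seed(master_seed, "backbone")),
    train = train_config(batch_size = base$batch_size %||% 32L,
                         iterations = base$iterations,
                         lr_schedule = base$lr_schedule, runs = base$runs,
                         proportions = base$proportions,
                         master_seed = as.integer(master_seed))),
    class = "experiment_config")
}

#' Named fixture configurations
#'
#' Registry of ready-made experiment configurations: the
#' `"default-twin"` fixture (shared happy/surprised, divergent
#' angry/sad), the `"identical-cultures"` null control, and the
#' `"disjoint-cultures"` extreme-divergence control.
#'
#' @param name Fixture name.
#' @param preset,master_seed,... Passed to [experiment_config()].
#' @return An `"experiment_config"`.
#' @export
fixture_suite <- function(name, preset = "desk", master_seed = 1L, ...) {
  registry <- c("default-twin", "identical-cultures", "disjoint-cultures")
  if (!name %in% registry)
    stopf("fixture_suite: unknown fixture '%s'; registry: %s", name,
          paste(registry, collapse = ", "))
  experiment_config(preset = preset, cultures = default_cultures(name),
                    master_seed = master_seed, ...)
}

#' Validate an experiment configuration without executing it
#'
#' Checks cross-component consistency (label vocabulary, split
#' divisibility, input sizes, variant counts) and returns the derived
#' structural numbers: variants per image, per-epoch sample counts,
#' final mini-batch size, iterations per epoch.
#'
#' @param config An [experiment_config()].
#' @return List of structural counts (invisibly printed as a summary).
#' @export
dry_run <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$aug$input_size != config$net$input_size)
    stopf("dry_run: augment and network input sizes differ")
  sizes <- config$n_identities * config$train$proportions /
    sum(config$train$proportions)
  if (any(sizes != round(sizes)))
    stopf("dry_run: %d identities are not divisible in proportions %s",
          config$n_identities, paste(config$train$proportions, collapse = "/"))
  nv <- n_variants(config$aug)
  n_train <- sizes[1] * 7 * nv
  n_val <- sizes[2] * 7 * nv
  rem <- n_train %% config$train$batch_size
  list(split = as.integer(sizes), variants_per_image = nv,
       train_samples_per_epoch = n_train, val_samples_per_epoch = n_val,
       batches_per_epoch = as.integer(ceiling(n_train / config$train$batch_size)),
       final_batch_size = as.integer(if (rem == 0) config$train$batch_size else rem),
       iterations = config$train$iterations, runs = config$train$runs,
       fc_sizes = config$net$fc_sizes, input_size = config$net$input_size)
}

#' Run the full twin-database experiment
#'
#' Executes the complete pipeline at the configured scale: generate the
#' two synthetic databases, standardize and augment, extract frozen
#' backbone features, train `runs` classifiers per database, evaluate
#' matched and swapped confusion matrices (paired per-run test splits),
#' compare conditions, probe AU tuning of every run, average and
#' normalize profiles, compute per-expression and cross-group profile
#' correlations, relate them to the swapped confusion matrices, and
#' reduce the profiles by PCA. Deterministic given the master seed.
#'
#' @param config An [experiment_config()].
#' @param probe_steps Intensities per AU probe series (default 11).
#' @return Object of class `"au_experiment"` — see Details.
#' @details The returned report contains: `confusion` (matched_a,
#'   matched_b, swapped_ab, swapped_ba), `comparison` (per database:
#'   matched vs swapped [compare_correct_rates()]), `profiles`
#'   (group-normalized tuning profiles per group), `per_expression`
#'   (correlation table), `corr_matrix` (both orientations),
#'   `corr_vs_confusion` (both swap directions), `pca`,
#'   `feature_matrix`, `fits`, `config` and `seeds`.
#' @export
run_full_experiment <- function(config, probe_steps = 11L) {
  stopifnot(inherits(config, "experiment_config"))
  dry_run(config)    # structural validation first
  ms <- config$master_seed

  spec_a <- database_spec("A", config$cultures$A, config$n_identities,
                          config$noise_sd, seed = derive_seed(ms, "db", "A"),
                          image_size = config$image_size)
  spec_b <- database_spec("B", config$cultures$B, config$n_identities,
                          config$noise_sd, seed = derive_seed(ms, "db", "B"),
                          image_size = config$image_size)
  net <- build_network(config$net)
  data_a <- prepare_database(generate_database(spec_a), net, config$prep, config$aug)
  data_b <- prepare_database(generate_database(spec_b), net, config$prep, config$aug)

  fits_a <- run_experiment(data_a, net, config$train)
  fits_b <- run_experiment(data_b, net, config$train)

  # paired swapped evaluation: run k of one group is tested on the test
  # split drawn for run k of the other group
  test_ids <- function(fits) lapply(fits, function(f) f$split$test)
  cm_matched_a <- confusion_matrix(fits_a, data_a)
  cm_matched_b <- confusion_matrix(fits_b, data_b)
  cm_swapped_ab <- swap_test_database(fits_a, data_b, test_ids(fits_b))
  cm_swapped_ba <- swap_test_database(fits_b, data_a, test_ids(fits_a))

  comparison <- list(
    A = compare_correct_rates(cm_matched_a, cm_swapped_ab,
                              labels = c("matched", "swapped")),
    B = compare_correct_rates(cm_matched_b, cm_swapped_ba,
                              labels = c("matched", "swapped")))

  probes <- generate_probe_set(config$image_size, probe_steps)
  pp <- prepare_probes(probes, net, config$prep)
  prof_of <- function(fits, group) {
    arrays <- lapply(fits, function(f)
      subtract_baseline(probe_responses(f, pp)))
    average_runs(arrays, group = group)
  }
  prof_a <- normalize_profile(prof_of(fits_a, "A"), "group")
  prof_b <- normalize_profile(prof_of(fits_b, "B"), "group")

  per_expr <- per_expression_correlations(prof_a, prof_b)
  corr_ab <- cross_correlation_matrix(prof_a, prof_b, orientation = "A")
  corr_ba <- cross_correlation_matrix(prof_a, prof_b, orientation = "B")
  corr_vs_conf <- list(
    # A-trained nets tested on B: true labels follow B's culture, so
    # rows must be the B-trained profiles
    ab = correlate_with_confusion(corr_ba, cm_swapped_ab),
    ba = correlate_with_confusion(corr_ab, cm_swapped_ba))

  fm <- build_feature_matrix(reduce_profile(prof_a), reduce_profile(prof_b))
  pca <- run_pca(fm, n_components = 3L)

  structure(list(
    config = config,
    confusion = list(matched_a = cm_matched_a, matched_b = cm_matched_b,
                     swapped_ab = cm_swapped_ab, swapped_ba = cm_swapped_ba),
    comparison = comparison,
    profiles = list(A = prof_a, B = prof_b),
    per_expression = per_expr,
    corr_matrix = list(A_rows = corr_ab, B_rows = corr_ba),
    corr_vs_confusion = corr_vs_conf,
    feature_matrix = fm,
    pca = pca,
    fits = list(A = fits_a, B = fits_b),
    seeds = list(master = ms, db_a = spec_a$seed, db_b = spec_b$seed,
                 backbone = config$net$backbone_seed)),
    class = "au_experiment")
}

#' @export
print.au_experiment <- function(x, ...) {
  acc <- vapply(x$confusion, function(cm) mean(diag(cm)), numeric(1))
  cat("<au_experiment>", x$config$preset, "preset, master seed",
      x$seeds$master, "\n")
  cat(sprintf("  mean correct rates: matched %.3f / %.3f, swapped %.3f / %.3f\n",
              acc[1], acc[2], acc[3], acc[4]))
  cat("  per-expression profile correlations (A vs B):\n")
  cat(sprintf("    %-9s rs = %+.2f%s\n", x$per_expression$expression,
              x$per_expression$rs,
              ifelse(x$per_expression$significant, " *", "")), sep = "")
  cat(sprintf("  correlation vs swapped confusion: rs = %.2f (A->B), %.2f (B->A)\n",
              x$corr_vs_confusion$ab$rs, x$corr_vs_confusion$ba$rs))
  invisible(x)
}

#' @export
summary.au_experiment <- function(object, ...) {
  acc <- vapply(object$confusion, function(cm) mean(diag(cm)), numeric(1))
  out <- list(preset = object$config$preset, master_seed = object$seeds$master,
              accuracy = acc,
              gap = c(A = unname(acc["matched_a"] - acc["swapped_ab"]),
                      B = unname(acc["matched_b"] - acc["swapped_ba"])),
              per_expression = object$per_expression,
              t_tests = lapply(object$comparison, `[[`, "t"),
              anova = lapply(object$comparison, `[[`, "anova"),
              explained = object$pca$explained[1:3])
  class(out) <- "summary.au_experiment"
  out
}

#' @export
print.summary.au_experiment <- function(x, ...) {
  cat(sprintf("Twin-database experiment (%s preset, master seed %d)\n",
              x$preset, x$master_seed))
  cat(sprintf("  matched accuracy:  A %.3f   B %.3f\n",
              x$accuracy["matched_a"], x$accuracy["matched_b"]))
  cat(sprintf("  swapped accuracy:  A->B %.3f   B->A %.3f\n",
              x$accuracy["swapped_ab"], x$accuracy["swapped_ba"]))
  cat(sprintf("  generalization gap: %.3f (A), %.3f (B); Welch t p = %.2g / %.2g\n",
              x$gap["A"], x$gap["B"], x$t_tests$A$p, x$t_tests$B$p))
  cat("  profile correlations:\n")
  print(transform(x$per_expression, rs = round(rs, 3), p = signif(p, 2)),
        row.names = FALSE)
  cat(sprintf("  PCA: first three components explain %.0f%% / %.0f%% / %.0f%%\n",
              100 * x$explained[1], 100 * x$explained[2], 100 * x$explained[3]))
  invisible(x)
}

#' Plot an experiment report
#'
#' Draws the four confusion matrices as heatmaps.
#'
#' @param x An `"au_experiment"`.
#' @param ... Unused.
#' @export
plot.au_experiment <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 5, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(x$confusion)) {
    cm <- x$confusion[[nm]]
    graphics::image(1:7, 1:7, t(unclass(cm))[, 7:1], zlim = c(0, 1),
                    col = grDevices::hcl.colors(64, "viridis"),
                    axes = FALSE, xlab = "chosen", ylab = "", main = nm)
    graphics::axis(1, 1:7, EXPRESSIONS, las = 2, cex.axis = 0.6)
    graphics::axis(2, 7:1, EXPRESSIONS, las = 2, cex.axis = 0.6)
  }
  invisible(x)
}

#' Export an experiment report as CSVs plus a JSON-like summary
#'
#' Writes the four confusion matrices, the per-expression correlation
#' table, the feature matrix and the PCA scores under `dir`.
#'
#' @param report An `"au_experiment"`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$confusion))
    write_confusion_csv(report$confusion[[nm]],
                        file.path(dir, paste0("confusion_", nm, ".csv")))
  utils::write.csv(report$per_expression,
                   file.path(dir, "per_expression_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$feature_matrix),
                   file.path(dir, "feature_matrix.csv"))
  utils::write.csv(as.data.frame(report$pca$scores),
                   file.path(dir, "pca_scores.csv"))
  for (g in names(report$profiles))
    write_profiles_csv(report$profiles[[g]],
                       file.path(dir, paste0("profiles_", g, ".csv")))
  invisible(dir)
}
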