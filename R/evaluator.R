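#' Confusion matrix over test images, averaged across runs
#'
#' For each fitted run, the centered un-augmented variant of every test
#' image is classified (argmax of the raw FC3 scores) and the 7 x 7
#' choice-rate matrix is formed: entry (i, j) is the fraction of
#' true-expression-i images labeled j. Matrices are then averaged
#' across runs. Rows sum to 1 exactly.
#'
#' @param fits A list of [train_run()] fits (e.g. [run_experiment()]).
#' @param data `"prepared_data"` of the test database.
#' @param test_ids Test identities: `NULL` (default) uses each fit's
#'   own held-out test split; a character vector applies to every fit;
#'   a list gives one vector per fit.
#' @param condition `"matched"` or `"swapped"` tag.
#' @return 7 x 7 matrix, class `"confusion_matrix"`, with attributes
#'   `per_run` (runs x 7 per-expression correct rates), `condition`,
#'   `train_db`, `test_db`, `n_runs`.
#' @export
confusion_matrix <- function(fits, data, test_ids = NULL,
                             condition = c("matched", "swapped")) {
  condition <- match.arg(condition)
  if (inherits(fits, "expr_fit")) fits <- list(fits)
  if (!length(fits)) stopf("confusion_matrix: no fits supplied")
  vocab_check(data)
  keep <- which(data$meta$centered)
  meta <- data$meta[keep, , drop = FALSE]
  acc <- matrix(0, 7, 7, dimnames = list(true = EXPRESSIONS,
                                         chosen = EXPRESSIONS))
  per_run <- matrix(NA_real_, length(fits), 7,
                    dimnames = list(NULL, EXPRESSIONS))
  for (r in seq_along(fits)) {
    fit <- fits[[r]]
    ids <- if (is.null(test_ids)) fit$split$test
           else if (is.list(test_ids)) test_ids[[r]] else test_ids
    if (condition == "matched" && identical(fit$database, data$database)) {
      overlap <- intersect(ids, c(fit$split$train, fit$split$validation))
      if (length(overlap))
        stopf("confusion_matrix: matched-condition test identities overlap training/validation: %s",
              paste(overlap, collapse = ", "))
    }
    sel <- which(meta$identity %in% ids)
    if (!length(sel)) stopf("confusion_matrix: empty test set")
    true <- match(meta$label[sel], EXPRESSIONS)
    if (length(unique(true)) < 7)
      stopf("confusion_matrix: no test image for expression '%s'",
            EXPRESSIONS[setdiff(1:7, unique(true))[1]])
    sc <- head_forward(fit$network, data$features[keep[sel], , drop = FALSE],
                       "eval")$scores
    chosen <- max.col(sc, "first")
    cm <- table(factor(true, 1:7), factor(chosen, 1:7))
    cm <- cm / rowSums(cm)
    acc <- acc + cm
    per_run[r, ] <- diag(cm)
  }
  out <- acc / length(fits)
  structure(out, class = c("confusion_matrix", "matrix"),
            per_run = per_run, condition = condition,
            train_db = fits[[1]]$database, test_db = data$database,
            n_runs = length(fits))
}

vocab_check <- function(data) {
  bad <- setdiff(unique(data$meta$label), EXPRESSIONS)
  if (length(bad))
    stopf("label vocabulary mismatch: unknown label(s) %s",
          paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Evaluate fits on the other database (database-swapped condition)
#'
#' Replaces the test set of the training database with images from the
#' other database (same 7-label vocabulary and preprocessing) and
#' computes the confusion matrix under the same contract as
#' [confusion_matrix()].
#'
#' @param fits Fits trained on database A.
#' @param swap_data `"prepared_data"` of database B.
#' @param test_ids Identities of B to test on (default: all of B's
#'   identities; pass per-run splits for a paired design).
#' @return A `"confusion_matrix"` with condition `"swapped"`.
#' @export
swap_test_database <- function(fits, swap_data, test_ids = NULL) {
  vocab_check(swap_data)
  if (is.null(test_ids)) test_ids <- swap_data$identities
  confusion_matrix(fits, swap_data, test_ids, condition = "swapped")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %s: trained on %s, tested on %s (%d runs)\n",
              attr(x, "condition"), attr(x, "train_db"), attr(x, "test_db"),
              attr(x, "n_runs")))
  print(round(unclass(x), 3))
  cat(sprintf("mean correct rate: %.3f (chance 1/7 = %.2f)\n",
              mean(diag(x)), 1 / 7))
  invisible(x)
}

#' Write a confusion matrix as labeled CSV
#'
#' @param x A `"confusion_matrix"`.
#' @param path Output file.
#' @export
write_confusion_csv <- function(x, path) {
  df <- as.data.frame(unclass(x))
  df <- cbind(true = rownames(x), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Compare per-run correct rates between two conditions
#'
#' Welch's two-sided t test on the per-run mean correct rates, plus a
#' two-way ANOVA with interaction on the per-run per-expression rates
#' (factors: condition/database and facial expression).
#'
#' @param cm_a,cm_b `"confusion_matrix"` objects carrying per-run
#'   rates (each from `>= 2` runs).
#' @param labels Length-2 labels for the two groups.
#' @return Object of class `"condition_comparison"`: per-expression
#'   means/sds for both groups, `t` (statistic, df, p), `anova` (data
#'   frame with F and p for both main effects and the interaction).
#' @export
compare_correct_rates <- function(cm_a, cm_b,
                                  labels = c(attr(cm_a, "condition"),
                                             attr(cm_b, "condition"))) {
  ra <- attr(cm_a, "per_run"); rb <- attr(cm_b, "per_run")
  if (is.null(ra) || is.null(rb) || nrow(ra) < 2 || nrow(rb) < 2)
    stopf("compare_correct_rates: need per-run rates from >= 2 runs per group")
  ma <- rowMeans(ra); mb <- rowMeans(rb)
  tt <- stats::t.test(ma, mb)
  long <- rbind(
    data.frame(rate = as.vector(ra), group = labels[1],
               expression = rep(EXPRESSIONS, each = nrow(ra))),
    data.frame(rate = as.vector(rb), group = labels[2],
               expression = rep(EXPRESSIONS, each = nrow(rb))))
  long$group <- factor(long$group, levels = unique(labels))
  long$expression <- factor(long$expression, levels = EXPRESSIONS)
  av <- stats::aov(rate ~ group * expression, data = long)
  sa <- summary(av)[[1]]
  anova_tab <- data.frame(
    effect = c("group", "expression", "interaction"),
    df = sa$Df[1:3], F = sa$`F value`[1:3], p = sa$`Pr(>F)`[1:3])
  structure(list(
    labels = labels,
    mean_rates = c(stats::setNames(mean(ma), labels[1]),
                   stats::setNames(mean(mb), labels[2])),
    per_expression = data.frame(
      expression = EXPRESSIONS,
      mean_a = colMeans(ra), sd_a = apply(ra, 2, stats::sd),
      mean_b = colMeans(rb), sd_b = apply(rb, 2, stats::sd)),
    t = list(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value),
    anova = anova_tab), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  mean correct rates: %.3f vs %.3f (Welch t = %.2f, p = %.3g)\n",
              x$mean_rates[1], x$mean_rates[2], x$t$statistic, x$t$p))
  cat("  two-way ANOVA:\n")
  print(transform(x$anova, F = round(F, 2), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' An untrained (randomly initialized) fit
#'
#' Wraps a freshly initialized network as an `"expr_fit"` without any
#' training — the chance-level reference for calibration checks.
#'
#' @param network An `"expression_net"`.
#' @param split A [split_identities()] assignment.
#' @param database Database tag.
#' @return An `"expr_fit"` whose head is the random initialization.
#' @export
untrained_fit <- function(network, split, database = "untrained") {
  structure(list(network = network, split = split, loss = numeric(0),
                 epochs = data.frame(epoch = integer(0),
                                     train_acc = numeric(0),
                                     val_acc = numeric(0)),
                 config = NULL, run_seed = NA_integer_, database = database),
            class = "expr_fit")
}
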