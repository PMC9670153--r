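#' Spearman's rank correlation coefficient
#'
#' Computed as the Pearson correlation of the average ranks (midranks
#' for ties). The two-sided p value uses the large-sample t
#' approximation `t = rs * sqrt((n - 2) / (1 - rs^2))` on `n - 2`
#' degrees of freedom; for small samples an exact permutation p value
#' can be requested instead.
#'
#' @param x,y Numeric vectors of equal length `>= 3`; each must have
#'   non-zero rank variance.
#' @param exact Use exact permutation p (enumerates all permutations;
#'   only allowed for `n <= 8`).
#' @return List with `rs`, `p` and `n`.
#' @export
spearman_rs <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) stopf("spearman_rs: x and y must have equal length")
  if (n < 3) stopf("spearman_rs: need at least 3 paired values")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stopf("spearman_rs: undefined for zero rank variance (constant input)")
  rs <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stopf("spearman_rs: exact permutation p limited to n <= 8")
    perms <- permutations_of(n)
    null_rs <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rs) >= abs(rs) - 1e-12)
  } else {
    tstat <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rs = rs, p = p, n = n)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlation between two full tuning profiles
#'
#' Flattens the two 20 x 11 profiles over (AU, intensity) cells and
#' computes Spearman's rs. The intensity-0 cells (responses to the null
#' image, identically 0 after baseline subtraction) are excluded by
#' default, leaving n = 200 paired values.
#'
#' @param pa,pb 20 x 11 matrices (one unit's profile per group).
#' @param exclude_null Drop the intensity-0 column (default `TRUE`).
#' @return List with `rs`, `p`, `n`.
#' @export
profile_correlation <- function(pa, pb, exclude_null = TRUE) {
  if (!identical(dim(pa), dim(pb)))
    stopf("profile_correlation: profiles differ in shape")
  if (exclude_null) {
    pa <- pa[, -1, drop = FALSE]
    pb <- pb[, -1, drop = FALSE]
  }
  spearman_rs(as.vector(pa), as.vector(pb))
}

unit_profile <- function(profiles, u) {
  if (inherits(profiles, "tuning_profiles")) profiles$responses[u, , ]
  else profiles[u, , ]
}

#' Per-expression profile correlations between two trained groups
#'
#' One Spearman correlation per same-expression unit pair, with
#' Bonferroni-corrected significance at `alpha / 7`.
#'
#' @param prof_a,prof_b `"tuning_profiles"` of the two groups (7 units
#'   each).
#' @param alpha Family-wise significance level (default 0.05).
#' @param correction `"bonferroni"` (only option).
#' @param exclude_null Passed to [profile_correlation()].
#' @return Data frame with columns `expression`, `rs`, `p`,
#'   `significant`.
#' @export
per_expression_correlations <- function(prof_a, prof_b, alpha = 0.05,
                                        correction = "bonferroni",
                                        exclude_null = TRUE) {
  correction <- match.arg(correction, "bonferroni")
  rows <- lapply(1:7, function(u) {
    r <- profile_correlation(unit_profile(prof_a, u), unit_profile(prof_b, u),
                             exclude_null)
    data.frame(expression = EXPRESSIONS[u], rs = r$rs, p = r$p,
               significant = r$p < alpha / 7)
  })
  do.call(rbind, rows)
}

#' Cross-group correlation matrix of tuning profiles
#'
#' All 49 pairings of the seven units of group A with the seven units
#' of group B. With `orientation = "A"` rows are A's units and columns
#' B's; `"B"` transposes the matrix without changing any value.
#'
#' @param prof_a,prof_b `"tuning_profiles"` of the two groups.
#' @param orientation Which group labels the rows (`"A"` or `"B"`).
#' @param exclude_null Passed to [profile_correlation()].
#' @return 7 x 7 matrix of rs values, class `"profile_cor_matrix"`,
#'   with attributes `p` (7 x 7 p values), `n` (pairs per cell),
#'   `row_group`, `col_group`.
#' @export
cross_correlation_matrix <- function(prof_a, prof_b, orientation = c("A", "B"),
                                     exclude_null = TRUE) {
  orientation <- match.arg(orientation)
  rs <- p <- matrix(NA_real_, 7, 7, dimnames = list(EXPRESSIONS, EXPRESSIONS))
  n <- NA_integer_
  for (i in 1:7) for (j in 1:7) {
    r <- profile_correlation(unit_profile(prof_a, i), unit_profile(prof_b, j),
                             exclude_null)
    rs[i, j] <- r$rs; p[i, j] <- r$p; n <- r$n
  }
  ga <- if (inherits(prof_a, "tuning_profiles")) prof_a$group else "A"
  gb <- if (inherits(prof_b, "tuning_profiles")) prof_b$group else "B"
  if (orientation == "B") {
    rs <- t(rs); p <- t(p)
    row_group <- gb; col_group <- ga
  } else {
    row_group <- ga; col_group <- gb
  }
  structure(rs, class = c("profile_cor_matrix", "matrix"), p = p, n = n,
            row_group = row_group, col_group = col_group)
}

#' @export
print.profile_cor_matrix <- function(x, ...) {
  cat(sprintf("<profile_cor_matrix> rows: %s units, columns: %s units (n = %s per cell)\n",
              attr(x, "row_group"), attr(x, "col_group"), attr(x, "n")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Correlate the profile-correlation matrix with a swapped confusion matrix
#'
#' Spearman correlation over the 49 (profile correlation, choice rate)
#' pairs. Axis conventions must agree: the correlation-matrix rows must
#' be the profiles of the group trained on the confusion matrix's test
#' database (the true-label axis), its columns the group whose fits
#' were evaluated (the chosen-label axis).
#'
#' @param corr A [cross_correlation_matrix()] result.
#' @param confusion A `"confusion_matrix"` from the swapped condition.
#' @return List with `rs`, `p`, `n` (= 49).
#' @export
correlate_with_confusion <- function(corr, confusion) {
  rg <- attr(corr, "row_group"); cg <- attr(corr, "col_group")
  test_db <- attr(confusion, "test_db"); train_db <- attr(confusion, "train_db")
  if (!is.null(rg) && !is.null(test_db) &&
      !(identical(rg, test_db) && identical(cg, train_db)))
    stopf(paste("correlate_with_confusion: axis convention mismatch -",
                "correlation rows are '%s' profiles and columns '%s', but the",
                "confusion matrix has true labels from '%s' and nets trained on '%s'"),
          rg, cg, test_db, train_db)
  spearman_rs(as.vector(unclass(corr)), as.vector(unclass(confusion)))
}

#' Reduce a tuning profile to one signed extremum per AU
#'
#' For each action unit, the response of largest magnitude across the
#' 11 intensities is kept with its sign (a peak or a trough); ties
#' break toward the higher intensity.
#'
#' @param profile 20 x 11 matrix (one unit), or a `"tuning_profiles"`
#'   object (reduced unit-wise).
#' @return Named 20-vector, or a 20 x 7 matrix (AU x unit) for a
#'   profile set.
#' @export
reduce_profile <- function(profile) {
  reduce_one <- function(m) {
    apply(m, 1, function(v) {
      k <- max(which(abs(v) == max(abs(v))))   # tie -> higher intensity
      v[k]
    })
  }
  if (inherits(profile, "tuning_profiles")) {
    out <- vapply(1:7, function(u) reduce_one(profile$responses[u, , ]),
                  numeric(20))
    dimnames(out) <- list(au_keys(), EXPRESSIONS)
    out
  } else {
    stats::setNames(reduce_one(profile), rownames(profile) %||% au_keys())
  }
}

#' Assemble the 20 x 14 feature matrix for PCA
#'
#' Columns are the reduced profiles of the 7 expressions of group A
#' followed by the 7 of group B (database-major, expressions in
#' [EXPRESSIONS] order); rows are the 20 AUs.
#'
#' @param reduced_a,reduced_b 20 x 7 reduced-profile matrices from
#'   [reduce_profile()] (columns named by expression).
#' @param names_ab Length-2 database labels for the column names.
#' @return 20 x 14 matrix, columns `"<label>.<expression>"`.
#' @export
build_feature_matrix <- function(reduced_a, reduced_b,
                                 names_ab = c("A", "B")) {
  for (m in list(reduced_a, reduced_b))
    if (!is.matrix(m) || !identical(dim(m), c(20L, 7L)))
      stopf("build_feature_matrix: need two complete 20 x 7 reduced-profile matrices")
  ra <- reduced_a[, EXPRESSIONS]; rb <- reduced_b[, EXPRESSIONS]
  out <- cbind(ra, rb)
  colnames(out) <- c(paste(names_ab[1], EXPRESSIONS, sep = "."),
                     paste(names_ab[2], EXPRESSIONS, sep = "."))
  rownames(out) <- au_keys()
  out
}

#' Principal component analysis of reduced tuning profiles
#'
#' The 14 (expression, database) columns of the feature matrix are the
#' observations and the 20 AUs the variables. Variables are
#' mean-centered (not variance-scaled); components are ordered by
#' explained variance.
#'
#' @param feature_matrix A [build_feature_matrix()] result (20 x 14).
#' @param n_components Components to retain, `<= 13` (14 observations
#'   support at most 13).
#' @param scale. Also scale variables to unit variance (default
#'   `FALSE`).
#' @return Object of class `"profile_pca"`: list with `scores`
#'   (14 x n_components), `loadings` (20 x n_components),
#'   `explained` (variance fractions of all components) and `n_components`.
#' @export
run_pca <- function(feature_matrix, n_components = 3L, scale. = FALSE) {
  n_obs <- ncol(feature_matrix)
  if (n_components > n_obs - 1)
    stopf("run_pca: n_components must be <= %d (%d observations)",
          n_obs - 1, n_obs)
  pc <- stats::prcomp(t(feature_matrix), center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 explained = expl, n_components = as.integer(n_components)),
            class = "profile_pca")
}

#' @export
print.profile_pca <- function(x, ...) {
  cat(sprintf("<profile_pca> %d components retained; explained variance: %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained[seq_len(x$n_components)]),
                    collapse = ", ")))
  invisible(x)
}

#' Plot PCA scores of the 14 (expression, database) points
#'
#' @param x A `"profile_pca"`.
#' @param components Length-2 component indices to span the plane.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.profile_pca <- function(x, components = c(1, 2), ...) {
  s <- x$scores[, components, drop = FALSE]
  grp <- sub("\\..*$", "", rownames(s))
  expr <- sub("^[^.]*\\.", "", rownames(s))
  pch <- stats::setNames(c(1, 2, 0, 5, 6, 8, 4), EXPRESSIONS)
  graphics::plot(s, pch = pch[expr],
                 col = ifelse(grp == unique(grp)[1], "black", "grey50"),
                 xlab = sprintf("PC%d (%.0f%%)", components[1],
                                100 * x$explained[components[1]]),
                 ylab = sprintf("PC%d (%.0f%%)", components[2],
                                100 * x$explained[components[2]]), ...)
  graphics::text(s, labels = expr, pos = 3, cex = 0.6)
  invisible(x)
}
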