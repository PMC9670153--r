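#' Prepare probe stimuli for the network
#'
#' Runs every probe image through the same standardization pipeline as
#' the training data (crop, histogram adjustment, oval mask, resize)
#' and extracts frozen backbone features once. The stimulus order is
#' AU-major, intensity-minor (20 x 11 rows).
#'
#' @param probes A [generate_probe_set()] result.
#' @param network An `"expression_net"`.
#' @param prep A [preprocess_config()].
#' @return Object of class `"prepared_probes"`: list with `features`
#'   (220 x d), `aus` (20 AU keys), `intensities`.
#' @export
prepare_probes <- function(probes, network, prep = preprocess_config()) {
  if (!inherits(probes, "probe_set"))
    stopf("prepare_probes: `probes` must be a probe_set")
  size <- network$config$input_size
  imgs <- list()
  for (key in names(probes$series))
    for (im in probes$series[[key]]) {
      pp <- preprocess_image(im, face_bbox(nrow(im)), prep)
      imgs[[length(imgs) + 1L]] <- resize_to_input(pp, size, prep$background)
    }
  structure(list(features = backbone_features(network, imgs),
                 aus = names(probes$series),
                 intensities = probes$intensities),
            class = "prepared_probes")
}

#' Raw output-unit responses to the AU probe series
#'
#' Presents all probe images (20 AUs x 11 intensities) to a fitted
#' classifier in eval mode and records the raw pre-softmax FC3 scores.
#'
#' @param fit An `"expr_fit"` (or `"expression_net"`).
#' @param probes A [prepare_probes()] result.
#' @return 7 x 20 x 11 array (unit x AU x intensity index), dimnames
#'   set to expressions, AU keys and intensities.
#' @export
probe_responses <- function(fit, probes) {
  state <- if (inherits(fit, "expr_fit")) fit$network else fit
  na <- length(probes$aus); ni <- length(probes$intensities)
  if (nrow(probes$features) != na * ni)
    stopf("probe_responses: probe feature matrix has %d rows, expected %d",
          nrow(probes$features), na * ni)
  sc <- head_forward(state, probes$features, "eval")$scores  # (20*11) x 7
  arr <- array(NA_real_, c(7, na, ni),
               dimnames = list(EXPRESSIONS, probes$aus, probes$intensities))
  for (u in 1:7) arr[u, , ] <- matrix(sc[, u], na, ni, byrow = TRUE)
  arr
}

#' Subtract the null-image baseline
#'
#' Subtracts each unit's response to the null image (intensity 0) from
#' all of its responses, so the null response becomes exactly 0 in
#' every unit. The intensity-0 responses must agree across the 20 AU
#' series (they are the same image); any spread above `1e-6` signals a
#' corrupted probe set.
#'
#' @param raw 7 x 20 x 11 array from [probe_responses()].
#' @return Baseline-subtracted array of the same shape.
#' @export
subtract_baseline <- function(raw) {
  null_resp <- raw[, , 1, drop = FALSE]
  spread <- apply(null_resp, 1, function(v) diff(range(v)))
  if (any(spread > 1e-6))
    stopf("subtract_baseline: null-image responses differ across AU series (max spread %.3g); probe set corrupt",
          max(spread))
  out <- sweep(raw, 1, raw[, 1, 1], "-")
  out
}

#' Average baseline-subtracted responses across runs
#'
#' @param arrays List of equally shaped response arrays (one per run).
#' @return Object of class `"tuning_profiles"`: list with `responses`
#'   (element-wise mean array), `n_runs`, `normalization = "raw"` and
#'   `group` (database tag, from the `group` argument).
#' @param group Label of the trained group the runs belong to.
#' @export
average_runs <- function(arrays, group = NA_character_) {
  if (!length(arrays)) stopf("average_runs: empty run list")
  dims <- dim(arrays[[1]])
  for (a in arrays)
    if (!identical(dim(a), dims))
      stopf("average_runs: response arrays differ in shape")
  m <- Reduce(`+`, arrays) / length(arrays)
  structure(list(responses = m, n_runs = length(arrays),
                 normalization = "raw", group = group),
            class = "tuning_profiles")
}

#' Normalize tuning profiles
#'
#' Divides by the maximum absolute response within the scope: per
#' `"unit"` (each unit's 220-cell profile peaks at |1|) or per
#' `"group"` (one joint maximum across all seven units).
#'
#' @param profiles A `"tuning_profiles"` object.
#' @param scope `"unit"` or `"group"`.
#' @return Normalized `"tuning_profiles"` (normalization tag updated).
#' @export
normalize_profile <- function(profiles, scope = c("unit", "group")) {
  scope <- match.arg(scope)
  r <- profiles$responses
  if (scope == "unit") {
    mx <- apply(abs(r), 1, max)
    if (any(mx == 0)) stopf("normalize_profile: all-zero profile in scope")
    r <- sweep(r, 1, mx, "/")
    profiles$normalization <- "unit-normalized"
  } else {
    mx <- max(abs(r))
    if (mx == 0) stopf("normalize_profile: all-zero profile in scope")
    r <- r / mx
    profiles$normalization <- "group-normalized"
  }
  profiles$responses <- r
  profiles
}

#' Add or subtract two groups' tuning profiles
#'
#' Element-wise combination of same-shape, same-normalization profile
#' sets. In the sum, tuning shared by the two groups keeps its sign and
#' grows; in the difference, opposite tuning acquires large magnitude.
#'
#' @param a,b `"tuning_profiles"` with identical shape and
#'   normalization tags.
#' @param op `"add"` or `"subtract"`.
#' @return A `"tuning_profiles"` object (group label `"A+B"` or
#'   `"A-B"`).
#' @export
combine_profiles <- function(a, b, op = c("add", "subtract")) {
  op <- match.arg(op)
  if (!identical(a$normalization, b$normalization))
    stopf("combine_profiles: normalization tags differ ('%s' vs '%s')",
          a$normalization, b$normalization)
  if (!identical(dim(a$responses), dim(b$responses)))
    stopf("combine_profiles: profile shapes differ")
  r <- if (op == "add") a$responses + b$responses else a$responses - b$responses
  structure(list(responses = r, n_runs = NA_integer_,
                 normalization = a$normalization,
                 group = paste0(a$group, if (op == "add") "+" else "-", b$group)),
            class = "tuning_profiles")
}

#' @export
print.tuning_profiles <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("<tuning_profiles> %s: %d units x %d AUs x %d intensities (%s, %s run(s))\n",
              x$group %||% "?", d[1], d[2], d[3], x$normalization,
              ifelse(is.na(x$n_runs), "combined", x$n_runs)))
  invisible(x)
}

#' Export tuning profiles as long-format CSV
#'
#' Columns: unit, au, intensity, response.
#'
#' @param profiles A `"tuning_profiles"`.
#' @param path Output file.
#' @export
write_profiles_csv <- function(profiles, path) {
  r <- profiles$responses
  dn <- dimnames(r)
  df <- expand.grid(unit = dn[[1]], au = dn[[2]], intensity = as.numeric(dn[[3]]),
                    stringsAsFactors = FALSE)
  df$response <- as.vector(r)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
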