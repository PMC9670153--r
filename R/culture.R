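#' Define an expression-to-AU culture map
#'
#' A culture map encodes how a (synthetic) culture poses each of the
#' seven facial expressions: for every expression label it gives the
#' mean intensity of each involved action unit, and optionally a
#' per-AU standard deviation. It is the construct under study — two
#' databases built from culture maps that agree for some expressions
#' and diverge for others emulate partially shared facial dialects.
#'
#' @param mapping Named list with one entry per expression label in
#'   [EXPRESSIONS]. Each entry is a named numeric vector of mean AU
#'   intensities in \[0, 1\] (names `"AU12"` or `"12"`), or a list with
#'   elements `mean` (named numeric) and `sd` (named numeric of the same
#'   names, values `>= 0`). `"neutral"` must map every AU to 0 and may
#'   be given as an empty vector.
#' @param name Culture label.
#' @return Object of class `"culture_map"`: list with `name`, `mean`
#'   (7 x 20 matrix, rows = expressions) and `sd` (7 x 20 matrix,
#'   `NA` where the database-level noise sd should apply).
#' @seealso [default_cultures()] for the built-in twin-culture fixtures.
#' @export
culture_map <- function(mapping, name = "culture") {
  missing_lab <- setdiff(EXPRESSIONS, names(mapping))
  if (length(missing_lab))
    stopf("culture_map: missing expression label(s): %s",
          paste(missing_lab, collapse = ", "))
  extra <- setdiff(names(mapping), EXPRESSIONS)
  if (length(extra))
    stopf("culture_map: unknown expression label(s): %s",
          paste(extra, collapse = ", "))
  mu <- matrix(0, 7, 20, dimnames = list(EXPRESSIONS, au_keys()))
  sd <- matrix(NA_real_, 7, 20, dimnames = list(EXPRESSIONS, au_keys()))
  for (lab in EXPRESSIONS) {
    ent <- mapping[[lab]]
    if (is.list(ent)) {
      mu[lab, ] <- validate_au_vector(au_vector(ent$mean %||% numeric()))
      if (!is.null(ent$sd)) {
        if (any(ent$sd < 0)) stopf("culture_map: sd must be >= 0")
        nm <- names(ent$sd)
        nm <- ifelse(grepl("^AU", nm), nm, paste0("AU", nm))
        sd[lab, nm] <- as.numeric(ent$sd)
      }
    } else {
      mu[lab, ] <- validate_au_vector(au_vector(ent))
    }
  }
  if (any(mu["neutral", ] != 0))
    stopf("culture_map: the neutral expression must map all AUs to 0")
  structure(list(name = name, mean = mu, sd = sd), class = "culture_map")
}

#' Built-in culture-map fixtures
#'
#' Returns a pair of culture maps. The `"default-twin"` pair shares the
#' happy (AU#12 + AU#6), surprised (AU#1+#2+#5+#26), fearful and
#' disgusted mappings while diverging in angry (A: AU#4+AU#22,
#' B: AU#4+AU#23) and sad (A: AU#1+#15, B: AU#1+#15+#22), so that happy
#' and surprised tuning profiles should correlate across the trained
#' groups while sad and angry should not. `"identical-cultures"` uses
#' culture A for both databases (null control). `"disjoint-cultures"`
#' assigns culture B a derangement of culture A's AU sets, so no
#' expression shares its facial pattern across databases.
#'
#' @param pair One of `"default-twin"`, `"identical-cultures"`,
#'   `"disjoint-cultures"`.
#' @return List with elements `A` and `B`, each a [culture_map()].
#' @export
default_cultures <- function(pair = c("default-twin", "identical-cultures",
                                      "disjoint-cultures")) {
  pair <- match.arg(pair)
  shared <- list(
    neutral   = c(),
    happy     = c(AU12 = 0.85, AU6 = 0.50),
    surprised = c(AU1 = 0.60, AU2 = 0.60, AU5 = 0.70, AU26 = 0.70),
    fearful   = c(AU1 = 0.50, AU2 = 0.30, AU4 = 0.30, AU5 = 0.60,
                  AU20 = 0.60, AU25 = 0.40),
    disgusted = c(AU9 = 0.70, AU10 = 0.50, AU4 = 0.30, AU7 = 0.40)
  )
  a <- culture_map(c(shared, list(
    angry = c(AU4 = 0.50, AU22 = 0.85),
    sad   = c(AU1 = 0.50, AU15 = 0.75)
  )), name = "culture-A")
  if (pair == "identical-cultures") {
    b <- culture_map(c(shared, list(
      angry = c(AU4 = 0.50, AU22 = 0.85),
      sad   = c(AU1 = 0.50, AU15 = 0.75)
    )), name = "culture-B")
    return(list(A = a, B = b))
  }
  if (pair == "default-twin") {
    b <- culture_map(c(shared, list(
      angry = c(AU4 = 0.50, AU23 = 0.85),
      sad   = c(AU1 = 0.50, AU15 = 0.75, AU22 = 0.60)
    )), name = "culture-B")
    return(list(A = a, B = b))
  }
  # disjoint: every non-neutral expression of B uses AU sets foreign to
  # the same expression (a derangement of A's patterns)
  b <- culture_map(list(
    neutral   = c(),
    happy     = c(AU4 = 0.80, AU22 = 0.70),              # A's angry
    surprised = c(AU9 = 0.70, AU10 = 0.50, AU7 = 0.40),  # A's disgusted core
    fearful   = c(AU12 = 0.85, AU6 = 0.50),              # A's happy
    disgusted = c(AU1 = 0.50, AU15 = 0.70),              # A's sad
    angry     = c(AU1 = 0.60, AU2 = 0.60, AU5 = 0.70, AU26 = 0.70), # A's surprised
    sad       = c(AU20 = 0.60, AU25 = 0.40, AU5 = 0.60, AU2 = 0.30) # A's fearful core
  ), name = "culture-B")
  list(A = a, B = b)
}

#' Sample an AU configuration for an expression
#'
#' Draws each action-unit intensity from a truncated normal
#' distribution: a normal draw around the culture's mean intensity,
#' clipped to \[0, 1\]. The per-AU sd from the culture map is used where
#' given; otherwise `noise_sd` applies. With `noise_sd = 0` (and no
#' per-AU sd) the culture means are returned exactly.
#'
#' @param culture A [culture_map()].
#' @param label Expression label in [EXPRESSIONS].
#' @param noise_sd Fallback intensity sd, `>= 0`.
#' @param seed Integer seed for the draw.
#' @return An [au_vector()].
#' @export
sample_expression_aus <- function(culture, label, noise_sd = 0, seed = 0L) {
  if (!inherits(culture, "culture_map"))
    stopf("sample_expression_aus: `culture` must be a culture_map")
  if (!label %in% EXPRESSIONS)
    stopf("sample_expression_aus: unknown expression label '%s'", label)
  if (noise_sd < 0) stopf("sample_expression_aus: noise_sd must be >= 0")
  mu <- culture$mean[label, ]
  sdv <- culture$sd[label, ]
  sdv[is.na(sdv)] <- noise_sd
  x <- if (all(sdv == 0)) mu else with_seed(seed, {
    clamp(stats::rnorm(20, mu, sdv), 0, 1)
  })
  au_vector(stats::setNames(x, au_keys()))
}

#' @export
print.culture_map <- function(x, ...) {
  cat("<culture_map>", x$name, "\n")
  for (lab in EXPRESSIONS) {
    on <- x$mean[lab, x$mean[lab, ] > 0]
    cat(sprintf("  %-9s %s\n", lab,
                if (!length(on)) "-" else
                  paste(sprintf("%s=%.2f", names(on), on), collapse = " ")))
  }
  invisible(x)
}

#' Read or write a culture map as YAML
#'
#' The document maps each expression label to a map of AU id to mean
#' intensity (optionally `{mean: ..., sd: ...}` maps).
#'
#' @param path File path.
#' @param x A [culture_map()] (for writing).
#' @return `read_culture_map()` returns a [culture_map()].
#' @export
read_culture_map <- function(path) {
  doc <- yaml::read_yaml(path)
  name <- doc$name %||% "culture"
  mapping <- lapply(doc$expressions, function(ent) {
    if (is.list(ent) && !is.null(ent$mean))
      list(mean = unlist(ent$mean), sd = unlist(ent$sd))
    else unlist(ent) %||% c()
  })
  culture_map(mapping, name = name)
}

#' @rdname read_culture_map
#' @export
write_culture_map <- function(x, path) {
  ex <- lapply(EXPRESSIONS, function(lab) {
    on <- x$mean[lab, x$mean[lab, ] > 0]
    as.list(on)
  })
  names(ex) <- EXPRESSIONS
  yaml::write_yaml(list(name = x$name, expressions = ex), path)
  invisible(path)
}
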