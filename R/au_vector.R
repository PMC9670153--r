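#' Construct an action-unit intensity vector
#'
#' An `au_vector` is the coordinate system of both face synthesis and
#' probing: a named numeric vector with one intensity in \[0, 1\] for
#' each of the 20 analyzed action units (see [AU_IDS]). Unspecified AUs
#' default to 0 (no movement).
#'
#' @param x Named numeric vector of intensities. Names may be given as
#'   `"AU12"` or `"12"`. May be empty (the neutral, all-zero vector) or
#'   a full 20-long vector.
#' @return Named numeric vector of length 20, names `AU1 ... AU27` in
#'   the fixed order of [AU_IDS], class `"au_vector"`.
#' @examples
#' au_vector(c(AU12 = 0.8))        # a happy-like configuration
#' au_vector()                     # neutral
#' @export
au_vector <- function(x = numeric()) {
  out <- stats::setNames(numeric(length(AU_IDS)), au_keys())
  if (length(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stopf("au_vector: intensities must be named by AU id")
    nm <- names(x)
    nm <- ifelse(grepl("^AU", nm), nm, paste0("AU", nm))
    bad <- setdiff(nm, au_keys())
    if (length(bad))
      stopf("au_vector: unknown action unit(s): %s (valid: %s)",
            paste(bad, collapse = ", "), paste(au_keys(), collapse = ", "))
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stopf("au_vector: intensities must lie in [0, 1]")
    out[nm] <- as.numeric(x)
  }
  structure(out, class = "au_vector")
}

validate_au_vector <- function(aus) {
  if (inherits(aus, "au_vector")) {
    v <- unclass(aus)
  } else if (is.numeric(aus) && !is.null(names(aus))) {
    v <- unclass(au_vector(aus))
  } else {
    stopf("expected an au_vector or named numeric vector of AU intensities")
  }
  if (!identical(names(v), au_keys()))
    stopf("au_vector: names must be exactly %s", paste(au_keys(), collapse = ", "))
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stopf("au_vector: intensities must lie in [0, 1]")
  v
}

#' @export
print.au_vector <- function(x, ...) {
  on <- x[x > 0]
  if (!length(on)) cat("<au_vector> neutral (all 20 AUs at 0)\n")
  else {
    cat("<au_vector>", length(on), "active of 20 AUs:\n")
    print(round(unclass(on), 3))
  }
  invisible(x)
}
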