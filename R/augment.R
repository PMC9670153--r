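#' Augmentation configuration
#'
#' Defines the deterministic variant grid applied to every preprocessed
#' image: a list of scale factors, a list of pixel position offsets and
#' the reflection setting. The variant count is always the product of
#' the three list lengths; the canonical configuration (5 scales x 5
#' positions x 2 reflections) yields 50 variants per image.
#'
#' @param scales Positive scale factors (default
#'   `c(0.90, 0.95, 1.00, 1.05, 1.10)`).
#' @param offsets List of `c(dx, dy)` integer pixel offsets (default
#'   center plus the four axial shifts of 5% of the input size).
#' @param reflections `"both"` (default), `"off"` or `"on"`.
#' @param input_size Network input side in pixels (canonical 224).
#' @return Object of class `"augment_config"`.
#' @export
augment_config <- function(scales = c(0.90, 0.95, 1.00, 1.05, 1.10),
                           offsets = NULL, reflections = "both",
                           input_size = 224L) {
  if (input_size < 32) stopf("augment_config: input_size must be >= 32")
  if (!length(scales) || any(scales <= 0))
    stopf("augment_config: scales must be a non-empty list of positive values")
  if (is.null(offsets)) {
    s <- max(1L, round(0.05 * input_size))
    offsets <- list(c(0L, 0L), c(-s, 0L), c(s, 0L), c(0L, -s), c(0L, s))
  }
  if (!length(offsets)) stopf("augment_config: offsets must be non-empty")
  lim <- input_size / 4
  for (i in seq_along(offsets)) {
    off <- offsets[[i]]
    if (length(off) != 2) stopf("augment_config: each offset must be c(dx, dy)")
    if (any(abs(off) >= lim))
      stopf("augment_config: offset %d (%d, %d) exceeds the image margin (|offset| < %g)",
            i, off[1], off[2], lim)
  }
  refl <- switch(match.arg(reflections, c("both", "off", "on")),
                 both = c(FALSE, TRUE), off = FALSE, on = TRUE)
  structure(list(scales = scales, offsets = offsets, reflections = refl,
                 input_size = as.integer(input_size)),
            class = "augment_config")
}

#' @rdname augment_config
#' @export
n_variants <- function(config) {
  length(config$scales) * length(config$offsets) * length(config$reflections)
}

# Bilinear resampling of `image` to h2 x w2.
resize_bilinear <- function(image, h2, w2) {
  h <- nrow(image); w <- ncol(image)
  ys <- (seq_len(h2) - 0.5) * h / h2 + 0.5
  xs <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  y0 <- clamp(floor(ys), 1, h); y1 <- clamp(y0 + 1, 1, h); fy <- clamp(ys - y0, 0, 1)
  x0 <- clamp(floor(xs), 1, w); x1 <- clamp(x0 + 1, 1, w); fx <- clamp(xs - x0, 0, 1)
  a <- image[y0, x0, drop = FALSE]; b <- image[y0, x1, drop = FALSE]
  c_ <- image[y1, x0, drop = FALSE]; d <- image[y1, x1, drop = FALSE]
  FY <- matrix(fy, h2, w2); FX <- matrix(fx, h2, w2, byrow = TRUE)
  a * (1 - FY) * (1 - FX) + b * (1 - FY) * FX + c_ * FY * (1 - FX) + d * FY * FX
}

#' Resize an image to the square network input
#'
#' The image is scaled (bilinear) so that its longer side equals `size`,
#' preserving aspect ratio, and centered on a square canvas padded with
#' the background value.
#'
#' @param image H x W numeric matrix.
#' @param size Target side in pixels, `>= 32`.
#' @param background Padding value.
#' @return `size` x `size` numeric matrix.
#' @export
resize_to_input <- function(image, size, background = 128) {
  if (size < 32) stopf("resize_to_input: size must be >= 32")
  h <- nrow(image); w <- ncol(image)
  if (h == size && w == size) return(image)
  sc <- size / max(h, w)
  h2 <- max(1L, round(h * sc)); w2 <- max(1L, round(w * sc))
  sm <- resize_bilinear(image, h2, w2)
  out <- matrix(background, size, size)
  oy <- floor((size - h2) / 2); ox <- floor((size - w2) / 2)
  out[oy + seq_len(h2), ox + seq_len(w2)] <- sm
  out
}

# Place a (possibly larger-than-canvas) image onto a size x size canvas
# at a pixel offset from center, clipping overflow, padding background.
paste_center <- function(image, size, dx, dy, background) {
  out <- matrix(background, size, size)
  h <- nrow(image); w <- ncol(image)
  oy <- floor((size - h) / 2) + dy; ox <- floor((size - w) / 2) + dx
  sy <- max(1L, 1L - oy); ey <- min(h, size - oy)
  sx <- max(1L, 1L - ox); ex <- min(w, size - ox)
  if (sy > ey || sx > ex) return(NULL)  # image pushed fully out of frame
  out[(oy + sy):(oy + ey), (ox + sx):(ox + ex)] <- image[sy:ey, sx:ex]
  out
}

#' Expand one image into its deterministic augmentation variants
#'
#' Produces `|scales| x |offsets| x |reflections|` variants in a fixed
#' lexicographic order (scale slowest, then offset, then reflection).
#' Each variant is the input resized so its longer side equals
#' `scale * input_size`, placed at the position offset on a square
#' canvas of the input size, then optionally mirrored left-to-right.
#'
#' @param image H x W numeric matrix (a preprocessed crop).
#' @param config An [augment_config()].
#' @param background Padding value for the canvas.
#' @return List of `n_variants(config)` matrices, with a `variants`
#'   attribute (data frame: scale, dx, dy, reflected, centered).
#' @export
make_variants <- function(image, config = augment_config(), background = 128) {
  size <- config$input_size
  out <- vector("list", n_variants(config))
  meta <- vector("list", n_variants(config))
  k <- 0L
  for (sc in config$scales) {
    long <- max(32L, round(sc * size))
    h <- nrow(image); w <- ncol(image)
    f <- long / max(h, w)
    scaled <- resize_bilinear(image, max(1L, round(h * f)), max(1L, round(w * f)))
    for (off in config$offsets) {
      placed <- paste_center(scaled, size, off[1], off[2], background)
      for (refl in config$reflections) {
        k <- k + 1L
        if (is.null(placed))
          stopf("make_variants: variant %d (scale %.2f, offset %d,%d) falls outside the input frame",
                k, sc, off[1], off[2])
        out[[k]] <- if (refl) placed[, rev(seq_len(size))] else placed
        meta[[k]] <- data.frame(scale = sc, dx = off[1], dy = off[2],
                                reflected = refl,
                                centered = (sc == 1 && off[1] == 0 &&
                                            off[2] == 0 && !refl))
      }
    }
  }
  attr(out, "variants") <- do.call(rbind, meta)
  out
}
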