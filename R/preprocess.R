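#' Image standardization configuration
#'
#' Controls the standardization applied to every image before it reaches
#' the network: histogram adjustment to a target mean/sd and oval
#' masking of everything outside the facial region.
#'
#' @param target_mean Target pixel mean after histogram adjustment
#'   (default 128).
#' @param target_sd Target pixel sd (default 32, must be `> 0`).
#' @param oval_rx,oval_ry Semi-axes of the mask oval as fractions of the
#'   crop width resp. height, in `(0, 1]`.
#' @param softness Width of the smooth mask boundary as a fraction of
#'   the crop height (default 0.05).
#' @param background Gray value outside the oval, in \[0, 255\]
#'   (default 128 so masking barely shifts the global mean).
#' @return Object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(target_mean = 128, target_sd = 32,
                              oval_rx = 0.46, oval_ry = 0.48,
                              softness = 0.05, background = 128) {
  if (target_sd <= 0) stopf("preprocess_config: target_sd must be > 0")
  if (oval_rx <= 0 || oval_rx > 1 || oval_ry <= 0 || oval_ry > 1)
    stopf("preprocess_config: oval semi-axes must lie in (0, 1]")
  if (background < 0 || background > 255)
    stopf("preprocess_config: background must lie in [0, 255]")
  structure(list(target_mean = target_mean, target_sd = target_sd,
                 oval_rx = oval_rx, oval_ry = oval_ry,
                 softness = softness, background = background),
            class = "preprocess_config")
}

#' Convert an RGB raster to grayscale
#'
#' Luminance-weighted combination with the standard weights
#' (0.299, 0.587, 0.114). Already-grayscale input (a plain matrix) is
#' returned unchanged.
#'
#' @param raster H x W x 3 array in \[0, 255\], or an H x W matrix.
#' @return H x W numeric matrix in \[0, 255\].
#' @export
to_grayscale <- function(raster) {
  if (is.matrix(raster)) return(raster)
  d <- dim(raster)
  if (length(d) != 3 || d[3] != 3)
    stopf("to_grayscale: expected an H x W x 3 RGB array (got %s channels)",
          if (length(d) == 3) d[3] else "unknown")
  0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
}

#' Crop the facial region
#'
#' Face detection is replaced by a bounding box: for synthetic images
#' the box comes from the generator's known geometry ([face_bbox()]);
#' for external images a user-supplied box is required.
#'
#' @param image H x W matrix.
#' @param bbox Integer vector `c(x1, y1, x2, y2)` (columns `x`, rows
#'   `y`, inclusive, 1-based) fully inside the image.
#' @return The cropped matrix of dimensions `(y2-y1+1) x (x2-x1+1)`.
#' @export
crop_face <- function(image, bbox) {
  if (length(bbox) != 4) stopf("crop_face: bbox must be c(x1, y1, x2, y2)")
  x1 <- bbox[1]; y1 <- bbox[2]; x2 <- bbox[3]; y2 <- bbox[4]
  if (x1 < 1 || y1 < 1 || x2 > ncol(image) || y2 > nrow(image) ||
      x1 > x2 || y1 > y2)
    stopf("crop_face: bbox [%d,%d,%d,%d] out of bounds for %d x %d image",
          x1, y1, x2, y2, nrow(image), ncol(image))
  image[y1:y2, x1:x2, drop = FALSE]
}

#' Bounding box of the synthetic face oval
#'
#' @param size Rendered image side in pixels.
#' @return `c(x1, y1, x2, y2)` covering the template face oval with a
#'   small margin.
#' @export
face_bbox <- function(size) {
  c(x1 = max(1L, as.integer(floor(0.095 * size))),
    y1 = max(1L, as.integer(floor(0.030 * size))),
    x2 = as.integer(ceiling(0.905 * size)),
    y2 = as.integer(ceiling(0.985 * size)))
}

#' Adjust the pixel-intensity histogram
#'
#' Affine remap `v' = (v - mean(v)) / sd(v) * target_sd + target_mean`
#' using the population standard deviation, followed by clipping to
#' \[0, 255\]. Before clipping, the result has exactly the target mean
#' and sd (up to numerical tolerance).
#'
#' @param image H x W numeric matrix with non-constant pixels.
#' @param config A [preprocess_config()].
#' @param clip Clip the remapped values to \[0, 255\] (default); set
#'   `FALSE` to inspect the exact pre-clipping remap.
#' @return Adjusted numeric matrix.
#' @export
histogram_adjust <- function(image, config = preprocess_config(), clip = TRUE) {
  m <- mean(image)
  s <- sqrt(mean((image - m)^2))      # population sd
  if (s == 0)
    stopf("histogram_adjust: degenerate histogram (constant image, sd = 0)")
  out <- (image - m) / s * config$target_sd + config$target_mean
  if (clip) clamp(out, 0, 255) else out
}

#' Mask everything outside the facial oval
#'
#' Pixels outside the centered oval plus its transition band are set to
#' the background value; pixels inside the oval are unchanged; within
#' the band the original value blends linearly with the background as a
#' function of radial distance. Exactly idempotent.
#'
#' @param image H x W numeric matrix.
#' @param config A [preprocess_config()].
#' @return Masked numeric matrix.
#' @export
apply_oval_mask <- function(image, config = preprocess_config()) {
  h <- nrow(image); w <- ncol(image)
  cy <- (1 + h) / 2; cx <- (1 + w) / 2
  ry <- config$oval_ry * h; rx <- config$oval_rx * w
  Y <- matrix(seq_len(h), h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  q <- sqrt(((X - cx) / rx)^2 + ((Y - cy) / ry)^2)
  band <- max(config$softness * h, .Machine$double.eps) / min(rx, ry)
  inside <- clamp((1 + band - q) / band, 0, 1)   # 1 inside oval, 0 outside band
  image * inside + config$background * (1 - inside)
}

#' Standardize one image for the network
#'
#' The full standardization pipeline in its fixed order: grayscale
#' conversion, face crop, histogram adjustment (statistics taken over
#' the crop, before masking), oval mask.
#'
#' @param image Raster (matrix or RGB array).
#' @param bbox Face bounding box; defaults to the synthetic-template
#'   box for the image's size (square images only).
#' @param config A [preprocess_config()].
#' @return Preprocessed numeric matrix.
#' @export
preprocess_image <- function(image, bbox = NULL, config = preprocess_config()) {
  g <- to_grayscale(image)
  if (is.null(bbox)) {
    if (nrow(g) != ncol(g))
      stopf("preprocess_image: a bbox is required for non-square images")
    bbox <- face_bbox(nrow(g))
  }
  cr <- crop_face(g, bbox)
  apply_oval_mask(histogram_adjust(cr, config), config)
}
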