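#' Create a synthetic face identity
#'
#' A face identity is a set of small, bounded perturbations of the
#' template face geometry (eye spacing and size, brow height, mouth
#' width and position, face-oval aspect, nose length, skin tone) plus a
#' texture seed controlling a faint smooth shading pattern. The same
#' `(id, seed)` pair always reproduces the same geometry.
#'
#' @param id Identity label (string).
#' @param seed Integer seed from which the geometric offsets are drawn.
#' @return An object of class `"face_identity"`.
#' @seealso [face_identity_average()] for the offset-free template face
#'   used as the probe stimulus carrier.
#' @export
face_identity <- function(id, seed = 0L) {
  s <- derive_seed(seed, "identity", id)
  off <- with_seed(s, {
    rn <- function(sd, lim = 2 * sd) clamp(stats::rnorm(1, 0, sd), -lim, lim)
    list(
      eye_dx     = rn(0.008),
      eye_dy     = rn(0.008),
      eye_h_fac  = clamp(1 + stats::rnorm(1, 0, 0.10), 0.80, 1.20),
      brow_dy    = rn(0.010),
      mouth_wfac = clamp(1 + stats::rnorm(1, 0, 0.08), 0.84, 1.16),
      mouth_dy   = rn(0.010),
      oval_wfac  = clamp(1 + stats::rnorm(1, 0, 0.05), 0.90, 1.10),
      oval_hfac  = clamp(1 + stats::rnorm(1, 0, 0.05), 0.90, 1.10),
      nose_len   = rn(0.012),
      tone       = clamp(stats::rnorm(1, 0, 8), -16, 16),
      tex_amp    = stats::runif(1, 2, 5),
      tex_freq   = stats::runif(3, 2, 7),
      tex_ang    = stats::runif(3, 0, pi),
      tex_phase  = stats::runif(3, 0, 1)
    )
  })
  structure(list(id = as.character(id), seed = as.integer(seed), offsets = off),
            class = "face_identity")
}

#' @rdname face_identity
#' @export
face_identity_average <- function() {
  zero <- list(eye_dx = 0, eye_dy = 0, eye_h_fac = 1, brow_dy = 0,
               mouth_wfac = 1, mouth_dy = 0, oval_wfac = 1, oval_hfac = 1,
               nose_len = 0, tone = 0, tex_amp = 0,
               tex_freq = c(0, 0, 0), tex_ang = c(0, 0, 0),
               tex_phase = c(0, 0, 0))
  structure(list(id = "average", seed = NA_integer_, offsets = zero),
            class = "face_identity")
}

# --- low-level drawing helpers (normalized coordinates, y increases
# downwards, anti-aliased by a ~1.5-pixel soft edge) -------------------

seg_dist <- function(X, Y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 < 1e-12) return(sqrt((X - x1)^2 + (Y - y1)^2))
  t <- clamp(((X - x1) * dx + (Y - y1) * dy) / L2, 0, 1)
  sqrt((X - x1 - t * dx)^2 + (Y - y1 - t * dy)^2)
}

ellipse_mask <- function(X, Y, cx, cy, rx, ry, aa) {
  q <- sqrt(((X - cx) / rx)^2 + ((Y - cy) / ry)^2)
  clamp(0.5 - (q - 1) * min(rx, ry) / aa, 0, 1)
}

band_mask <- function(d, halfw, aa) clamp((halfw - d) / aa + 0.5, 0, 1)

blend <- function(img, val, mask, w = 1) img + (val - img) * (mask * w)

# Resolve template geometry + identity offsets + AU displacement fields
# into concrete drawing parameters. Each AU drives a documented,
# spatially local deformation; magnitudes scale linearly with intensity.
face_params <- function(identity, v) {
  o <- identity$offsets
  g <- function(k) v[[paste0("AU", k)]]

  # upper face -----------------------------------------------------------
  brow_in_y  <- 0.315 + o$brow_dy - 0.050 * g(1) + 0.045 * g(4)
  brow_out_y <- 0.300 + o$brow_dy - 0.050 * g(2) + 0.020 * g(4)
  brow_in_x  <- 0.075 - 0.018 * g(4)           # AU4 pulls brows together
  brow_out_x <- 0.235
  eye_dx   <- 0.155 + o$eye_dx
  eye_cy   <- 0.400 + o$eye_dy
  # AU5 widens the palpebral fissure, AU7 narrows it, AU6 pushes the
  # lower lid up from below
  eye_open <- o$eye_h_fac * (1 + 0.55 * g(5) - 0.45 * g(7) - 0.25 * g(6))
  eye_open <- max(eye_open, 0.25)

  # nose ----------------------------------------------------------------
  nose_tip <- 0.600 + o$nose_len - 0.035 * g(9)   # AU9 shortens / wrinkles

  # mouth ---------------------------------------------------------------
  chin_dy  <- 0.022 * g(26) + 0.045 * g(27)       # jaw drop lowers the chin
  mouth_cy <- 0.730 + o$mouth_dy + 0.5 * chin_dy
  mw <- 0.155 * o$mouth_wfac +
    0.030 * g(12) + 0.055 * g(20) - 0.040 * g(22) -
    0.015 * g(23) - 0.020 * g(27)
  mw <- max(mw, 0.06)
  lip_th <- 0.020 + 0.026 * g(22) - 0.011 * g(23) - 0.008 * g(24)
  lip_th <- max(lip_th, 0.006)
  corner_dy <- -0.038 * g(12) + 0.038 * g(15)     # up for AU12, down for AU15
  top_dy    <- 0.026 * g(10)                      # upper lip raised
  bottom_dy <- 0.030 * g(16) - 0.020 * g(17)      # lowered (AU16) / raised (AU17)
  aperture  <- 0.015 * g(22) + 0.018 * g(10) + 0.020 * g(16) +
    0.028 * g(25) + 0.055 * g(26) + 0.095 * g(27)
  aperture  <- max(aperture - 0.035 * g(24), 0)   # AU24 presses the lips shut

  list(
    oval = list(cx = 0.5, cy = 0.49, rx = 0.360 * o$oval_wfac,
                ry = 0.430 * o$oval_hfac, chin_dy = chin_dy),
    skin = 190 + o$tone,
    brows = list(in_x = brow_in_x, in_y = brow_in_y,
                 out_x = brow_out_x, out_y = brow_out_y, halfw = 0.0115),
    eyes = list(dx = eye_dx, cy = eye_cy, rx = 0.085,
                ry = 0.038 * eye_open, iris_r = 0.027),
    nose = list(tip = nose_tip, wrinkle = g(9)),
    cheek = list(raise = g(6)),
    nasolabial = 0.15 + 0.55 * g(11) + 0.30 * g(6),
    mouth = list(cy = mouth_cy, mw = mw, th = lip_th, corner_dy = corner_dy,
                 top_dy = top_dy, bottom_dy = bottom_dy, ap = aperture,
                 press = g(24)),
    chin_crease = 0.08 + 0.60 * g(17),
    chin_crease_y = mouth_cy + 0.075 - 0.018 * g(17),
    tex = o[c("tex_amp", "tex_freq", "tex_ang", "tex_phase")]
  )
}

#' Render a synthetic grayscale face
#'
#' Draws the parametric template face of geometric primitives (face
#' oval, brows, eyes, nose, mouth, shading lines) after applying the
#' identity's geometry offsets and the AU-indexed control-point
#' displacements. Each action unit drives a local deformation whose
#' magnitude scales linearly with its intensity, e.g. AU#12 displaces
#' the mouth corners upward/outward, AU#4 lowers and narrows the brows,
#' AU#26/#27 open the jaw, AU#5 raises the upper lid. Rendering is fully
#' deterministic: identical arguments give bit-identical rasters.
#'
#' @param identity A [face_identity()].
#' @param aus An [au_vector()] (or named numeric convertible to one).
#' @param size Output raster side in pixels (square), `>= 32`.
#' @return `size` x `size` integer matrix with values in \[0, 255\].
#' @export
render_face <- function(identity, aus = au_vector(), size = 64L) {
  if (!inherits(identity, "face_identity"))
    stopf("render_face: `identity` must be a face_identity")
  if (!is.numeric(size) || size < 32)
    stopf("render_face: `size` must be >= 32 pixels")
  size <- as.integer(size)
  v <- validate_au_vector(aus)
  p <- face_params(identity, as.list(v))

  xs <- (seq_len(size) - 0.5) / size
  X <- matrix(xs, size, size, byrow = TRUE)   # column coordinate
  Y <- matrix(xs, size, size)                 # row coordinate, downwards
  aa <- 1.5 / size

  img <- matrix(60, size, size)               # background

  # face oval; the lower semi-axis stretches with jaw drop
  ov <- p$oval
  ry_eff <- ov$ry + ov$chin_dy * (Y > ov$cy)
  q <- sqrt(((X - ov$cx) / ov$rx)^2 + ((Y - ov$cy) / ry_eff)^2)
  m_oval <- clamp(0.5 - (q - 1) * min(ov$rx, ov$ry) / aa, 0, 1)
  img <- blend(img, p$skin, m_oval)

  # identity texture: faint sum of oriented cosine gratings, face only
  tx <- p$tex
  if (tx$tex_amp > 0) {
    tex <- 0
    for (k in 1:3) {
      u <- cos(tx$tex_ang[k]) * X + sin(tx$tex_ang[k]) * Y
      tex <- tex + cos(2 * pi * (tx$tex_freq[k] * u + tx$tex_phase[k]))
    }
    img <- img + (tx$tex_amp / 3) * tex * m_oval
  }

  # cheek raise (AU6): soft brightening under the eyes
  if (p$cheek$raise > 0) {
    for (sgn in c(-1, 1)) {
      m <- ellipse_mask(X, Y, 0.5 + sgn * 0.170, 0.520, 0.060, 0.045, aa * 2)
      img <- blend(img, 215, m * m_oval, 0.5 * p$cheek$raise)
    }
  }

  # nasolabial furrows
  for (sgn in c(-1, 1)) {
    d <- seg_dist(X, Y, 0.5 + sgn * 0.045, 0.600,
                  0.5 + sgn * (0.100 + 0.020 * p$cheek$raise), 0.700)
    img <- blend(img, 120, band_mask(d, 0.008, aa), clamp(p$nasolabial, 0, 1))
  }

  # brows
  b <- p$brows
  for (sgn in c(-1, 1)) {
    d <- seg_dist(X, Y, 0.5 + sgn * b$in_x, b$in_y, 0.5 + sgn * b$out_x, b$out_y)
    img <- blend(img, 70, band_mask(d, b$halfw, aa))
  }

  # eyes: sclera ellipse + iris disk clipped to the sclera
  e <- p$eyes
  for (sgn in c(-1, 1)) {
    cx <- 0.5 + sgn * e$dx
    m_sc <- ellipse_mask(X, Y, cx, e$cy, e$rx, e$ry, aa)
    img <- blend(img, 233, m_sc)
    m_ir <- ellipse_mask(X, Y, cx, e$cy, e$iris_r, e$iris_r, aa)
    img <- blend(img, 60, m_ir * m_sc)
  }

  # nose bridge, nostrils, AU9 root wrinkles
  n <- p$nose
  d <- seg_dist(X, Y, 0.500, 0.440, 0.505, n$tip)
  img <- blend(img, 150, band_mask(d, 0.007, aa))
  for (sgn in c(-1, 1)) {
    m <- ellipse_mask(X, Y, 0.5 + sgn * 0.024, n$tip + 0.012, 0.009, 0.007, aa)
    img <- blend(img, 95, m)
  }
  if (n$wrinkle > 0) {
    for (k in 1:2) {
      yw <- 0.436 - 0.014 * k
      d <- seg_dist(X, Y, 0.455, yw, 0.545, yw)
      img <- blend(img, 100, band_mask(d, 0.005, aa), n$wrinkle)
    }
  }

  # mouth: two lip bands around parabolic lip curves + dark aperture
  mo <- p$mouth
  U <- (X - 0.5) / mo$mw
  lat <- clamp((1 - abs(U)) * mo$mw / aa + 0.5, 0, 1)
  yu <- mo$cy - mo$ap / 2 - mo$top_dy + mo$corner_dy * U^2
  yl <- mo$cy + mo$ap / 2 + mo$bottom_dy + mo$corner_dy * U^2
  th_x <- pmax(mo$th * (1 - 0.6 * U^2), 0.004)
  lip_val <- 110 - 35 * mo$press
  img <- blend(img, lip_val, lat * band_mask(abs(Y - yu), th_x, aa))
  img <- blend(img, lip_val, lat * band_mask(abs(Y - yl), th_x, aa))
  lat_in <- clamp((0.92 - abs(U)) * mo$mw / aa + 0.5, 0, 1)
  m_ap <- lat_in *
    clamp(((yl - th_x / 2) - Y) / aa + 0.5, 0, 1) *
    clamp((Y - (yu + th_x / 2)) / aa + 0.5, 0, 1)
  img <- blend(img, 45, m_ap)

  # chin boss crease (AU17)
  d <- seg_dist(X, Y, 0.450, p$chin_crease_y, 0.550, p$chin_crease_y)
  img <- blend(img, 120, band_mask(d, 0.006, aa), clamp(p$chin_crease, 0, 1))

  matrix(as.integer(round(clamp(img, 0, 255))), size, size)
}

#' @export
print.face_identity <- function(x, ...) {
  cat("<face_identity>", x$id,
      if (is.na(x$seed)) "(average template)" else sprintf("(seed %d)", x$seed),
      "\n")
  invisible(x)
}
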