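#' Specify a synthetic face database
#'
#' @param name Database name (tag carried by every image).
#' @param culture A [culture_map()] defining the expression-to-AU
#'   mapping of the database's posers.
#' @param n_identities Number of posers (default 60, minimum 12 so the
#'   canonical 40/8/12-proportioned split stays supportable).
#' @param noise_sd Intensity sd of the truncated-normal AU noise applied
#'   around the culture means (per-AU sds in the culture map take
#'   precedence).
#' @param seed Integer seed; the database is fully deterministic given
#'   the seed.
#' @param image_size Rendered image side in pixels.
#' @return Object of class `"database_spec"`.
#' @export
database_spec <- function(name, culture, n_identities = 60L, noise_sd = 0.1,
                          seed = 0L, image_size = 80L) {
  if (!inherits(culture, "culture_map"))
    stopf("database_spec: `culture` must be a culture_map")
  if (n_identities < 12)
    stopf("database_spec: n_identities must be >= 12")
  if (noise_sd < 0) stopf("database_spec: noise_sd must be >= 0")
  if (image_size < 32) stopf("database_spec: image_size must be >= 32")
  structure(list(name = name, culture = culture,
                 n_identities = as.integer(n_identities),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 image_size = as.integer(image_size)),
            class = "database_spec")
}

labeled_image <- function(pixels, label, identity, database) {
  structure(list(pixels = pixels, label = label, identity = identity,
                 database = database),
            class = "labeled_image")
}

#' Generate a synthetic face database
#'
#' Renders one image per (identity, expression) pair: `n_identities`
#' posers, each displaying all seven expressions, with AU intensities
#' drawn from the database's culture map under truncated-normal noise.
#' Deterministic given the spec's seed.
#'
#' @param spec A [database_spec()].
#' @return Object of class `"face_database"`: list with `spec`,
#'   `images` (list of labeled images, identity-major, expressions in
#'   [EXPRESSIONS] order) and `identities` (character vector).
#' @export
generate_database <- function(spec) {
  if (!inherits(spec, "database_spec"))
    stopf("generate_database: `spec` must be a database_spec")
  ids <- sprintf("%s-id%02d", spec$name, seq_len(spec$n_identities))
  images <- vector("list", spec$n_identities * 7L)
  k <- 0L
  for (i in seq_len(spec$n_identities)) {
    ident <- face_identity(ids[i], seed = derive_seed(spec$seed, "geom", i))
    for (lab in EXPRESSIONS) {
      aus <- sample_expression_aus(spec$culture, lab, spec$noise_sd,
                                   seed = derive_seed(spec$seed, "aus", i, lab))
      k <- k + 1L
      images[[k]] <- labeled_image(render_face(ident, aus, spec$image_size),
                                   lab, ids[i], spec$name)
    }
  }
  structure(list(spec = spec, images = images, identities = ids),
            class = "face_database")
}

#' @export
print.face_database <- function(x, ...) {
  cat(sprintf("<face_database> %s: %d identities x 7 expressions = %d images (%dpx, noise sd %.2g)\n",
              x$spec$name, x$spec$n_identities, length(x$images),
              x$spec$image_size, x$spec$noise_sd))
  invisible(x)
}

#' Generate the AU probe stimulus set
#'
#' Builds the 20 single-AU image series used to measure output-unit
#' tuning: for each action unit, the template face is rendered with
#' that AU alone at `steps` intensities spanning 0 to 1 while all other
#' AUs are shut off. The intensity-0 image (the "null image") contains
#' no AU and is bit-identical across all 20 series. The template is the
#' average face (all identity offsets zero).
#'
#' @param size Image side in pixels.
#' @param steps Number of intensity steps (default 11, i.e. 0.0, 0.1,
#'   ..., 1.0).
#' @param template Carrier [face_identity()]; defaults to the average
#'   face.
#' @return Object of class `"probe_set"`: list with `null` (raster),
#'   `series` (named list, one entry per AU key, each a list of `steps`
#'   rasters), `intensities` and `size`.
#' @export
generate_probe_set <- function(size = 80L, steps = 11L,
                               template = face_identity_average()) {
  if (steps < 2) stopf("generate_probe_set: steps must be >= 2")
  grid <- seq(0, 1, length.out = steps)
  null_img <- render_face(template, au_vector(), size)
  series <- lapply(au_keys(), function(key) {
    lapply(grid, function(t) {
      if (t == 0) null_img                       # shared null image
      else render_face(template, au_vector(stats::setNames(t, key)), size)
    })
  })
  names(series) <- au_keys()
  structure(list(null = null_img, series = series, intensities = grid,
                 size = as.integer(size), template = template),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %d AU series x %d intensities (%dpx), shared null image\n",
              length(x$series), length(x$intensities), x$size))
  invisible(x)
}

#' Write or read a face database as PNG files plus a CSV manifest
#'
#' Images are written as 8-bit grayscale PNGs; the manifest has columns
#' `path, label, identity, database`.
#'
#' @param db A `"face_database"` (or any list of labeled images).
#' @param dir Output directory (created if needed).
#' @param manifest Path to a manifest CSV (for reading).
#' @return `write_database()` returns the manifest path invisibly;
#'   `read_database()` returns a list of labeled images with a
#'   `manifest` attribute.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  images <- if (inherits(db, "face_database")) db$images else db
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    fn <- sprintf("%s_%s.png", im$identity, im$label)
    png::writePNG(im$pixels / 255, file.path(dir, fn))
    data.frame(path = fn, label = im$label, identity = im$identity,
               database = im$database, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}

#' @rdname write_database
#' @export
read_database <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("path", "label", "identity", "database")
  if (!all(need %in% names(man)))
    stopf("read_database: manifest must have columns %s",
          paste(need, collapse = ", "))
  bad <- setdiff(unique(man$label), EXPRESSIONS)
  if (length(bad))
    stopf("read_database: unknown label(s) in manifest: %s",
          paste(bad, collapse = ", "))
  dir <- dirname(manifest)
  images <- lapply(seq_len(nrow(man)), function(i) {
    px <- png::readPNG(file.path(dir, man$path[i]))
    if (length(dim(px)) == 3) px <- to_grayscale(px * 255) else px <- px * 255
    labeled_image(matrix(as.integer(round(px)), nrow(px), ncol(px)),
                  man$label[i], man$identity[i], man$database[i])
  })
  attr(images, "manifest") <- man
  images
}
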