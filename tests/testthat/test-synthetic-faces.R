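test_that("au_vector enforces the 20-AU coordinate system", {
  v <- au_vector()
  expect_length(v, 20)
  expect_identical(names(v), paste0("AU", AU_IDS))
  expect_true(all(v == 0))

  v <- au_vector(c(AU12 = 0.8, `4` = 0.3))
  expect_equal(unname(v["AU12"]), 0.8)
  expect_equal(unname(v["AU4"]), 0.3)
  expect_equal(sum(v > 0), 2)

  expect_error(au_vector(c(AU3 = 0.5)), "unknown action unit.*AU3")
  expect_error(au_vector(c(AU12 = 1.2)), "\\[0, 1\\]")
  expect_error(au_vector(c(AU12 = -0.1)), "\\[0, 1\\]")
})

test_that("rendering is deterministic and zero deformation is the identity", {
  id <- face_identity("p1", seed = 5)
  a <- render_face(id, au_vector(), 64)
  b <- render_face(id, au_vector(), 64)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 255))
  expect_true(is.integer(a))

  # same (id, seed) reproduces identical geometry
  id2 <- face_identity("p1", seed = 5)
  expect_identical(render_face(id2, au_vector(), 64), a)
  # different seed changes the face
  id3 <- face_identity("p1", seed = 6)
  expect_false(identical(render_face(id3, au_vector(), 64), a))

  expect_error(render_face(id, au_vector(), 16), ">= 32")
})

test_that("AU#12 deformation is confined to the lower face half", {
  id <- face_identity("p2", seed = 1)
  neutral <- render_face(id, au_vector(), 96)
  smiling <- render_face(id, au_vector(c(AU12 = 1)), 96)
  d <- abs(smiling - neutral)
  expect_identical(sum(d[1:48, ]), 0L)     # upper half untouched
  expect_gt(sum(d[49:96, ]), 0)            # lower half deformed
})

test_that("deformation magnitude grows monotonically with AU intensity", {
  id <- face_identity_average()
  neutral <- render_face(id, au_vector(), 64)
  for (k in c(1L, 5L, 12L, 22L, 23L, 26L)) {
    l1 <- vapply(seq(0, 1, 0.25), function(t) {
      v <- au_vector(stats::setNames(t, paste0("AU", k)))
      sum(abs(render_face(id, v, 64) - neutral))
    }, numeric(1))
    expect_false(is.unsorted(l1), label = sprintf("AU%d L1 monotone", k))
    expect_gt(l1[5], 0)
  }
})

test_that("expression sampling follows the culture map", {
  cu <- default_cultures("default-twin")$A
  # degenerate sd returns the means exactly
  v <- sample_expression_aus(cu, "happy", noise_sd = 0, seed = 1)
  expect_equal(unname(v["AU12"]), 0.85)
  expect_equal(unname(v["AU6"]), 0.50)
  expect_equal(sum(v > 0), 2)
  expect_true(all(sample_expression_aus(cu, "neutral", 0, 1) == 0))
  expect_error(sample_expression_aus(cu, "smug", 0, 1), "unknown expression")

  # truncated-normal draws: sample mean of a mid-range AU stays unbiased
  draws <- vapply(1:10000, function(i)
    sample_expression_aus(cu, "sad", noise_sd = 0.1, seed = i)["AU1"],
    numeric(1))
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("generate_database yields one image per identity-expression pair", {
  cu <- default_cultures("default-twin")$A
  spec <- database_spec("T", cu, n_identities = 12, noise_sd = 0.05,
                        seed = 9, image_size = 64)
  db <- generate_database(spec)
  expect_length(db$images, 12 * 7)
  labs <- vapply(db$images, `[[`, character(1), "label")
  ids <- vapply(db$images, `[[`, character(1), "identity")
  expect_equal(as.vector(table(labs)[EXPRESSIONS]), rep(12L, 7))
  expect_true(all(table(ids, labs) == 1))

  # determinism: regenerate-and-compare is byte-wise identical
  db2 <- generate_database(spec)
  expect_identical(lapply(db$images, `[[`, "pixels"),
                   lapply(db2$images, `[[`, "pixels"))

  expect_error(database_spec("T", cu, n_identities = 8), ">= 12")
})

test_that("culture separability: only divergent expressions differ between twins", {
  tw <- default_cultures("default-twin")
  mk <- function(cu) generate_database(
    database_spec("X", cu, n_identities = 12, noise_sd = 0.08,
                  seed = 77, image_size = 64))
  da <- mk(tw$A); db <- mk(tw$B)
  labs <- vapply(da$images, `[[`, character(1), "label")
  for (lab in c("neutral", "happy", "surprised", "fearful", "disgusted")) {
    i <- which(labs == lab)
    expect_identical(lapply(da$images[i], `[[`, "pixels"),
                     lapply(db$images[i], `[[`, "pixels"))
  }
  for (lab in c("angry", "sad")) {
    i <- which(labs == lab)
    expect_false(identical(lapply(da$images[i], `[[`, "pixels"),
                           lapply(db$images[i], `[[`, "pixels")))
  }
})

test_that("probe set has 20 series of 11 steps with a shared null image", {
  ps <- generate_probe_set(size = 64, steps = 11)
  expect_length(ps$series, 20)
  expect_identical(names(ps$series), paste0("AU", AU_IDS))
  expect_true(all(lengths(ps$series) == 11))
  expect_equal(ps$intensities, seq(0, 1, 0.1))
  for (key in names(ps$series))
    expect_identical(ps$series[[key]][[1]], ps$null)
  # probe carrier is the average face
  expect_identical(ps$null, render_face(face_identity_average(),
                                        au_vector(), 64))
})

test_that("databases round-trip through PNG + manifest", {
  skip_if_not_installed("png")
  cu <- default_cultures("default-twin")$A
  db <- generate_database(database_spec("RT", cu, n_identities = 12,
                                        noise_sd = 0, seed = 3,
                                        image_size = 48))
  dir <- withr::local_tempdir()
  man <- write_database(db$images[1:14], dir)
  back <- read_database(man)
  expect_length(back, 14)
  expect_identical(back[[1]]$pixels, db$images[[1]]$pixels)
  expect_identical(vapply(back, `[[`, character(1), "label"),
                   vapply(db$images[1:14], `[[`, character(1), "label"))
})
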