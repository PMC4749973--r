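test_that("volume types enforce their invariants", {
  expect_error(intensity_volume(matrix(1, 2, 2), c(1, 1, 1)), "3D")
  expect_error(intensity_volume(array(-1, c(2, 2, 2)), c(1, 1, 1)),
               "non-negative")
  expect_error(intensity_volume(array(1, c(2, 2, 2)), c(1, 0, 1)),
               "positive")
  expect_error(label_volume(array(0.5, c(2, 2, 2)), 1), "binary")
  expect_warning(label_volume(array(0, c(2, 2, 2)), 1), "no foreground")
  v <- intensity_volume(array(2, c(2, 3, 4)), c(1, 2, 3), "dapi")
  expect_identical(dim(v$data), c(2L, 3L, 4L))
  expect_error(as_label_volume(intensity_volume(array(1:8, c(2, 2, 2)),
                                                1)), "not binary")
})

test_that("TIFF volumes round-trip exactly", {
  set.seed(42)
  tmp <- withr::local_tempdir()
  # 8-bit seeded volume
  v8 <- intensity_volume(array(sample(0:255, 8 * 8 * 4, TRUE), c(8, 8, 4)),
                         c(1, 1, 2))
  p8 <- file.path(tmp, "v8.tif")
  write_volume(v8, p8)
  expect_identical(read_volume(p8)$data, v8$data)
  # 16-bit
  v16 <- intensity_volume(array(sample(0:65535, 5 * 7 * 3, TRUE), c(5, 7, 3)),
                          c(0.5, 0.5, 1))
  p16 <- file.path(tmp, "v16.tif")
  write_volume(v16, p16)
  expect_identical(read_volume(p16)$data, v16$data)
  # float
  vf <- intensity_volume(array(runif(4 * 4 * 4), c(4, 4, 4)), c(1, 1, 1))
  pf <- file.path(tmp, "vf.tif")
  write_volume(vf, pf)
  expect_equal(read_volume(pf)$data, vf$data, tolerance = 1e-7)
  # constant-zero label pages are all zero
  pz <- file.path(tmp, "zero.tif")
  suppressWarnings(write_volume(label_volume(array(0, c(4, 4, 4)), 1), pz))
  expect_true(all(read_volume(pz)$data == 0))
})

test_that("TIFF shape contract is (width, height, pages)", {
  tmp <- withr::local_tempdir()
  v <- intensity_volume(array(seq_len(5 * 7 * 3), c(5, 7, 3)), c(1, 1, 1))
  p <- file.path(tmp, "shape.tif")
  write_volume(v, p)
  expect_identical(dim(read_volume(p)$data), c(5L, 7L, 3L))
})

test_that("anisotropic spacing is persisted within 1e-6", {
  tmp <- withr::local_tempdir()
  v <- intensity_volume(array(1, c(4, 4, 4)), c(0.333, 0.333, 0.72))
  p <- file.path(tmp, "sp.tif")
  write_volume(v, p)
  expect_equal(read_volume(p)$spacing, c(0.333, 0.333, 0.72),
               tolerance = 1e-6)
})

test_that("a {0,255} mask reads as a {0,1} label with matching counts", {
  set.seed(7)
  tmp <- withr::local_tempdir()
  raw255 <- array(sample(c(0, 255), 6 * 6 * 3, TRUE), c(6, 6, 3))
  n255 <- sum(raw255 == 255)  # derived before writing
  p <- file.path(tmp, "mask.tif")
  write_volume(intensity_volume(raw255, c(1, 1, 1)), p)
  lab <- read_volume(p, as_label = TRUE)
  expect_s3_class(lab, "label_volume")
  expect_setequal(unique(as.vector(lab$data)), c(0, 1))
  expect_identical(sum(lab$data == 1), n255)
  # non-binary data refused as label
  p2 <- file.path(tmp, "nb.tif")
  write_volume(intensity_volume(array(0:7, c(2, 2, 2)), 1), p2)
  expect_error(read_volume(p2, as_label = TRUE), "not binary")
})

test_that("missing spacing metadata defaults to 1 um with a warning", {
  tmp <- withr::local_tempdir()
  # python's tifffile writes no morphatlas description block
  skip_if_not(nzchar(Sys.which("python")))
  p <- file.path(tmp, "py.tif")
  code <- sprintf(paste0(
    "import numpy, tifffile; ",
    "a = (numpy.arange(120, dtype=numpy.uint16)).reshape(6, 4, 5); ",
    "tifffile.imwrite(%s, a, photometric='minisblack')"), shQuote(p))
  res <- system2("python", c("-c", shQuote(code)))
  skip_if_not(res == 0)
  expect_warning(v <- read_volume(p), "assuming 1 um")
  expect_identical(v$spacing, c(1, 1, 1))
  # (pages, rows, cols) = (6, 4, 5) -> extents (5, 4, 6)
  expect_identical(dim(v$data), c(5L, 4L, 6L))
  expect_identical(v$data[, , 1][1:5], as.numeric(0:4))
})

test_that("tifffile reads our TIFF bit-identically (external oracle)", {
  skip_if_not(nzchar(Sys.which("python")))
  tmp <- withr::local_tempdir()
  set.seed(11)
  v <- intensity_volume(array(sample(0:65535, 6 * 5 * 4, TRUE), c(6, 5, 4)),
                        c(1, 1, 1))
  p <- file.path(tmp, "ours.tif")
  out <- file.path(tmp, "dump.txt")
  write_volume(v, p)
  code <- sprintf(paste0(
    "import numpy, tifffile; a = tifffile.imread(%s); ",
    "numpy.savetxt(%s, a.reshape(-1)[None], fmt='%%d')"),
    shQuote(p), shQuote(out))
  res <- system2("python", c("-c", shQuote(code)))
  skip_if_not(res == 0)
  vals <- scan(out, quiet = TRUE)
  # tifffile returns (pages, rows, cols); C-order flattening runs x
  # fastest, matching R's column-major order on (x, y, z)
  expect_identical(vals, as.vector(v$data))
})

test_that("landmark CSV I/O preserves order and validates", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "lm.csv")
  writeLines(c("name,x,y,z",
               paste0("lm", 1:7, ",", 1:7, ",", (1:7) * 2, ",", (1:7) * 3)),
             p)
  lm <- read_landmarks(p)
  expect_equal(nrow(lm$points), 7)
  expect_identical(lm$names, paste0("lm", 1:7))
  expect_equal(lm$points[3, ], c(x = 3, y = 6, z = 9))
  # empty body errors
  writeLines("name,x,y,z", p)
  expect_error(read_landmarks(p), "no points")
  # duplicate names error
  writeLines(c("name,x,y,z", "a,1,1,1", "a,2,2,2"), p)
  expect_error(read_landmarks(p), "unique")
  # non-numeric coordinates error
  writeLines(c("name,x,y,z", "a,1,foo,1"), p)
  expect_error(read_landmarks(p), "non-numeric")
  # seeded round trip
  set.seed(3)
  lm2 <- landmark_set("obj", paste0("p", 1:5), matrix(runif(15, 0, 50), 5))
  p2 <- file.path(tmp, "rt.csv")
  write_landmarks(lm2, p2)
  back <- read_landmarks(p2, object_id = "obj")
  expect_identical(back$names, lm2$names)
  expect_equal(back$points, lm2$points, tolerance = 1e-12)
})

test_that("OTS containers round-trip losslessly", {
  tmp <- withr::local_tempdir()
  # empty-record OTS
  o0 <- ots("obj", c(8, 9, 10), c(1, 2, 3))
  p <- file.path(tmp, "o0.ots.json")
  write_ots(o0, p)
  b0 <- read_ots(p)
  expect_identical(b0$object_id, "obj")
  expect_identical(b0$volume_shape, c(8L, 9L, 10L))
  expect_length(b0$records, 0)
  # 6 iterations x 3 planes = 18 records with seeded coefficients
  set.seed(5)
  shape <- c(8L, 9L, 10L)
  recs <- list()
  for (it in 1:6) for (pl in c("YZ", "ZX", "XY")) {
    ext <- shape[morphatlas:::plane_axes(pl)$inplane]
    g <- bspline_grid(array(rnorm(5 * 5 * 2), c(5, 5, 2)), ext)
    recs[[length(recs) + 1]] <- ots_record(it, pl, g)
  }
  o <- ots("obj", shape, c(1, 1, 1), recs)
  p2 <- file.path(tmp, "o18.ots.json")
  write_ots(o, p2)
  b <- read_ots(p2)
  expect_length(b$records, 18)
  for (i in seq_len(18)) {
    expect_identical(b$records[[i]]$plane, o$records[[i]]$plane)
    expect_identical(b$records[[i]]$iteration_index,
                     o$records[[i]]$iteration_index)
    expect_identical(b$records[[i]]$transform$coeffs,
                     o$records[[i]]$transform$coeffs)
  }
  # version / format guard
  doc <- jsonlite::fromJSON(p2, simplifyDataFrame = FALSE)
  doc$version <- 99
  p3 <- file.path(tmp, "bad.ots.json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), p3)
  expect_error(read_ots(p3), "version")
  # record extent validated against the plane
  expect_error(
    ots("x", c(8, 9, 10), c(1, 1, 1),
        list(ots_record(1, "XY",
                        bspline_grid(array(0, c(4, 4, 2)), c(9, 10))))),
    "inconsistent")
})

test_that("OTS from the group-wise driver holds 3k records after k iterations", {
  labs <- list(blob_label(c(20, 20, 20), radii = c(6, 5, 4)),
               blob_label(c(20, 20, 20), centre = c(11, 9, 10),
                          radii = c(5, 6, 4)))
  cfg <- groupwise_config(iterations = 2,
                          elastic = elastic_params(final_grid_intervals = 4,
                                                   max_optimizer_steps = 40))
  res <- register_groupwise(labs, cfg)
  expect_length(res$ots[[1]]$records, 6)
  expect_length(res$ots[[2]]$records, 6)
  its <- vapply(res$ots[[1]]$records, `[[`, integer(1), "iteration_index")
  pls <- vapply(res$ots[[1]]$records, `[[`, character(1), "plane")
  expect_identical(its, rep(1:2, each = 3))
  expect_identical(pls, rep(c("YZ", "ZX", "XY"), 2))
})
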