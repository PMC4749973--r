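#' Orthogonal transform sequence (OTS)
#'
#' The ordered, replayable record of the per-plane 2D transforms applied
#' to one object during group-wise registration. Replaying the records in
#' order IS the definition of the object's total transformation; the
#' sequence can be applied to the original label, to derivative intensity
#' or signal volumes, and (via numerical inversion) to landmark sets.
#'
#' @param object_id free-text object identifier.
#' @param volume_shape integer `(nx, ny, nz)` of the volume the sequence
#'   acts on.
#' @param spacing voxel spacing `(sx, sy, sz)` in um.
#' @param records list of records as produced by [ots_record()], ordered
#'   by (iteration, position in plane order).
#' @return An object of class `ots`.
#' @export
ots <- function(object_id, volume_shape, spacing, records = list()) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 1))
    stop("volume_shape must be three positive extents")
  spacing <- check_spacing(spacing)
  for (r in records) check_ots_record(r, volume_shape)
  structure(list(object_id = object_id, volume_shape = volume_shape,
                 spacing = spacing, records = records),
            class = "ots")
}

#' One step of an orthogonal transform sequence
#'
#' @param iteration_index iteration this record belongs to (`>= 1`).
#' @param plane `"YZ"`, `"ZX"` or `"XY"`; the transform acts on every
#'   slice along the plane's projection axis (X, Y, Z respectively).
#' @param transform a [bspline_grid()] whose extent equals the plane's 2D
#'   extent of the parent volume.
#' @return A list with class `ots_record`.
#' @export
ots_record <- function(iteration_index, plane, transform) {
  plane <- match.arg(plane, c("YZ", "ZX", "XY"))
  if (iteration_index < 1) stop("iteration_index must be >= 1")
  structure(list(iteration_index = as.integer(iteration_index),
                 plane = plane, transform = transform),
            class = "ots_record")
}

check_ots_record <- function(r, volume_shape) {
  if (!inherits(r, "ots_record")) stop("records must be ots_record objects")
  ax <- plane_axes(r$plane)
  want <- volume_shape[ax$inplane]
  if (!identical(as.integer(r$transform$image_extent), as.integer(want)))
    stop("record transform extent ", paste(r$transform$image_extent, collapse = "x"),
         " inconsistent with plane ", r$plane, " extent ",
         paste(want, collapse = "x"))
  invisible(r)
}

# Plane conventions: projection axis and ordered in-plane axes (cyclic),
# as volume dimension indices 1 = x, 2 = y, 3 = z.
plane_axes <- function(plane) {
  switch(plane,
         YZ = list(proj = 1L, inplane = c(2L, 3L)),
         ZX = list(proj = 2L, inplane = c(3L, 1L)),
         XY = list(proj = 3L, inplane = c(1L, 2L)),
         stop("unknown plane '", plane, "'"))
}

#' @export
print.ots <- function(x, ...) {
  cat(sprintf("<ots> '%s': %d records on a %s volume\n", x$object_id,
              length(x$records), paste(x$volume_shape, collapse = "x")))
  invisible(x)
}

OTS_FORMAT <- "morphatlas-ots"
OTS_VERSION <- 1L

#' Write an OTS to disk
#'
#' The on-disk form is a versioned JSON container; coefficient blocks are
#' base64-encoded IEEE doubles, so round trips are lossless at full
#' floating precision.
#'
#' @param x an [ots()].
#' @param path output path (conventionally `*.ots.json`).
#' @return `path`, invisibly.
#' @export
write_ots <- function(x, path) {
  recs <- lapply(x$records, function(r) {
    tr <- r$transform
    list(iteration = r$iteration_index,
         plane = r$plane,
         grid = list(shape = dim(tr$coeffs)[1:2],
                     image_extent = tr$image_extent,
                     pixel_spacing = tr$pixel_spacing,
                     coeffs_b64 = jsonlite::base64_enc(
                       writeBin(as.numeric(tr$coeffs), raw(),
                                size = 8, endian = "little"))))
  })
  doc <- list(format = OTS_FORMAT, version = OTS_VERSION,
              object_id = x$object_id, volume_shape = x$volume_shape,
              spacing = x$spacing, records = recs)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read an OTS from disk
#'
#' @param path path written by [write_ots()].
#' @return An [ots()].
#' @export
read_ots <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!identical(doc$format, OTS_FORMAT))
    stop("'", path, "' is not an OTS container")
  if (!identical(as.integer(doc$version), OTS_VERSION))
    stop("unsupported OTS version ", doc$version)
  recs <- lapply(doc$records, function(r) {
    g <- r$grid
    shape <- as.integer(unlist(g$shape))
    n <- shape[1] * shape[2] * 2
    bytes <- jsonlite::base64_dec(g$coeffs_b64)
    if (length(bytes) != 8 * n) stop("corrupted coefficient block in '", path, "'")
    co <- readBin(bytes, "double", n, size = 8, endian = "little")
    ots_record(r$iteration, r$plane,
               bspline_grid(array(co, dim = c(shape, 2L)),
                            as.integer(unlist(g$image_extent)),
                            as.numeric(unlist(g$pixel_spacing))))
  })
  ots(doc$object_id, as.integer(unlist(doc$volume_shape)),
      as.numeric(unlist(doc$spacing)), recs)
}
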