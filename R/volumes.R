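#' 3D intensity volume
#'
#' A 3D array of non-negative scalars indexed `(x, y, z)` (0-based voxel
#' indices in world-coordinate formulas) with anisotropic voxel spacing in
#' micrometres. The world coordinate of voxel `(i, j, k)` is
#' `(i * sx, j * sy, k * sz)` um.
#'
#' @param data numeric 3D array, all values finite and `>= 0`.
#' @param spacing numeric length-3 vector `(sx, sy, sz)` of voxel edge
#'   lengths in um; all `> 0`. Typical two-photon stacks are anisotropic,
#'   e.g. `c(0.333, 0.333, 0.72)`.
#' @param channel_name free-text channel label.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(data, spacing, channel_name = "") {
  data <- check_volume_array(data)
  spacing <- check_spacing(spacing)
  if (any(data < 0)) stop("intensity data must be non-negative")
  structure(list(data = data, spacing = spacing, channel_name = channel_name),
            class = c("intensity_volume", "morph_volume"))
}

#' Binary segmentation label volume
#'
#' A strictly binary (0/1) 3D array marking one segmented object, with the
#' same spacing semantics as [intensity_volume()]. An empty (all-zero) mask
#' is allowed but flagged with a warning since it is not a valid
#' segmentation of an object.
#'
#' @param data numeric/logical/integer 3D array with values in `{0, 1}`.
#' @param spacing voxel spacing `(sx, sy, sz)` in um.
#' @param object_id free-text object identifier.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, object_id = "") {
  data <- check_volume_array(data)
  spacing <- check_spacing(spacing)
  if (!all(data %in% c(0, 1)))
    stop("label data must be strictly binary (0/1)")
  if (!any(data == 1))
    warning("label volume '", object_id, "' has no foreground voxel")
  structure(list(data = data, spacing = spacing, object_id = object_id),
            class = c("label_volume", "morph_volume"))
}

#' Signal-ratio volume
#'
#' Holds per-voxel nuclear signal ratios (protein / counterstain), zero
#' where no value was assigned, plus a validity mask recording where a
#' value actually exists (a ratio of 0 is distinguishable from "no
#' nucleus here").
#'
#' @param data numeric 3D array, `>= 0`.
#' @param spacing voxel spacing in um.
#' @param valid_mask logical array of the same shape; defaults to
#'   `data > 0`.
#' @param normalised logical flag: has the volume been divided by its
#'   background scalar (see [merge_registered()])?
#' @param channel_name free-text channel label.
#' @return An object of class `signal_volume`.
#' @export
signal_volume <- function(data, spacing, valid_mask = NULL,
                          normalised = FALSE, channel_name = "") {
  data <- check_volume_array(data)
  spacing <- check_spacing(spacing)
  if (any(data < 0)) stop("signal data must be non-negative")
  if (is.null(valid_mask)) valid_mask <- data > 0
  if (!identical(dim(valid_mask), dim(data)))
    stop("valid_mask shape must match data")
  storage.mode(valid_mask) <- "logical"
  structure(list(data = data, spacing = spacing, valid_mask = valid_mask,
                 normalised = isTRUE(normalised), channel_name = channel_name),
            class = c("signal_volume", "morph_volume"))
}

#' @export
print.morph_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s um",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing, 6), collapse = " x ")))
  id <- x$object_id %||% x$channel_name %||% ""
  if (nzchar(id)) cat(", '", id, "'", sep = "")
  cat("\n")
  invisible(x)
}

check_volume_array <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 1)) stop("all three extents must be >= 1")
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("volume data must be finite")
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (um)")
  spacing
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reinterpret a volume as a binary label
#'
#' Maps any strictly two-valued `{0, v}` volume to `{0, 1}`. Used when a
#' mask TIFF stores foreground as 255.
#'
#' @param vol an [intensity_volume()] or plain array-bearing volume.
#' @param object_id identifier for the resulting label.
#' @return A [label_volume()].
#' @export
as_label_volume <- function(vol, object_id = "") {
  d <- vol$data
  vals <- sort(unique(as.vector(d)))
  if (!all(vals %in% c(0, vals[length(vals)])) || length(vals) > 2)
    stop("volume is not binary; cannot reinterpret as label")
  if (length(vals) == 2 && vals[1] != 0)
    stop("binary volume must use 0 as background")
  if (length(vals) == 2) d[] <- as.numeric(d == vals[2])
  label_volume(d, vol$spacing, object_id = object_id)
}
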