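#' 2D elastic transform as a cubic B-spline coefficient lattice
#'
#' The transform is `T(p) = p + d(p)` where `d` is the tensor-product
#' cubic B-spline interpolation of the coefficient lattice over the pixel
#' domain `[0, nu-1] x [0, nv-1]`. `T` maps TARGET pixel coordinates to
#' SOURCE pixel coordinates (backward/resampling convention): warping an
#' image computes `out(p) = img(T(p))`.
#'
#' A lattice with `g` control points per axis spans `g - 3` knot
#' intervals, so `g >= 4` is required for cubic support.
#'
#' @param coeffs numeric array `(gu, gv, 2)` of displacement coefficients
#'   `(du, dv)` in pixel units.
#' @param image_extent integer `(nu, nv)`: the plane extent the transform
#'   acts on.
#' @param pixel_spacing numeric `(su, sv)`: in-plane voxel spacing in um.
#' @return An object of class `bspline_grid2d`.
#' @export
bspline_grid <- function(coeffs, image_extent, pixel_spacing = c(1, 1)) {
  coeffs <- as.array(coeffs)
  d <- dim(coeffs)
  if (length(d) != 3 || d[3] != 2)
    stop("coeffs must be a (gu, gv, 2) array")
  if (d[1] < 4 || d[2] < 4)
    stop("lattice needs >= 4 control points per axis (cubic support)")
  image_extent <- as.integer(image_extent)
  if (length(image_extent) != 2 || any(image_extent < 2))
    stop("image_extent must be two extents >= 2")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2 || any(pixel_spacing <= 0))
    stop("pixel_spacing must be two positive values")
  storage.mode(coeffs) <- "double"
  structure(list(coeffs = coeffs, image_extent = image_extent,
                 pixel_spacing = pixel_spacing),
            class = "bspline_grid2d")
}

#' Identity transform on a given plane extent
#'
#' @param image_extent `(nu, nv)` pixel extent.
#' @param intervals lattice intervals per axis; defaults to the grid
#'   geometry used by [register_pair()] for this extent.
#' @param pixel_spacing in-plane spacing in um.
#' @return A [bspline_grid()] with an all-zero lattice.
#' @export
identity_grid <- function(image_extent, intervals = NULL,
                          pixel_spacing = c(1, 1)) {
  if (is.null(intervals)) intervals <- plane_intervals(image_extent, 8L)
  bspline_grid(array(0, dim = c(intervals[1] + 3, intervals[2] + 3, 2)),
               image_extent, pixel_spacing)
}

# Lattice interval counts for a plane: `final` intervals along the longer
# axis, proportionally fewer (>= 1) along the shorter, fixed by extent
# alone so lattices from any image content are average-compatible.
plane_intervals <- function(extent, final) {
  extent <- as.numeric(extent)
  long <- max(extent); short <- min(extent)
  i_long <- as.integer(final)
  i_short <- max(1L, as.integer(round(final * (short - 1) / (long - 1))))
  if (extent[1] >= extent[2]) c(i_long, i_short) else c(i_short, i_long)
}

grid_geom <- function(t) {
  d <- dim(t$coeffs)
  list(gu = d[1], gv = d[2], iu = d[1] - 3L, iv = d[2] - 3L,
       nu = t$image_extent[1], nv = t$image_extent[2])
}

#' Evaluate the displacement field of a transform
#'
#' Cubic B-spline interpolation of the coefficient lattice; smooth (C2)
#' in the query point. Constant lattices return the constant (partition
#' of unity).
#'
#' @param t a [bspline_grid()].
#' @param p numeric length-2 point or (m x 2) matrix of pixel
#'   coordinates inside the image extent.
#' @return Displacement(s) in pixels: length-2 vector or (m x 2) matrix.
#' @export
displacement_at <- function(t, p) {
  pm <- rbind(p)
  if (ncol(pm) != 2) stop("points must have two columns")
  g <- grid_geom(t)
  if (any(pm[, 1] < 0 | pm[, 1] > g$nu - 1 | pm[, 2] < 0 | pm[, 2] > g$nv - 1))
    stop("point outside image extent")
  out <- cpp_disp_at(t$coeffs, g$gu, g$gv, g$nu, g$nv, g$iu, g$iv, pm)
  if (is.matrix(p)) out else drop(out)
}

#' Average a list of compatible transforms
#'
#' Element-wise arithmetic mean of the coefficient lattices; this is the
#' group-wise averaging step that turns n pair-wise transforms into one
#' mean transform per object. All grids must share lattice shape, image
#' extent and spacing.
#'
#' @param ts nonempty list of [bspline_grid()] objects.
#' @return A [bspline_grid()].
#' @export
mean_transforms <- function(ts) {
  if (!is.list(ts) || length(ts) == 0) stop("need a nonempty list of transforms")
  ref <- ts[[1]]
  for (t in ts) {
    if (!identical(dim(t$coeffs), dim(ref$coeffs)) ||
        !identical(t$image_extent, ref$image_extent))
      stop("transform lattices/extents do not match")
    if (!isTRUE(all.equal(t$pixel_spacing, ref$pixel_spacing)))
      stop("transform spacings do not match")
  }
  acc <- Reduce(`+`, lapply(ts, `[[`, "coeffs"))
  bspline_grid(acc / length(ts), ref$image_extent, ref$pixel_spacing)
}

#' Warp a 2D image through a transform
#'
#' Backward mapping: `out(p) = img(T(p))` with the chosen interpolation;
#' source positions outside the image fill with 0 (background-neutral for
#' label projections).
#'
#' @param img numeric matrix matching `t$image_extent`.
#' @param t a [bspline_grid()].
#' @param interp `"linear"` or `"nearest"`.
#' @return Warped matrix of the same extent.
#' @export
warp_image <- function(img, t, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  img <- as.matrix(img)
  g <- grid_geom(t)
  if (nrow(img) != g$nu || ncol(img) != g$nv)
    stop("image extent does not match transform")
  cpp_warp2d(img, t$coeffs, g$gu, g$gv, g$iu, g$iv,
             if (interp == "nearest") 0L else 1L)
}

#' Numerically invert a transform at a point
#'
#' Finds `p` with `|T(p) - q| <= tol` by the fixed-point iteration
#' `p <- q - d(p)`. Because `T` is the backward (resampling) map, this `p`
#' is where content originally at `q` appears after warping — it is how
#' landmarks are moved WITH the image content.
#'
#' @param t a [bspline_grid()], diffeomorphic on the support of interest.
#' @param q length-2 point or (m x 2) matrix inside the extent.
#' @param tol convergence tolerance in pixels.
#' @param max_iter iteration cap; non-convergence is reported with a
#'   warning and flagged in the `converged` attribute.
#' @return Inverted point(s), with attribute `converged`.
#' @export
invert_point <- function(t, q, tol = 1e-3, max_iter = 50) {
  qm <- rbind(q)
  g <- grid_geom(t)
  if (any(qm[, 1] < 0 | qm[, 1] > g$nu - 1 | qm[, 2] < 0 | qm[, 2] > g$nv - 1))
    stop("point outside image extent")
  res <- cpp_invert_points(t$coeffs, g$gu, g$gv, g$nu, g$nv, g$iu, g$iv,
                           qm, tol, as.integer(max_iter))
  if (!all(res$converged))
    warning(sum(!res$converged), " point(s) did not converge within ",
            max_iter, " iterations (tol ", tol, " px)")
  out <- if (is.matrix(q)) res$points else drop(res$points)
  attr(out, "converged") <- as.logical(res$converged)
  out
}
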