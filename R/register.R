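#' Parameters of the pair-wise elastic registration
#'
#' The pair-wise step minimises a mean-squared intensity difference (in
#' both directions when `consistency_weight > 0`) plus a bending-energy
#' penalty on the coefficient lattice, over a coarse-to-fine schedule.
#' All defaults are package choices exposed for tuning; none is dictated
#' by the registration scheme itself.
#'
#' @param final_grid_intervals control intervals along the longer in-plane
#'   axis of the lattice (default 8). The lattice shape is a function of
#'   this number and the image extent only — never of image content — so
#'   lattices from different pairs are always average-compatible.
#' @param pyramid_levels coarse-to-fine passes (default 3); coarser passes
#'   see more strongly smoothed images on the same fixed lattice.
#' @param similarity_weight weight of the intensity term (default 1).
#' @param consistency_weight weight of the inverse-consistency coupling
#'   between the forward and reverse transforms (default 1); set 0 for a
#'   cheaper unidirectional fit.
#' @param regularization_weight bending-energy weight (default 1). The
#'   penalty is normalised as the thin-plate bending energy of the
#'   continuous displacement field (second differences scaled by the
#'   lattice cell sizes), so 1 is a balanced default against the
#'   intensity term.
#' @param max_optimizer_steps gradient-descent iterations per level
#'   (default 200).
#' @param tol convergence tolerance on the relative energy decrease
#'   (default 1e-4).
#' @return An object of class `elastic_params`.
#' @export
elastic_params <- function(final_grid_intervals = 8, pyramid_levels = 3,
                           similarity_weight = 1, consistency_weight = 1,
                           regularization_weight = 1,
                           max_optimizer_steps = 200, tol = 1e-4) {
  p <- list(final_grid_intervals = as.integer(final_grid_intervals),
            pyramid_levels = as.integer(pyramid_levels),
            similarity_weight = as.numeric(similarity_weight),
            consistency_weight = as.numeric(consistency_weight),
            regularization_weight = as.numeric(regularization_weight),
            max_optimizer_steps = as.integer(max_optimizer_steps),
            tol = as.numeric(tol))
  if (p$final_grid_intervals < 1) stop("final_grid_intervals must be >= 1")
  if (p$pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  if (any(c(p$similarity_weight, p$consistency_weight,
            p$regularization_weight) < 0))
    stop("weights must be >= 0")
  structure(p, class = "elastic_params")
}

#' Consistent elastic pair-wise registration of two 2D images
#'
#' Estimates the B-spline transform at the finest lattice density such
#' that resampling `source` through it approximates `target`. The
#' optimisation is gradient descent from the zero (identity) lattice with
#' a backtracking line search — fully deterministic, no randomness.
#'
#' @param source,target numeric matrices of equal extent, finite,
#'   normalised to `[0, 1]`.
#' @param params an [elastic_params()] object.
#' @param pixel_spacing in-plane spacing in um carried on the result.
#' @param both also return the reverse transform (target resampled toward
#'   source), available whenever `consistency_weight > 0`; the forward and
#'   reverse transforms of one run are each other's approximate inverses,
#'   so group-wise registration computes each unordered pair once.
#' @return A [bspline_grid()]; when `both`, a list with elements
#'   `forward` and `reverse`.
#' @export
register_pair <- function(source, target, params = elastic_params(),
                          pixel_spacing = c(1, 1), both = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!identical(dim(source), dim(target)))
    stop("source and target extents must match")
  if (any(!is.finite(source)) || any(!is.finite(target)))
    stop("images must be finite")
  rng <- range(source, target)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("images must be normalized to [0, 1]")
  if (both && params$consistency_weight <= 0)
    stop("reverse transform requires consistency_weight > 0")
  ext <- dim(source)
  iv <- plane_intervals(ext, params$final_grid_intervals)
  res <- cpp_register_pair(source, target, iv[1], iv[2],
                           params$pyramid_levels, params$max_optimizer_steps,
                           params$tol, params$similarity_weight,
                           params$consistency_weight,
                           params$regularization_weight)
  fwd <- bspline_grid(res$forward, ext, pixel_spacing)
  if (!both) return(fwd)
  list(forward = fwd,
       reverse = bspline_grid(res$reverse, ext, pixel_spacing))
}
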