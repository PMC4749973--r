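# Seeded generators for every fixture the test-suite and validation
# experiments need: deformed vesicle-like blobs with embedded landmarks,
# two-channel nuclei scenes, and zoned multi-channel signal volumes.
# Every generator is deterministic under its seed and returns its own
# ground truth; the ambient RNG state is left untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' A two-lobed ellipsoidal blob (a large and a smaller lobe fused along
#' one axis, emulating a vesicle-like embryonic tissue) on a regular
#' grid. The default is a 64^3 grid at 2 um isotropic spacing — desk
#' scale, yet large enough for a meaningful 8-interval registration
#' lattice.
#'
#' @param extent grid extents `(nx, ny, nz)`.
#' @param spacing voxel spacing in um.
#' @param centre blob centre in um (default: grid centre).
#' @param radii semi-axes of the main lobe in um.
#' @param lobe_offset centre offset of the second lobe along x, um.
#' @param lobe_scale size of the second lobe relative to the first.
#' @param smoothness Gaussian sigma (um) applied before re-thresholding,
#'   controlling surface smoothness.
#' @param landmark_count number of landmarks (default 7: six axis-extreme
#'   surface points plus the centroid; additional ones are seeded
#'   interior points).
#' @param seed RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent = c(64, 64, 64), spacing = c(2, 2, 2),
                         centre = NULL, radii = c(34, 26, 22),
                         lobe_offset = 22, lobe_scale = 0.65,
                         smoothness = 4, landmark_count = 7, seed = 1) {
  extent <- as.integer(extent)
  spacing <- check_spacing(spacing)
  if (is.null(centre)) centre <- (extent - 1) / 2 * spacing
  if (landmark_count < 1) stop("landmark_count must be >= 1")
  structure(list(extent = extent, spacing = spacing, centre = centre,
                 radii = as.numeric(radii), lobe_offset = lobe_offset,
                 lobe_scale = lobe_scale, smoothness = smoothness,
                 landmark_count = as.integer(landmark_count),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom label volume with embedded landmarks
#'
#' @param spec a [phantom_spec()].
#' @return List with `label` (a [label_volume()]) and `landmarks` (a
#'   [landmark_set()]). Landmarks are placed deterministically at the six
#'   axis-extreme surface voxels and the centroid, then (if requested) at
#'   seeded interior points. Errors if the blob comes within 4 voxels of
#'   the grid boundary.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  d <- spec$extent
  sp <- spec$spacing
  co <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  X <- co[[1]][slice.index(array(0, d), 1)]
  Y <- co[[2]][slice.index(array(0, d), 2)]
  Z <- co[[3]][slice.index(array(0, d), 3)]
  c1 <- spec$centre
  c2 <- spec$centre + c(spec$lobe_offset, 0, 0)
  r1 <- spec$radii
  r2 <- spec$radii * spec$lobe_scale
  inside <- (((X - c1[1]) / r1[1])^2 + ((Y - c1[2]) / r1[2])^2 +
               ((Z - c1[3]) / r1[3])^2 <= 1) |
            (((X - c2[1]) / r2[1])^2 + ((Y - c2[2]) / r2[2])^2 +
               ((Z - c2[3]) / r2[3])^2 <= 1)
  mask <- array(as.numeric(inside), dim = d)
  if (spec$smoothness > 0) {
    sm <- cpp_smooth3d(mask, spec$smoothness / sp)
    mask <- array(as.numeric(sm >= 0.5), dim = d)
  }
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("phantom blob is empty")
  if (any(fg <= 4) || any(sweep(fg, 2, d - 4L) > 0))
    stop("phantom blob must keep a 4-voxel margin from the grid boundary")

  extreme <- function(axis, side) {
    v <- fg[, axis]
    best <- if (side > 0) max(v) else min(v)
    cand <- fg[v == best, , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
    cand[1, ]
  }
  pts <- rbind(extreme(1, -1), extreme(1, +1),
               extreme(2, -1), extreme(2, +1),
               extreme(3, -1), extreme(3, +1),
               round(colMeans(fg)))
  if (spec$landmark_count > 7) {
    extra_n <- spec$landmark_count - 7
    idx <- with_seed(spec$seed, sample(nrow(fg), extra_n))
    pts <- rbind(pts, fg[idx, , drop = FALSE])
  }
  pts <- pts[seq_len(min(spec$landmark_count, nrow(pts))), , drop = FALSE]
  # voxel indices (1-based) -> um
  pts_um <- sweep(pts - 1, 2, sp, `*`)
  nm <- c("x_min", "x_max", "y_min", "y_max", "z_min", "z_max", "centroid",
          if (spec$landmark_count > 7) paste0("interior", seq_len(spec$landmark_count - 7)))
  list(label = label_volume(mask, sp, object_id = "phantom"),
       landmarks = landmark_set("phantom", nm[seq_len(nrow(pts_um))], pts_um))
}

#' Deformation specification
#'
#' A seeded smooth random displacement field drawn on a coarse 3D
#' B-spline lattice; the amplitude bound (less than half the lattice
#' spacing) keeps the field diffeomorphic.
#'
#' @param lattice intervals per axis of the coarse lattice (default 2:
#'   low-frequency, tissue-scale bending rather than local ripple).
#' @param amplitude realized maximum per-axis displacement in um: the
#'   drawn field is rescaled so its largest per-axis displacement over
#'   the volume equals this value, which must stay below half the
#'   lattice spacing.
#' @param seed RNG seed.
#' @return An object of class `deform_spec`.
#' @export
deform_spec <- function(lattice = c(2, 2, 2), amplitude = 20, seed = 1) {
  lattice <- as.integer(lattice)
  if (length(lattice) == 1) lattice <- rep(lattice, 3)
  if (any(lattice < 1)) stop("lattice intervals must be >= 1")
  structure(list(lattice = lattice, amplitude = as.numeric(amplitude),
                 seed = as.integer(seed)),
            class = "deform_spec")
}

#' Deform a phantom and carry its landmarks along
#'
#' The label is warped by backward mapping through the random field
#' (linear interpolation, re-thresholded at 0.5); landmarks are moved by
#' numerically inverting the backward map, so landmark k in the deformed
#' object marks the same material point as in the original.
#'
#' @param label a [label_volume()].
#' @param pts the matching [landmark_set()].
#' @param spec a [deform_spec()].
#' @return List with `label`, `landmarks` and `coeffs` (the displacement
#'   lattice, voxel units).
#' @export
deform_phantom <- function(label, pts, spec = deform_spec()) {
  d <- dim(label$data)
  sp <- label$spacing
  cell_um <- (d - 1) * sp / spec$lattice
  if (spec$amplitude >= min(cell_um) / 2)
    stop("amplitude ", spec$amplitude, " um violates the diffeomorphic bound ",
         "(half lattice spacing = ", signif(min(cell_um) / 2, 4), " um)")
  g <- spec$lattice + 3L
  co <- with_seed(spec$seed,
                  array(runif(prod(g) * 3, -1, 1), dim = c(g, 3L)))
  # rescale the drawn field so its realized per-axis maximum (probed on a
  # stride-2 voxel grid) equals the requested amplitude
  probe <- as.matrix(expand.grid(x = seq(0, d[1] - 1, by = 2),
                                 y = seq(0, d[2] - 1, by = 2),
                                 z = seq(0, d[3] - 1, by = 2)))
  dp <- cpp_disp3d_at(as.numeric(co), g, d, spec$lattice, probe)
  for (ax in 1:3) {
    mx <- max(abs(dp[, ax]))
    if (mx > 0)
      co[, , , ax] <- co[, , , ax] / mx * spec$amplitude / sp[ax]
  }
  warped <- cpp_warp3d_bspline(label$data, as.numeric(co), g, spec$lattice, 1L)
  warped <- array(as.numeric(warped >= 0.5), dim = d)

  q_vox <- sweep(pts$points, 2, sp, `/`)
  inv <- cpp_invert_points3d(as.numeric(co), g, d, spec$lattice, q_vox,
                             1e-4, 100L)
  if (!all(inv$converged))
    warning(sum(!inv$converged), " landmark inversion(s) did not converge")
  new_pts <- sweep(inv$points, 2, sp, `*`)
  list(label = label_volume(warped, sp, object_id = label$object_id),
       landmarks = landmark_set(pts$object_id, pts$names, new_pts),
       coeffs = co)
}

#' Generate a deformed phantom group (the standard benchmark triplet)
#'
#' One base phantom deformed n times with independent seeded fields —
#' the stand-in for a manually deformed single-tissue benchmark.
#'
#' @param n number of objects (default 3).
#' @param spec a [phantom_spec()].
#' @param amplitude deformation amplitude in um.
#' @param lattice coarse lattice intervals.
#' @param seed base seed; object i uses `seed * 1000 + i`.
#' @return List with `labels`, `landmarks` (lists of n), and `base` (the
#'   undeformed phantom).
#' @export
make_phantom_group <- function(n = 3, spec = phantom_spec(),
                               amplitude = 20, lattice = c(2, 2, 2),
                               seed = 1) {
  base <- make_phantom(spec)
  labels <- vector("list", n)
  lms <- vector("list", n)
  for (i in seq_len(n)) {
    df <- deform_phantom(base$label, base$landmarks,
                         deform_spec(lattice, amplitude,
                                     seed = seed * 1000 + i))
    df$label$object_id <- paste0("object", i)
    df$landmarks$object_id <- paste0("object", i)
    labels[[i]] <- df$label
    lms[[i]] <- df$landmarks
  }
  list(labels = labels, landmarks = lms, base = base)
}

#' Generate a two-channel nuclei scene with known per-nucleus ratios
#'
#' Places n non-overlapping spheres (radius 2-3 um) at seeded positions
#' inside the label. The counterstain is constant per nucleus with
#' multiplicative Gaussian noise; the protein channel is the counterstain
#' scaled by the ratio field evaluated at the nucleus centroid. The exact
#' per-nucleus ratio is returned as ground truth.
#'
#' @param label a [label_volume()] the nuclei must fit inside.
#' @param n_nuclei requested nucleus count.
#' @param ratio_field scalar, or `function(x, y, z)` of um coordinates
#'   returning the true ratio at a centroid.
#' @param noise_sd relative noise level (0.05 = 5% intensity noise).
#' @param seed RNG seed.
#' @return List with `protein`, `counterstain` (both
#'   [intensity_volume()]) and `truth` (data frame: `nucleus_id`,
#'   `cx, cy, cz`, `radius_um`, `ratio`). Warns if fewer than `n_nuclei`
#'   spheres could be placed.
#' @export
make_nuclei_scene <- function(label, n_nuclei = 20, ratio_field = 1,
                              noise_sd = 0, seed = 1) {
  if (!any(label$data > 0)) stop("label is empty")
  d <- dim(label$data)
  sp <- label$spacing
  rf <- if (is.function(ratio_field)) ratio_field
        else function(x, y, z) rep(ratio_field, length(x))
  with_seed(seed, {
    fg <- which(label$data > 0, arr.ind = TRUE)
    centres <- matrix(0, 0, 3)
    radii <- numeric(0)
    tries <- 0
    while (nrow(centres) < n_nuclei && tries < 5000) {
      tries <- tries + 1
      cand_i <- fg[sample(nrow(fg), 1), ]
      ctr <- (cand_i - 1) * sp
      r <- runif(1, 2, 3)
      # sphere fully inside the label?
      lo <- pmax(1L, as.integer(floor((ctr - r) / sp)) + 1L)
      hi <- pmin(d, as.integer(ceiling((ctr + r) / sp)) + 1L)
      sub <- label$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      gx <- (seq(lo[1], hi[1]) - 1) * sp[1]
      gy <- (seq(lo[2], hi[2]) - 1) * sp[2]
      gz <- (seq(lo[3], hi[3]) - 1) * sp[3]
      dist2 <- outer(outer((gx - ctr[1])^2, (gy - ctr[2])^2, `+`),
                     (gz - ctr[3])^2, `+`)
      if (any(sub[dist2 <= r^2] == 0)) next
      if (nrow(centres) > 0 &&
          any(sqrt(rowSums(sweep(centres, 2, ctr)^2)) <
                radii + r + 2 * max(sp))) next
      centres <- rbind(centres, ctr)
      radii <- c(radii, r)
    }
    if (nrow(centres) < n_nuclei)
      warning("placed only ", nrow(centres), " of ", n_nuclei, " nuclei")
    n <- nrow(centres)
    base <- runif(n, 0.6, 1.0)
    ratio <- rf(centres[, 1], centres[, 2], centres[, 3])
    cs <- array(0, dim = d)
    pr <- array(0, dim = d)
    for (k in seq_len(n)) {
      ctr <- centres[k, ]; r <- radii[k]
      lo <- pmax(1L, as.integer(floor((ctr - r) / sp)) + 1L)
      hi <- pmin(d, as.integer(ceiling((ctr + r) / sp)) + 1L)
      gx <- (seq(lo[1], hi[1]) - 1) * sp[1]
      gy <- (seq(lo[2], hi[2]) - 1) * sp[2]
      gz <- (seq(lo[3], hi[3]) - 1) * sp[3]
      dist2 <- outer(outer((gx - ctr[1])^2, (gy - ctr[2])^2, `+`),
                     (gz - ctr[3])^2, `+`)
      vox <- which(dist2 <= r^2, arr.ind = TRUE)
      vox <- sweep(vox, 2, lo - 1L, `+`)
      nv <- nrow(vox)
      cs[vox] <- base[k] * (1 + rnorm(nv, 0, noise_sd))
      pr[vox] <- base[k] * ratio[k] * (1 + rnorm(nv, 0, noise_sd))
    }
    cs <- pmax(cs, 0); pr <- pmax(pr, 0)
    list(protein = intensity_volume(pr, sp, channel_name = "protein"),
         counterstain = intensity_volume(cs, sp, channel_name = "counterstain"),
         truth = data.frame(nucleus_id = seq_len(n), cx = centres[, 1],
                            cy = centres[, 2], cz = centres[, 3],
                            radius_um = radii, ratio = ratio))
  })
}

#' Generate zoned multi-channel signal volumes with known zone map
#'
#' Partitions the label into k contiguous slabs along x (equal-width over
#' the foreground bounding box) and fills each channel with its planted
#' zone mean plus Gaussian noise. The full-resolution truth map is
#' returned alongside.
#'
#' @param consensus a [label_volume()].
#' @param k_zones number of slabs.
#' @param channel_means numeric k x C matrix of planted means.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return List with `channels` (named list of [signal_volume()]) and
#'   `truth` (integer array of zone ids, 0 outside the label).
#' @export
make_zoned_signal <- function(consensus, k_zones, channel_means,
                              noise_sd = 0, seed = 1) {
  channel_means <- as.matrix(channel_means)
  if (nrow(channel_means) != k_zones)
    stop("channel_means must have one row per zone")
  if (!any(consensus$data > 0)) stop("consensus is empty")
  d <- dim(consensus$data)
  fg <- which(consensus$data > 0, arr.ind = TRUE)
  xr <- range(fg[, 1])
  edges <- seq(xr[1], xr[2] + 1, length.out = k_zones + 1)
  zone_of_x <- pmin(k_zones, findInterval(seq_len(d[1]), edges))
  zone_of_x[seq_len(d[1]) < xr[1]] <- 0L
  truth <- array(0L, dim = d)
  idx <- which(consensus$data > 0)
  ix <- (idx - 1) %% d[1] + 1
  truth[idx] <- zone_of_x[ix]
  if (any(tabulate(truth[idx], k_zones) == 0))
    stop("cannot realize ", k_zones, " slabs: a slab has no foreground voxel")
  ch_names <- colnames(channel_means)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(ncol(channel_means)))
  channels <- with_seed(seed, {
    lapply(seq_len(ncol(channel_means)), function(cc) {
      v <- array(0, dim = d)
      v[idx] <- pmax(0, channel_means[truth[idx], cc] +
                       rnorm(length(idx), 0, noise_sd))
      signal_volume(v, consensus$spacing,
                    valid_mask = consensus$data > 0,
                    channel_name = ch_names[cc])
    })
  })
  names(channels) <- ch_names
  list(channels = channels, truth = truth)
}
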