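#' Configuration of the group-wise 3D registration
#'
#' @param plane_order permutation of `c("YZ", "ZX", "XY")`; each iteration
#'   visits the three orthogonal planes in this order.
#' @param iterations number of full plane sweeps (default 6; alignment
#'   improves with iterations but the gain diminishes, so 6 is where the
#'   benchmark convergence curves flatten).
#' @param include_self include each object's own identity transform in its
#'   coefficient mean (default `TRUE`), making the mean run over n
#'   lattices and damping per-iteration overshoot.
#' @param elastic an [elastic_params()] for the pair-wise 2D steps.
#' @param label_interp `"linear"` (warped labels re-binarised at 0.5,
#'   giving smoother consensus boundaries) or `"nearest"`.
#' @param min_update_px resolution floor in pixels (default 0.4): a mean
#'   transform whose largest coefficient magnitude falls below this is
#'   recorded as exact identity. Updates this far below voxel resolution
#'   are invisible to the re-thresholded binary volume; recording them
#'   would only accumulate spurious sub-voxel motion in replayed landmark
#'   tracks once the group has converged. Set 0 to disable.
#' @return An object of class `groupwise_config`.
#' @export
groupwise_config <- function(plane_order = c("YZ", "ZX", "XY"),
                             iterations = 6, include_self = TRUE,
                             elastic = elastic_params(),
                             label_interp = c("linear", "nearest"),
                             min_update_px = 0.4) {
  label_interp <- match.arg(label_interp)
  if (!setequal(plane_order, c("YZ", "ZX", "XY")) || length(plane_order) != 3)
    stop("plane_order must be a permutation of YZ, ZX, XY")
  iterations <- as.integer(iterations)
  if (iterations < 1) stop("iterations must be >= 1")
  if (min_update_px < 0) stop("min_update_px must be >= 0")
  structure(list(plane_order = plane_order, iterations = iterations,
                 include_self = isTRUE(include_self), elastic = elastic,
                 label_interp = label_interp,
                 min_update_px = as.numeric(min_update_px)),
            class = "groupwise_config")
}

#' Average intensity projection of a volume along a plane's third axis
#'
#' The mean of voxel values along the projection axis of `plane` (X for
#' YZ, Y for ZX, Z for XY), rescaled to `[0, 1]` by its maximum unless
#' all-zero. Projections of the current (partially warped) volumes are
#' what the 2D group-wise steps register.
#'
#' @param vol a volume object or bare 3D array.
#' @param plane `"YZ"`, `"ZX"` or `"XY"`.
#' @return A numeric matrix with the two in-plane extents of the volume.
#' @export
average_projection <- function(vol, plane) {
  data <- if (is.list(vol)) vol$data else vol
  ax <- plane_axes(plane)
  m <- apply(data, ax$inplane, mean)
  mx <- max(m)
  if (mx > 0) m <- m / mx
  m
}

#' Group-wise 2D registration within one plane
#'
#' Registers every object's projection pair-wise to every other, then
#' averages per object: object `i` collects, for every peer `j`, the
#' transform whose application to `i`'s stack pulls `i` toward `j`
#' (estimated with `source = projection_i`, `target = projection_j` under
#' the backward-resampling convention), plus its own identity transform
#' when `include_self`, and returns the coefficient mean — one transform
#' per object. When the pair-wise step is run with inverse consistency,
#' each unordered pair is registered once and both directions reused.
#'
#' @param projections list of n equal-extent matrices in `[0, 1]`.
#' @param cfg a [groupwise_config()].
#' @param pixel_spacing in-plane spacing (um) carried on the transforms.
#' @return List of n [bspline_grid()] mean transforms.
#' @export
register_plane_groupwise <- function(projections, cfg = groupwise_config(),
                                     pixel_spacing = c(1, 1)) {
  n <- length(projections)
  if (n < 1) stop("need at least one projection")
  ext <- dim(projections[[1]])
  for (p in projections)
    if (!identical(dim(p), ext)) stop("projection extents must match")
  par <- cfg$elastic
  iv <- plane_intervals(ext, par$final_grid_intervals)
  id <- identity_grid(ext, iv, pixel_spacing)
  if (n == 1) return(list(id))

  peer <- vector("list", n)
  for (i in seq_len(n)) peer[[i]] <- list()
  if (par$consistency_weight > 0) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      res <- register_pair(projections[[i]], projections[[j]], par,
                           pixel_spacing, both = TRUE)
      peer[[i]][[length(peer[[i]]) + 1]] <- res$forward
      peer[[j]][[length(peer[[j]]) + 1]] <- res$reverse
    }
  } else {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      peer[[i]][[length(peer[[i]]) + 1]] <-
        register_pair(projections[[i]], projections[[j]], par, pixel_spacing)
    }
  }
  lapply(seq_len(n), function(i) {
    ts <- peer[[i]]
    if (cfg$include_self) ts <- c(ts, list(id))
    m <- mean_transforms(ts)
    # resolution floor: a sub-voxel update is invisible to the
    # re-thresholded binary volume and only adds landmark jitter
    if (max(abs(m$coeffs)) < cfg$min_update_px) m <- id
    m
  })
}

# Warp every slice of `data` along the projection axis of `plane` with one
# 2D transform; binarize = re-threshold at 0.5 (label volumes).
warp_volume_plane <- function(data, plane, transform, interp, binarize) {
  ax <- plane_axes(plane)
  perm <- c(ax$inplane, ax$proj)
  arr <- aperm(data, perm)
  for (s in seq_len(dim(arr)[3]))
    arr[, , s] <- warp_image(arr[, , s], transform, interp)
  if (binarize) arr[] <- as.numeric(arr >= 0.5)
  aperm(arr, order(perm))
}

#' Group-wise 3D elastic registration of segmented objects
#'
#' The core algorithm: for each iteration and each plane in
#' `cfg$plane_order`, project every current object
#' ([average_projection()]), compute per-object mean 2D transforms
#' ([register_plane_groupwise()]), apply each object's mean transform to
#' every slice of that object's stack along the plane's projection axis,
#' and append the transform to that object's OTS. Projections are
#' recomputed from the current (partially warped) volumes at every plane
#' pass. After `k` iterations each OTS holds exactly `3k` records.
#'
#' @param labels list of n [label_volume()] objects with equal extents and
#'   spacing.
#' @param cfg a [groupwise_config()].
#' @param landmarks optional list of n [landmark_set()] objects, moved
#'   along with their objects (content-forward, via numerical transform
#'   inversion) and used for the per-iteration landmark-distance metric.
#' @return A list with elements `ots` (list of [ots()] objects), `labels`
#'   (registered label volumes), `landmarks` (moved sets or `NULL`) and
#'   `report` (data frame: `iteration`, `overlap_pct`, `landmark_dist_um`,
#'   `pairs_per_plane`).
#' @export
register_groupwise <- function(labels, cfg = groupwise_config(),
                               landmarks = NULL) {
  n <- length(labels)
  if (n < 1) stop("need at least one label volume")
  shape <- dim(labels[[1]]$data)
  spacing <- labels[[1]]$spacing
  for (l in labels) {
    if (!identical(dim(l$data), shape)) stop("label extents must match")
    if (!isTRUE(all.equal(l$spacing, spacing))) stop("label spacings must match")
  }
  if (!is.null(landmarks) && length(landmarks) != n)
    stop("need one landmark set per object")

  cur <- lapply(labels, function(l) l$data)
  cur_lm <- landmarks
  seqs <- lapply(labels, function(l)
    ots(l$object_id, shape, spacing, list()))
  pair_count <- as.integer(
    if (cfg$elastic$consistency_weight > 0) n * (n - 1) / 2 else n * (n - 1))

  report <- data.frame(iteration = integer(), overlap_pct = numeric(),
                       landmark_dist_um = numeric(),
                       pairs_per_plane = integer())
  for (it in seq_len(cfg$iterations)) {
    for (plane in cfg$plane_order) {
      ax <- plane_axes(plane)
      ps <- spacing[ax$inplane]
      projections <- lapply(cur, average_projection, plane = plane)
      transforms <- register_plane_groupwise(projections, cfg, ps)
      for (i in seq_len(n)) {
        cur[[i]] <- warp_volume_plane(cur[[i]], plane, transforms[[i]],
                                      interp = cfg$label_interp,
                                      binarize = cfg$label_interp == "linear")
        seqs[[i]]$records[[length(seqs[[i]]$records) + 1]] <-
          ots_record(it, plane, transforms[[i]])
        if (!is.null(cur_lm))
          cur_lm[[i]] <- move_points_record(cur_lm[[i]], plane,
                                            transforms[[i]], spacing)
      }
    }
    lab_objs <- lapply(seq_len(n), function(i)
      label_volume(cur[[i]], spacing, labels[[i]]$object_id))
    ov <- volumetric_overlap(lab_objs)
    ld <- if (!is.null(cur_lm)) mean_landmark_distance(cur_lm)$mean_um else NA_real_
    report <- rbind(report, data.frame(iteration = it,
                                       overlap_pct = ov$mean_pct,
                                       landmark_dist_um = ld,
                                       pairs_per_plane = pair_count))
  }
  list(ots = seqs,
       labels = lapply(seq_len(n), function(i)
         label_volume(cur[[i]], spacing, labels[[i]]$object_id)),
       landmarks = cur_lm,
       report = report)
}

# Move a landmark set through one plane record: in-plane um coordinates
# are converted to pixels, moved content-forward by transform inversion,
# and converted back; the third coordinate is untouched.
move_points_record <- function(lm, plane, transform, spacing) {
  ax <- plane_axes(plane)
  ps <- spacing[ax$inplane]
  px <- sweep(lm$points[, ax$inplane, drop = FALSE], 2, ps, `/`)
  ext <- transform$image_extent
  px[, 1] <- pmin(pmax(px[, 1], 0), ext[1] - 1)
  px[, 2] <- pmin(pmax(px[, 2], 0), ext[2] - 1)
  moved <- invert_point(transform, px)
  pts <- lm$points
  pts[, ax$inplane] <- sweep(unclass(moved), 2, ps, `*`)
  landmark_set(lm$object_id, lm$names, pts)
}

#' Replay an OTS onto a volume
#'
#' Applies the recorded transforms in order: for each record, every slice
#' along the record plane's projection axis is warped with the stored 2D
#' transform. Replaying an object's own OTS onto its original label
#' reproduces, voxel for voxel, the registered label emitted by
#' [register_groupwise()] under the same interpolation settings. An empty
#' OTS is the identity.
#'
#' @param vol an [intensity_volume()], [label_volume()] or
#'   [signal_volume()] whose shape equals `o$volume_shape`.
#' @param o an [ots()].
#' @param interp `"linear"` or `"nearest"`; label inputs warped linearly
#'   are re-binarised at 0.5 after each record.
#' @return The transformed volume, same class as `vol`.
#' @export
apply_ots_volume <- function(vol, o, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  if (!identical(dim(vol$data), as.integer(o$volume_shape)) &&
      !identical(dim(vol$data), o$volume_shape))
    stop("volume shape does not match OTS volume_shape")
  is_label <- inherits(vol, "label_volume")
  data <- vol$data
  mask <- if (inherits(vol, "signal_volume")) vol$valid_mask + 0 else NULL
  for (r in o$records) {
    data <- warp_volume_plane(data, r$plane, r$transform, interp,
                              binarize = is_label && interp == "linear")
    if (!is.null(mask))
      mask <- warp_volume_plane(mask, r$plane, r$transform, interp,
                                binarize = interp == "linear")
  }
  if (is_label) {
    if (interp == "linear") data[] <- as.numeric(data >= 0.5)
    label_volume(data, vol$spacing, vol$object_id)
  } else if (inherits(vol, "signal_volume")) {
    signal_volume(pmax(data, 0), vol$spacing, valid_mask = mask >= 0.5,
                  normalised = vol$normalised, channel_name = vol$channel_name)
  } else {
    intensity_volume(pmax(data, 0), vol$spacing, vol$channel_name)
  }
}

#' Replay an OTS onto a landmark set
#'
#' Landmarks move WITH the image content: each record's transform is
#' numerically inverted at the landmark's in-plane position (the backward
#' resampling map must be inverted to push content forward), with the
#' third coordinate unchanged within a record.
#'
#' @param pts a [landmark_set()] with points inside the volume bounds.
#' @param o an [ots()].
#' @return The moved [landmark_set()].
#' @export
apply_ots_points <- function(pts, o) {
  for (r in o$records)
    pts <- move_points_record(pts, r$plane, r$transform, o$spacing)
  pts
}
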