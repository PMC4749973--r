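#' Segment nuclei from a counterstain volume
#'
#' A standard chain: Gaussian smoothing, global automatic (Otsu)
#' threshold, 3D connected components (6-connectivity), minimum-size
#' filter. Touching nuclei are not split (no watershed), which is the
#' documented limitation of a pure threshold-components approach.
#'
#' @param counterstain an [intensity_volume()] (nuclear dye channel).
#' @param smooth_sigma_um Gaussian sigma in um (default 1), converted
#'   per axis to voxels.
#' @param min_volume_um3 minimum component volume in um^3 (default 50);
#'   smaller components are dropped.
#' @return Integer array of the counterstain's shape with components
#'   labelled `1..K` (0 = background), with attribute `n` = K. Errors if
#'   no component survives.
#' @export
segment_nuclei <- function(counterstain, smooth_sigma_um = 1,
                           min_volume_um3 = 50) {
  data <- counterstain$data
  spacing <- counterstain$spacing
  if (max(data) <= 0) stop("counterstain volume is blank; no nuclei found")
  sig <- smooth_sigma_um / spacing
  sm <- if (smooth_sigma_um > 0) cpp_smooth3d(data, sig) else data
  thr <- otsu_threshold(as.vector(sm))
  mask <- (sm > thr) + 0
  dim(mask) <- dim(data)
  if (!any(mask == 1)) stop("threshold produced an empty mask; no nuclei found")
  lab <- cpp_label3d(mask)
  min_vox <- max(1, ceiling(min_volume_um3 / prod(spacing)))
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_vox)
  if (length(keep) == 0) stop("no component passes the size filter")
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim = dim(data))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  attr(out, "n") <- length(keep)
  out
}

# Otsu's threshold on a 256-bin histogram of the value range.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + as.integer((v - rng[1]) / diff(rng) * nb)), nb)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  between <- (mu_t * om - mu)^2 / (om * (1 - om))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  rng[1] + k / nb * diff(rng)
}

#' Quantify nuclear signal relative to the counterstain
#'
#' Per nucleus, `ratio = mean(protein) / mean(counterstain)` over the
#' nucleus's voxels — a gain-invariant relative measure of nuclear
#' protein level. The companion volume assigns each nuclear voxel its
#' nucleus's ratio (0 elsewhere).
#'
#' @param protein,counterstain [intensity_volume()] objects of equal
#'   shape.
#' @param nuclei labelled nucleus map from [segment_nuclei()].
#' @return A list with `records` (data frame: `nucleus_id`, centroid
#'   `cx, cy, cz` in um, `voxel_count`, `mean_protein`,
#'   `mean_counterstain`, `ratio`) and `signal` (a [signal_volume()]).
#'   Nuclei with zero counterstain mean are excluded with a warning.
#' @export
extract_nuclear_signal <- function(protein, counterstain, nuclei) {
  if (!identical(dim(protein$data), dim(counterstain$data)) ||
      !identical(dim(protein$data), dim(nuclei)))
    stop("protein, counterstain and nucleus map shapes must match")
  lab <- as.vector(nuclei)
  nz <- lab > 0
  ids <- lab[nz]
  k <- max(ids)
  cnt <- tabulate(ids, k)
  mp <- rowsum(protein$data[nz], ids)[, 1] / cnt
  mc <- rowsum(counterstain$data[nz], ids)[, 1] / cnt
  d <- dim(nuclei)
  idx <- which(nz)
  ix <- (idx - 1) %% d[1]
  iy <- ((idx - 1) %/% d[1]) %% d[2]
  iz <- (idx - 1) %/% (d[1] * d[2])
  sp <- protein$spacing
  cx <- rowsum(ix * sp[1], ids)[, 1] / cnt
  cy <- rowsum(iy * sp[2], ids)[, 1] / cnt
  cz <- rowsum(iz * sp[3], ids)[, 1] / cnt

  bad <- mc <= 0
  if (any(bad))
    warning(sum(bad), " nucleus/nuclei with zero counterstain mean excluded")
  ratio <- ifelse(bad, NA_real_, mp / mc)

  records <- data.frame(nucleus_id = seq_len(k), cx = cx, cy = cy, cz = cz,
                        voxel_count = cnt, mean_protein = mp,
                        mean_counterstain = mc, ratio = ratio)
  records <- records[!bad, , drop = FALSE]

  svol <- array(0, dim = d)
  ok_ids <- !bad[ids]
  svol[idx[ok_ids]] <- ratio[ids[ok_ids]]
  valid <- array(FALSE, dim = d)
  valid[idx[ok_ids]] <- TRUE
  list(records = records,
       signal = signal_volume(svol, sp, valid_mask = valid,
                              channel_name = protein$channel_name))
}

#' Local-averaging projection parameters
#'
#' The volume is tiled with target cubes; each receives the mean nuclear
#' signal from its larger concentric sample cube, filling intra-nuclear
#' space before the result is cropped by the morphology label.
#'
#' @param target_edge edge of the target voxel in um (default 12).
#' @param sample_edge edge of the concentric sample voxel in um (default
#'   36); must be `>= target_edge`.
#' @return An object of class `projection_params`.
#' @export
projection_params <- function(target_edge = 12, sample_edge = 36) {
  target_edge <- as.numeric(target_edge)
  sample_edge <- as.numeric(sample_edge)
  if (!(sample_edge >= target_edge && target_edge > 0))
    stop("require sample_edge >= target_edge > 0")
  structure(list(target_edge = target_edge, sample_edge = sample_edge),
            class = "projection_params")
}

#' Project nuclear signal onto segmented morphology by local averaging
#'
#' Tiles the volume with axis-aligned cubes of edge `target_edge` um
#' (converted per axis to voxels; partial edge tiles kept). Each tile's
#' value is the mean of the signal over valid (nuclear) voxels inside the
#' concentric cube of edge `sample_edge` um, clipped at the volume
#' bounds; every voxel of the tile receives that value. Tiles whose
#' sample cube contains no valid voxel get 0 and an unset valid mask.
#' Finally all voxels outside the label are zeroed, restoring surface
#' morphology.
#'
#' @param signal a [signal_volume()] (e.g. from
#'   [extract_nuclear_signal()]).
#' @param label a [label_volume()] of matching shape/spacing.
#' @param params a [projection_params()].
#' @param mode `"voxel"` (default: mean over nuclear voxels, weighting
#'   larger nuclei more) — per-nucleus aggregation can be emulated by
#'   passing a signal volume holding one value per nucleus centroid.
#' @return A [signal_volume()].
#' @export
project_to_label <- function(signal, label, params = projection_params(),
                             mode = "voxel") {
  if (!identical(dim(signal$data), dim(label$data)))
    stop("signal and label shapes must match")
  if (!any(label$data > 0)) stop("label is empty")
  d <- dim(label$data)
  sp <- signal$spacing
  tgt <- pmax(1L, as.integer(round(params$target_edge / sp)))
  half <- params$sample_edge / 2
  out <- array(0, dim = d)
  valid <- array(FALSE, dim = d)
  starts <- lapply(1:3, function(a) seq(1L, d[a], by = tgt[a]))
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ex <- min(sx + tgt[1] - 1L, d[1])
    ey <- min(sy + tgt[2] - 1L, d[2])
    ez <- min(sz + tgt[3] - 1L, d[3])
    # tile centre in um (0-based voxel coordinates)
    ctr <- c((sx + ex - 2) / 2 * sp[1], (sy + ey - 2) / 2 * sp[2],
             (sz + ez - 2) / 2 * sp[3])
    lo <- pmax(1L, as.integer(ceiling((ctr - half) / sp)) + 1L)
    hi <- pmin(d, as.integer(floor((ctr + half) / sp)) + 1L)
    sub_v <- signal$valid_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    if (any(sub_v)) {
      sub_s <- signal$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      out[sx:ex, sy:ey, sz:ez] <- mean(sub_s[sub_v])
      valid[sx:ex, sy:ey, sz:ez] <- TRUE
    }
  }
  out[label$data == 0] <- 0
  valid[label$data == 0] <- FALSE
  signal_volume(out, sp, valid_mask = valid,
                normalised = signal$normalised,
                channel_name = signal$channel_name)
}

#' Merge registered signal replicates into a mean distribution
#'
#' Each replicate is first normalised to background — divided by a
#' per-replicate scalar (by default the median of its positive in-mask
#' values) — then the voxel-wise mean is taken over the replicates that
#' carry a valid value at each voxel. The result is scale invariant under
#' per-replicate positive rescaling.
#'
#' @param replicates list of [signal_volume()] objects of equal shape,
#'   already transformed to consensus space.
#' @param background `"median"` (default), `"mean"`, or a numeric vector
#'   of per-replicate scalars.
#' @return A [signal_volume()] flagged `normalised`.
#' @export
merge_registered <- function(replicates, background = "median") {
  n <- length(replicates)
  if (n < 1) stop("need at least one replicate")
  d <- dim(replicates[[1]]$data)
  for (r in replicates)
    if (!identical(dim(r$data), d)) stop("replicate shapes must match")
  bg <- vapply(seq_len(n), function(i) {
    r <- replicates[[i]]
    if (is.numeric(background)) return(background[[min(i, length(background))]])
    v <- r$data[r$valid_mask & r$data > 0]
    if (length(v) == 0) stop("replicate ", i, " has no positive values")
    if (background == "median") median(v) else mean(v)
  }, numeric(1))
  if (any(bg <= 0)) stop("background scalars must be positive")
  acc <- array(0, dim = d)
  cnt <- array(0L, dim = d)
  for (i in seq_len(n)) {
    m <- replicates[[i]]$valid_mask
    acc[m] <- acc[m] + replicates[[i]]$data[m] / bg[i]
    cnt[m] <- cnt[m] + 1L
  }
  out <- array(0, dim = d)
  any_valid <- cnt > 0
  out[any_valid] <- acc[any_valid] / cnt[any_valid]
  signal_volume(out, replicates[[1]]$spacing, valid_mask = any_valid,
                normalised = TRUE,
                channel_name = replicates[[1]]$channel_name)
}

#' Build a per-nucleus-centroid signal volume
#'
#' Alternative aggregation for [project_to_label()]: instead of weighting
#' every nuclear voxel, each nucleus contributes exactly one valid voxel
#' (its centroid) holding its ratio, so the local average weights all
#' nuclei equally regardless of size.
#'
#' @param records nucleus table from [extract_nuclear_signal()].
#' @param shape volume extents `(nx, ny, nz)`.
#' @param spacing voxel spacing in um.
#' @return A [signal_volume()] that is zero except at nucleus centroids.
#' @export
centroid_signal_volume <- function(records, shape, spacing) {
  shape <- as.integer(shape)
  data <- array(0, dim = shape)
  valid <- array(FALSE, dim = shape)
  idx <- cbind(pmin(pmax(round(records$cx / spacing[1]) + 1, 1), shape[1]),
               pmin(pmax(round(records$cy / spacing[2]) + 1, 1), shape[2]),
               pmin(pmax(round(records$cz / spacing[3]) + 1, 1), shape[3]))
  data[idx] <- records$ratio
  valid[idx] <- TRUE
  signal_volume(data, spacing, valid_mask = valid)
}

#' Write a nucleus record table as CSV
#'
#' @param records data frame from [extract_nuclear_signal()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nucleus_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
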