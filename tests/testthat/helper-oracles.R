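# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written as direct/brute-force computations,
# independent of the package's evaluation paths.

# Gaussian blob image in [0, 1], pixel coordinates 0-based.
blob_image <- function(n, cx, cy, r = 8) {
  x <- 0:(n - 1)
  m <- exp(-outer((x - cx)^2, (x - cy)^2, `+`) / (2 * r^2))
  m / max(m)
}

# Small, fast phantom for unit tests (32^3 at 2 um).
small_phantom_spec <- function(seed = 1) {
  phantom_spec(extent = c(32, 32, 32), spacing = c(2, 2, 2),
               radii = c(17, 13, 11), lobe_offset = 11, smoothness = 3,
               seed = seed)
}

# Ellipsoidal blob label volume on an arbitrary grid.
blob_label <- function(extent, spacing = c(1, 1, 1), centre = NULL,
                       radii = extent / 3) {
  if (is.null(centre)) centre <- (extent - 1) / 2
  g <- expand.grid(x = 0:(extent[1] - 1), y = 0:(extent[2] - 1),
                   z = 0:(extent[3] - 1))
  v <- ((g$x - centre[1]) / radii[1])^2 + ((g$y - centre[2]) / radii[2])^2 +
    ((g$z - centre[3]) / radii[3])^2 <= 1
  label_volume(array(as.numeric(v), dim = extent), spacing)
}

# Direct tensor-product cubic B-spline summation over ALL control points:
# the independent oracle for displacement_at. Control point k (1-based)
# sits at knot position (k - 2) * h; the cardinal basis is beta3.
beta3 <- function(x) {
  ax <- abs(x)
  ifelse(ax >= 2, 0,
         ifelse(ax >= 1, (2 - ax)^3 / 6, 2 / 3 - ax^2 + ax^3 / 2))
}

oracle_displacement <- function(coeffs, extent, p) {
  gu <- dim(coeffs)[1]; gv <- dim(coeffs)[2]
  hu <- (extent[1] - 1) / (gu - 3); hv <- (extent[2] - 1) / (gv - 3)
  u <- p[1] / hu; v <- p[2] / hv
  d <- c(0, 0)
  for (k in seq_len(gu)) for (l in seq_len(gv)) {
    w <- beta3(u - (k - 2)) * beta3(v - (l - 2))
    d <- d + w * coeffs[k, l, ]
  }
  d
}

# Brute-force landmark-pair distances: double loop over object pairs and
# landmarks.
oracle_landmark_mean <- function(sets) {
  ds <- c()
  n <- length(sets)
  for (a in 1:(n - 1)) for (b in (a + 1):n)
    for (i in seq_len(nrow(sets[[a]]$points)))
      ds <- c(ds, sqrt(sum((sets[[a]]$points[i, ] - sets[[b]]$points[i, ])^2)))
  list(mean = mean(ds), n = length(ds))
}

# Brute-force re-averaging oracle for project_to_label: recomputes every
# voxel's value from the tile/sample-cube definition directly.
oracle_project <- function(signal, label, params) {
  d <- dim(signal$data)
  sp <- signal$spacing
  tgt <- pmax(1L, as.integer(round(params$target_edge / sp)))
  half <- params$sample_edge / 2
  out <- array(0, dim = d)
  pos <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) for (iz in seq_len(d[3])) {
    if (label$data[ix, iy, iz] == 0) next
    ti <- (c(ix, iy, iz) - 1L) %/% tgt  # 0-based tile index
    lo_t <- ti * tgt + 1L
    hi_t <- pmin(lo_t + tgt - 1L, d)
    ctr <- c((lo_t[1] + hi_t[1] - 2) / 2 * sp[1],
             (lo_t[2] + hi_t[2] - 2) / 2 * sp[2],
             (lo_t[3] + hi_t[3] - 2) / 2 * sp[3])
    sel1 <- which(abs(pos[[1]] - ctr[1]) <= half + 1e-9)
    sel2 <- which(abs(pos[[2]] - ctr[2]) <= half + 1e-9)
    sel3 <- which(abs(pos[[3]] - ctr[3]) <= half + 1e-9)
    vv <- signal$valid_mask[sel1, sel2, sel3]
    if (any(vv)) out[ix, iy, iz] <- mean(signal$data[sel1, sel2, sel3][vv])
  }
  out
}

# Seeded smooth diffeomorphic 2D transform for inversion tests.
seeded_smooth_grid <- function(extent, intervals = c(6, 6), amp = 1.5,
                               seed = 7) {
  co <- morphatlas:::with_seed(seed,
    array(runif(prod(intervals + 3) * 2, -amp, amp),
          dim = c(intervals + 3, 2)))
  bspline_grid(co, extent)
}

expect_equal_tol <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)
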