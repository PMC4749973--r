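#' Supervoxel sampling parameters
#'
#' @param edge supervoxel edge length in um (default 18, one step above
#'   the 12/36 um scales of the local-averaging projection).
#' @param min_coverage fraction of a supervoxel that must lie inside the
#'   consensus mask for its row to be kept (default 0.5).
#' @return An object of class `sampling_params`.
#' @export
sampling_params <- function(edge = 18, min_coverage = 0.5) {
  edge <- as.numeric(edge)
  min_coverage <- as.numeric(min_coverage)
  if (edge <= 0) stop("edge must be > 0")
  if (!(min_coverage > 0 && min_coverage <= 1))
    stop("min_coverage must be in (0, 1]")
  structure(list(edge = edge, min_coverage = min_coverage),
            class = "sampling_params")
}

#' Sample registered signal volumes into a supervoxel feature table
#'
#' Lays an isotropic cubic grid of edge `params$edge` um over the
#' bounding box of the consensus mask; every grid cell covering at least
#' `min_coverage` of consensus foreground becomes one row, whose value
#' per channel is the mean of that channel's valid voxels inside the
#' cell. Rows carry their grid indices so zone maps can be reconstructed.
#'
#' @param channels named list of [signal_volume()] objects sharing shape
#'   and spacing with `consensus`.
#' @param consensus the consensus [label_volume()].
#' @param params a [sampling_params()].
#' @return A data frame of class `cluster_table`: columns `gi, gj, gk`
#'   (grid indices), `cx, cy, cz` (world centroid, um), then one column
#'   per channel (NA where a channel had no valid voxel in the cell).
#'   Grid geometry is carried in attribute `grid`.
#' @export
sample_for_clustering <- function(channels, consensus,
                                  params = sampling_params()) {
  if (length(channels) == 0) stop("need at least one channel")
  d <- dim(consensus$data)
  sp <- consensus$spacing
  for (ch in channels)
    if (!identical(dim(ch$data), d)) stop("channel shapes must match consensus")
  if (!any(consensus$data > 0)) stop("consensus mask is empty")
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("ch", seq_along(channels))

  fg <- which(consensus$data > 0, arr.ind = TRUE)
  bb_lo <- apply(fg, 2, min)
  cell <- pmax(1L, as.integer(round(params$edge / sp)))
  ncell <- as.integer(ceiling((apply(fg, 2, max) - bb_lo + 1) / cell))

  rows <- list()
  for (gk in seq_len(ncell[3])) for (gj in seq_len(ncell[2]))
    for (gi in seq_len(ncell[1])) {
      lo <- bb_lo + (c(gi, gj, gk) - 1L) * cell
      hi <- pmin(lo + cell - 1L, d)
      sub_c <- consensus$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      cov <- sum(sub_c) / prod(cell)
      if (cov < params$min_coverage) next
      vals <- vapply(channels, function(ch) {
        sv <- ch$valid_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
        if (!any(sv)) return(NA_real_)
        mean(ch$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]][sv])
      }, numeric(1))
      ctr <- (lo + hi - 2) / 2 * sp
      rows[[length(rows) + 1]] <-
        c(gi = gi, gj = gj, gk = gk, cx = ctr[1], cy = ctr[2], cz = ctr[3],
          vals)
    }
  if (length(rows) == 0) stop("no supervoxel meets the coverage threshold")
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("gi", "gj", "gk", "cx", "cy", "cz", nm)
  for (cc in c("gi", "gj", "gk")) tab[[cc]] <- as.integer(tab[[cc]])
  attr(tab, "grid") <- list(origin = as.integer(bb_lo), cell = cell,
                            ncell = ncell, shape = d, spacing = sp,
                            channels = nm)
  class(tab) <- c("cluster_table", class(tab))
  tab
}

cluster_channels <- function(table) {
  g <- attr(table, "grid")
  if (!is.null(g$channels)) return(g$channels)
  setdiff(names(table), c("gi", "gj", "gk", "cx", "cy", "cz"))
}

cluster_matrix <- function(table) {
  as.matrix(table[, cluster_channels(table), drop = FALSE])
}

#' Hierarchical clustering of supervoxel rows
#'
#' Agglomerative clustering of the channel vectors with Euclidean
#' distance and, by default, complete linkage. Rows containing any
#' missing channel are dropped with a warning. Deterministic: ties are
#' resolved by `stats::hclust`'s documented ordering of observations.
#'
#' @param table a `cluster_table` from [sample_for_clustering()].
#' @param metric distance metric; only `"euclidean"` is supported.
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return A list of class `zone_dendrogram`: `merge` (the merge matrix),
#'   `height`, `leaf_count`, `rows` (indices of the rows clustered, into
#'   the original table), `hclust` (the underlying object).
#' @export
hierarchical_cluster <- function(table, metric = "euclidean",
                                 linkage = c("complete", "average", "single")) {
  metric <- match.arg(metric, "euclidean")
  linkage <- match.arg(linkage)
  m <- cluster_matrix(table)
  keep <- which(stats::complete.cases(m))
  if (length(keep) < nrow(m))
    warning(nrow(m) - length(keep), " row(s) with missing channels dropped")
  if (length(keep) < 2) stop("need at least two complete rows to cluster")
  hc <- hclust(dist(m[keep, , drop = FALSE], method = metric),
               method = linkage)
  structure(list(merge = hc$merge, height = hc$height,
                 leaf_count = length(keep), rows = keep, hclust = hc),
            class = "zone_dendrogram")
}

#' @export
print.zone_dendrogram <- function(x, ...) {
  cat(sprintf("<zone_dendrogram> %d leaves, %d merges, max height %.4g\n",
              x$leaf_count, nrow(x$merge), max(x$height)))
  invisible(x)
}

#' Cut a dendrogram into k zones
#'
#' Zone ids are assigned by decreasing cluster size; ties broken by the
#' smallest member row index, so the labelling is deterministic.
#'
#' @param dend a `zone_dendrogram`.
#' @param k number of zones, `1 <= k <= leaf_count`.
#' @return A list of class `zone_assignment`: `zone` (integer vector over
#'   the clustered rows), `rows` (their indices in the source table),
#'   `k`.
#' @export
cut_zones <- function(dend, k) {
  k <- as.integer(k)
  if (k < 1 || k > dend$leaf_count) stop("k must be in [1, leaf_count]")
  raw <- cutree(dend$hclust, k = k)
  sizes <- tabulate(raw, k)
  first <- vapply(seq_len(k), function(z) min(which(raw == z)), integer(1))
  ord <- order(-sizes, first)
  zone <- match(raw, ord)
  structure(list(zone = as.integer(zone), rows = dend$rows, k = k),
            class = "zone_assignment")
}

#' Mean signal profile of each zone
#'
#' Arithmetic mean per zone and channel. A held-out channel table (rows
#' aligned by grid index, e.g. a signal deliberately excluded from the
#' clustering to test its predictive power) can be appended.
#'
#' @param table the `cluster_table` the zones were cut from.
#' @param zones a `zone_assignment`.
#' @param extra optional `cluster_table` sharing the sampling grid whose
#'   channels are profiled without having influenced the clustering.
#' @return Numeric matrix zone x channel of mean signals, with a
#'   `zone_size` attribute.
#' @export
zone_profiles <- function(table, zones, extra = NULL) {
  m <- cluster_matrix(table)[zones$rows, , drop = FALSE]
  cols <- colnames(m)
  if (!is.null(extra)) {
    key <- function(t) paste(t$gi, t$gj, t$gk)
    idx <- match(key(table)[zones$rows], key(extra))
    if (any(is.na(idx))) stop("extra table does not cover the sampling grid")
    em <- cluster_matrix(extra)[idx, , drop = FALSE]
    cols <- c(cols, colnames(em))
    m <- cbind(m, em)
  }
  prof <- matrix(NA_real_, nrow = zones$k, ncol = ncol(m),
                 dimnames = list(paste0("zone", seq_len(zones$k)), cols))
  for (z in seq_len(zones$k))
    prof[z, ] <- colMeans(m[zones$zone == z, , drop = FALSE], na.rm = TRUE)
  attr(prof, "zone_size") <- tabulate(zones$zone, zones$k)
  prof
}

#' Reconstruct the zone map at full volume resolution
#'
#' Every voxel inside the consensus mask takes the zone id of the
#' supervoxel it falls in; voxels whose row was dropped (coverage or
#' missing channels) stay 0.
#'
#' @param zones a `zone_assignment`.
#' @param table the `cluster_table` the zones refer to.
#' @param consensus the consensus [label_volume()] used for sampling.
#' @return Integer 3D array of zone ids (0 = unassigned/background).
#' @export
reconstruct_zone_volume <- function(zones, table, consensus) {
  g <- attr(table, "grid")
  if (is.null(g)) stop("table lacks grid geometry")
  if (!identical(dim(consensus$data), g$shape))
    stop("consensus shape does not match the sampling grid")
  out <- array(0L, dim = g$shape)
  d <- g$shape
  for (r in seq_along(zones$rows)) {
    row <- table[zones$rows[r], ]
    lo <- g$origin + (c(row$gi, row$gj, row$gk) - 1L) * g$cell
    hi <- pmin(lo + g$cell - 1L, d)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- zones$zone[r]
  }
  out[consensus$data == 0] <- 0L
  out
}

#' Export a cluster table in Cluster 3.0 input layout
#'
#' Tab-delimited text with supervoxels as rows (UNIQID column first),
#' importable by the external Cluster 3.0 program for cross-checking the
#' internal clustering.
#'
#' @param table a `cluster_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(table, path) {
  nm <- cluster_channels(table)
  df <- data.frame(UNIQID = sprintf("sv_%d_%d_%d", table$gi, table$gj,
                                    table$gk),
                   table[, nm, drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write zone profiles as CSV
#'
#' @param profiles matrix from [zone_profiles()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- data.frame(zone = rownames(profiles), profiles, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
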