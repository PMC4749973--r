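#' Majority-vote consensus mask of registered objects
#'
#' A voxel is consensus foreground iff it is foreground in at least
#' `ceiling(n/2)` of the n objects; ties count as foreground so the n = 2
#' case stays meaningful (the consensus is then the union).
#'
#' @param labels list of [label_volume()] objects with equal shapes and
#'   spacings.
#' @return A [label_volume()] (possibly empty, with a warning).
#' @export
consensus_mask <- function(labels) {
  n <- length(labels)
  if (n < 1) stop("need at least one label volume")
  shape <- dim(labels[[1]]$data)
  for (l in labels)
    if (!identical(dim(l$data), shape)) stop("label shapes must match")
  counts <- Reduce(`+`, lapply(labels, `[[`, "data"))
  cons <- (counts >= ceiling(n / 2)) + 0
  dim(cons) <- shape
  label_volume(cons, labels[[1]]$spacing, object_id = "consensus")
}

#' Volumetric overlap of registered objects against their consensus
#'
#' Per object `i`, `overlap_i = 100 * |O_i & C| / |O_i | C|` (Jaccard
#' index, as a percentage) against the majority consensus `C`; the result
#' carries the per-object values plus mean and standard deviation. Any
#' list containing only copies of one object scores exactly 100%.
#'
#' @param labels list of [label_volume()] objects.
#' @param method `"jaccard"` (default) or `"dice"`
#'   (`100 * 2|O & C| / (|O| + |C|)`).
#' @return A list of class `overlap_result`: `per_object`, `mean_pct`,
#'   `sd_pct`.
#' @export
volumetric_overlap <- function(labels, method = c("jaccard", "dice")) {
  method <- match.arg(method)
  cons <- suppressWarnings(consensus_mask(labels))
  cvec <- cons$data > 0
  if (!any(cvec)) {
    warning("empty consensus; overlaps defined as 0")
    per <- rep(0, length(labels))
  } else {
    per <- vapply(labels, function(l) {
      o <- l$data > 0
      inter <- sum(o & cvec)
      if (method == "jaccard") {
        un <- sum(o | cvec)
        if (un == 0) 0 else 100 * inter / un
      } else {
        s <- sum(o) + sum(cvec)
        if (s == 0) 0 else 100 * 2 * inter / s
      }
    }, numeric(1))
  }
  names(per) <- vapply(labels, function(l)
    if (nzchar(l$object_id)) l$object_id else "", character(1))
  structure(list(per_object = per, mean_pct = mean(per),
                 sd_pct = if (length(per) > 1) sd(per) else 0),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> mean %.2f%% +/- %.2f%% over %d objects\n",
              x$mean_pct, x$sd_pct, length(x$per_object)))
  invisible(x)
}

#' Mean landmark-pair distance across registered objects
#'
#' Euclidean distance in um between the same named landmark in every
#' unordered pair of objects: L landmarks over n objects give
#' `L * n(n-1)/2` pairs (e.g. 7 landmarks over 3 objects: 21 pairs).
#'
#' @param sets list of >= 2 [landmark_set()] objects with identical name
#'   lists.
#' @return A list of class `landmark_distance_result`: `per_pair` (data
#'   frame with `landmark`, `object_a`, `object_b`, `distance_um`),
#'   `mean_um`, `sd_um`, `pair_count`.
#' @export
mean_landmark_distance <- function(sets) {
  n <- length(sets)
  if (n < 2) stop("need at least two landmark sets")
  ref <- sets[[1]]$names
  for (s in sets)
    if (!identical(s$names, ref)) stop("landmark name lists must be identical")
  rows <- list()
  for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
    d <- sqrt(rowSums((sets[[a]]$points - sets[[b]]$points)^2))
    rows[[length(rows) + 1]] <- data.frame(
      landmark = ref,
      object_a = sets[[a]]$object_id, object_b = sets[[b]]$object_id,
      distance_um = as.numeric(d))
  }
  per <- do.call(rbind, rows)
  structure(list(per_pair = per, mean_um = mean(per$distance_um),
                 sd_um = if (nrow(per) > 1) sd(per$distance_um) else 0,
                 pair_count = nrow(per)),
            class = "landmark_distance_result")
}

#' @export
print.landmark_distance_result <- function(x, ...) {
  cat(sprintf("<landmark_distance_result> mean %.3f um +/- %.3f um over %d pairs\n",
              x$mean_um, x$sd_um, x$pair_count))
  invisible(x)
}

#' Write an overlap or landmark-distance result as CSV
#'
#' @param x an `overlap_result` or `landmark_distance_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(x, path) {
  if (inherits(x, "overlap_result")) {
    df <- data.frame(object = names(x$per_object), overlap_pct = x$per_object)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "landmark_distance_result")) {
    write.csv(x$per_pair, path, row.names = FALSE, quote = FALSE)
  } else stop("unsupported result type")
  invisible(path)
}
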