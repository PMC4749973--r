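#' Named 3D landmark set
#'
#' Ordered named points in micrometres tied to one object. Corresponding
#' sets across objects must share identical name lists so landmark-pair
#' distances are well defined.
#'
#' @param object_id free-text object identifier.
#' @param names character vector of unique landmark names.
#' @param points numeric matrix (n x 3) of coordinates in um.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(object_id, names, points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have three columns (x, y, z)")
  if (nrow(points) == 0) stop("landmark set must contain at least one point")
  names <- as.character(names)
  if (length(names) != nrow(points)) stop("one name per point required")
  if (anyDuplicated(names)) stop("landmark names must be unique within a set")
  if (any(!is.finite(points))) stop("landmark coordinates must be numeric")
  storage.mode(points) <- "double"
  dimnames(points) <- list(names, c("x", "y", "z"))
  structure(list(object_id = object_id, names = names, points = points),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> '%s': %d points (um)\n", x$object_id,
              nrow(x$points)))
  invisible(x)
}

#' Read landmarks from CSV
#'
#' Expects a header `name,x,y,z` with coordinates in um; row order is
#' preserved and names are validated unique.
#'
#' @param path CSV file path.
#' @param object_id identifier for the resulting set (defaults to the file
#'   base name).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, object_id = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns name,x,y,z")
  if (nrow(df) == 0) stop("landmark CSV has no points")
  for (cc in c("x", "y", "z"))
    if (!is.numeric(df[[cc]])) stop("non-numeric coordinates in column ", cc)
  if (is.null(object_id))
    object_id <- tools::file_path_sans_ext(basename(path))
  landmark_set(object_id, df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' Write landmarks to CSV
#'
#' @param lm a [landmark_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  df <- data.frame(name = lm$names, x = lm$points[, 1], y = lm$points[, 2],
                   z = lm$points[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
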