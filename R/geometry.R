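#' Multi-electrode array geometry
#'
#' An `electrode_array` holds the planar layout of a multi-electrode array
#' (MEA): integer electrode ids, their coordinates in micrometres, and the
#' nominal pitch. Electrode ids are `0 .. E-1` and index the rows of every
#' `E`-row voltage matrix in the package (row = id + 1).
#'
#' @param ids integer vector of electrode ids, `0 .. E-1`.
#' @param x,y numeric coordinates in micrometres.
#' @param pitch nominal nearest-neighbour spacing in micrometres.
#' @return an object of class `electrode_array`.
#' @export
electrode_array <- function(ids, x, y, pitch) {
  ids <- as.integer(ids)
  stopifnot(length(ids) >= 1, length(x) == length(ids), length(y) == length(ids))
  if (anyDuplicated(ids)) stop("electrode ids must be unique")
  if (!identical(sort(ids), seq_along(ids) - 1L))
    stop("electrode ids must be 0 .. E-1")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("electrode positions must be finite")
  ord <- order(ids)
  structure(
    list(ids = ids[ord], x = as.numeric(x)[ord], y = as.numeric(y)[ord],
         pitch = as.numeric(pitch)),
    class = "electrode_array")
}

#' Build a rectangular grid MEA
#'
#' Electrodes are laid out on a `rows` x `cols` lattice with the given pitch;
#' ids run `0 .. rows*cols - 1` in row-major order.
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @param pitch lattice spacing in micrometres (> 0).
#' @return an [electrode_array].
#' @examples
#' arr <- build_grid_geometry(16, 32, 60)  # 512 electrodes, 60 um pitch
#' @export
build_grid_geometry <- function(rows, cols, pitch = 60) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  if (pitch <= 0) stop("pitch must be > 0")
  r <- rep(seq_len(rows) - 1L, each = cols)
  c <- rep(seq_len(cols) - 1L, times = rows)
  electrode_array(ids = seq_len(rows * cols) - 1L,
                  x = c * pitch, y = r * pitch, pitch = pitch)
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %d electrodes, pitch %g um\n",
              length(x$ids), x$pitch))
  invisible(x)
}

n_electrodes <- function(array) length(array$ids)

electrode_xy <- function(array, id) {
  i <- match(id, array$ids)
  if (anyNA(i)) stop("unknown electrode id: ", paste(id[is.na(i)], collapse = ", "))
  cbind(array$x[i], array$y[i])
}

#' Electrodes within a radius of a centre electrode
#'
#' @param array an [electrode_array].
#' @param center electrode id.
#' @param radius Euclidean radius in micrometres.
#' @param include_center keep the centre electrode itself?
#' @return integer vector of electrode ids in ascending order.
#' @export
neighbors_within <- function(array, center, radius, include_center = FALSE) {
  p <- electrode_xy(array, center)
  d <- sqrt((array$x - p[1])^2 + (array$y - p[2])^2)
  tol <- 1e-9 * max(1, radius)
  sel <- d <= radius + tol
  if (!include_center) sel[match(center, array$ids)] <- FALSE
  sort(array$ids[sel])
}

#' Read / write an electrode geometry CSV
#'
#' The CSV has header `electrode_id,x_um,y_um`; ids must be `0 .. E-1`.
#'
#' @param path file path.
#' @param array an [electrode_array] (for writing).
#' @param pitch pitch recorded on the object when reading (defaults to the
#'   minimal pairwise distance).
#' @return [read_geometry_csv()] returns an [electrode_array];
#'   [write_geometry_csv()] returns `path` invisibly.
#' @export
read_geometry_csv <- function(path, pitch = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("electrode_id", "x_um", "y_um") %in% names(df)))
  if (is.null(pitch)) {
    xy <- cbind(df$x_um, df$y_um)
    pitch <- min(stats::dist(xy))
  }
  electrode_array(df$electrode_id, df$x_um, df$y_um, pitch)
}

#' @rdname read_geometry_csv
#' @export
write_geometry_csv <- function(array, path) {
  utils::write.csv(
    data.frame(electrode_id = array$ids, x_um = array$x, y_um = array$y),
    path, row.names = FALSE)
  invisible(path)
}
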