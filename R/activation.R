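#' Binarize a source epoch into an activation mask
#'
#' A source is "active" at a sample when the absolute value of its current
#' exceeds that source's epoch-wide threshold: the mean plus the sample
#' standard deviation (N - 1 denominator) of the absolute amplitudes over
#' *all* samples of the epoch.  The inequality is strict, so a source whose
#' absolute amplitude is constant (SD = 0, every sample exactly at threshold)
#' never activates.  Thresholds are always computed on the full epoch, never
#' per window, so the supra-threshold set is comparable across windows.
#'
#' @param epoch a [source_epoch()] with at least two samples.
#' @return an `activation_mask`: list with `mask` (logical
#'   `n_sources x n_samples`) and `thresholds` (per-source numeric vector,
#'   same units as `values`).
#' @examples
#' ep <- source_epoch(rbind(c(0, 0, 0, 10)), cbind(0, 0, 0), fs = 4)
#' binarize_epoch(ep)$mask       # only the 4th sample is supra-threshold
#' @export
binarize_epoch <- function(epoch) {
  stopifnot(inherits(epoch, "source_epoch"))
  if (ncol(epoch$values) < 2L)
    stop_fd4d("epoch too short for threshold estimation (need >= 2 samples)")
  a <- abs(epoch$values)
  n <- ncol(a)
  mu <- rowMeans(a)
  # row-wise sample SD without apply(); guard tiny negative fp residuals
  v <- (rowSums(a * a) - n * mu * mu) / (n - 1)
  thr <- mu + sqrt(pmax(v, 0))
  mask <- a > thr  # thr recycles down columns: per-source threshold
  structure(list(mask = mask, thresholds = thr), class = "activation_mask")
}

#' @export
print.activation_mask <- function(x, ...) {
  cat(sprintf("<activation_mask> %d sources x %d samples, %.1f%% active\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Normalize source coordinates onto the unit cube
#'
#' Affine per-axis map of a bounding box onto `[0, 1)`.  By default the box
#' is the global bounding box of *all* sources of the subject (not only the
#' active ones), so clouds built from different windows of one epoch share a
#' frame; pass a precomputed `box` (e.g. the union box of a cohort) for
#' cross-subject comparability.  Axis maxima land just below 1 so the top
#' boundary falls in the last grid cell under the half-open convention; a
#' degenerate axis (zero extent) maps to 0.
#'
#' @param coords numeric `n x 3` (or `n x d`) matrix of positions.
#' @param box optional list with numeric vectors `min` and `max` (one entry
#'   per axis) to normalize against instead of the coords' own bounding box.
#' @return list with `coords` (normalized matrix, entries in `[0, 1)`) and
#'   `box` (the bounding box used).
#' @export
normalize_coords <- function(coords, box = NULL) {
  assert_finite_matrix(coords, "coords")
  if (nrow(coords) < 1L) stop_fd4d("need at least one source")
  if (is.null(box)) {
    box <- list(min = apply(coords, 2, min), max = apply(coords, 2, max))
  }
  stopifnot(length(box$min) == ncol(coords), length(box$max) == ncol(coords))
  ext <- box$max - box$min
  out <- matrix(0, nrow(coords), ncol(coords))
  top <- 1 - 2^-53  # largest double below 1
  for (j in seq_len(ncol(coords))) {
    if (ext[j] > 0) {
      s <- (coords[, j] - box$min[j]) / ext[j]
      out[, j] <- pmin(pmax(s, 0), top)
    }  # degenerate axis stays 0
  }
  list(coords = out, box = box)
}

#' Point clouds on the unit hypercube
#'
#' A deduplicated set of points in `[0, 1)^dim`, `dim` 3 (one sample's
#' activations) or 4 (a window's activations with time as the fourth axis).
#'
#' @param points numeric matrix with `dim` columns; rows are points.
#' @param dim 3 or 4.
#' @param provenance free-text origin tag.
#' @param dedupe drop duplicated rows (skip when the caller guarantees
#'   uniqueness, e.g. distinct source positions).
#' @return object of class `point_cloud` with `points`, `dim`, `n_points`,
#'   `provenance`.
#' @export
point_cloud <- function(points, dim = ncol(points), provenance = "",
                        dedupe = TRUE) {
  if (!is.matrix(points)) points <- matrix(points, ncol = dim)
  stopifnot(dim >= 1)  # 3 and 4 in the pipeline; other dims for validation
  if (ncol(points) != dim)
    stop_fd4d("points has %d columns, expected dim = %d", ncol(points), dim)
  if (nrow(points) > 0) {
    assert_finite_matrix(points, "points")
    if (any(points < 0) || any(points >= 1))
      stop_fd4d("point coordinates must lie in [0, 1)")
    if (dedupe) {
      # radix-based row dedupe; unique.matrix() pastes rows and is far slower
      dup <- duplicated(data.table::as.data.table(points))
      if (any(dup)) points <- points[!dup, , drop = FALSE]
    }
  }
  structure(list(points = points, dim = as.integer(dim),
                 n_points = nrow(points), provenance = provenance),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> dim %d, %d points%s\n", x$dim, x$n_points,
              if (nzchar(x$provenance)) paste0(" (", x$provenance, ")") else ""))
  invisible(x)
}

#' Build the 3D point cloud of one time sample
#'
#' Returns the normalized positions of every source whose mask entry at
#' sample `t` is `TRUE`.  An empty cloud is a legal result.
#'
#' @param mask an `activation_mask` (or a logical matrix).
#' @param ncoords normalized coordinates from [normalize_coords()] (the
#'   `coords` element), one row per source.
#' @param t sample index, 1-based.
#' @return a `point_cloud` with `dim = 3`.
#' @export
cloud_3d <- function(mask, ncoords, t) {
  m <- if (inherits(mask, "activation_mask")) mask$mask else mask
  if (t < 1L || t > ncol(m)) stop_fd4d("sample index %d out of range", t)
  point_cloud(ncoords[m[, t], , drop = FALSE], dim = 3L,
              provenance = sprintf("sample %d", t))
}

#' Build the 4D point cloud of a window
#'
#' Stacks the per-sample 3D clouds of `width` consecutive samples starting at
#' `start`, appending the within-window time coordinate `(t - t0) / width`
#' (in `[0, 1)`) as the fourth axis, and deduplicates.
#'
#' @inheritParams cloud_3d
#' @param start first sample of the window (1-based).
#' @param width window width in samples; the window is
#'   `[start, start + width - 1]` and must lie inside the epoch.
#' @param dedupe see [point_cloud()]; duplicates can only arise when two
#'   sources share a normalized position.
#' @return a `point_cloud` with `dim = 4`.
#' @export
cloud_4d <- function(mask, ncoords, start, width, dedupe = TRUE) {
  m <- if (inherits(mask, "activation_mask")) mask$mask else mask
  if (start < 1L || width < 1L || start + width - 1L > ncol(m))
    stop_fd4d("window [%d, %d] extends past the epoch (n_samples = %d)",
              start, start + width - 1L, ncol(m))
  sel <- m[, start:(start + width - 1L), drop = FALSE]
  idx <- which(sel, arr.ind = TRUE, useNames = FALSE)
  pts <- cbind(ncoords[idx[, 1L], , drop = FALSE], (idx[, 2L] - 1) / width)
  point_cloud(pts, dim = 4L, dedupe = dedupe,
              provenance = sprintf("window %d+%d", start, width))
}

#' Export an activation mask as run-length-encoded TSV
#'
#' One row per activation run: `source`, `start` (1-based sample), `length`.
#' Inspection/debugging aid only; nothing in the pipeline reads it back.
#'
#' @param mask an `activation_mask`.
#' @param path output file.
#' @export
write_mask_rle <- function(mask, path) {
  stopifnot(inherits(mask, "activation_mask"))
  rows <- lapply(seq_len(nrow(mask$mask)), function(i) {
    r <- rle(as.vector(mask$mask[i, ]))
    ends <- cumsum(r$lengths)
    on <- which(r$values)
    if (!length(on)) return(NULL)
    data.frame(source = i, start = ends[on] - r$lengths[on] + 1L,
               length = r$lengths[on])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(source = integer(0), start = integer(0),
                      length = integer(0))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
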