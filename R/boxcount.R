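#' Count occupied boxes of a point cloud at one grid resolution
#'
#' Partitions `[0, 1)^dim` into `r^dim` congruent boxes (cell index per axis
#' = `floor(coordinate * r)`) and returns the number of cells containing at
#' least one point.  The kernel maps every point to a mixed-radix integer key
#' and counts distinct keys, so no `r^dim` occupancy array is ever allocated.
#'
#' @param cloud a [point_cloud()] (or a bare numeric matrix of points in
#'   `[0, 1)`); must be non-empty.
#' @param r grid divisions per axis (integer >= 1).
#' @return the number of occupied boxes (integer-valued numeric).
#' @examples
#' count_boxes(point_cloud(matrix(runif(300), ncol = 3)), r = 8)
#' @export
count_boxes <- function(cloud, r) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else cloud
  stopifnot(is.numeric(r), length(r) == 1L, r >= 1, r == floor(r))
  if (is.null(pts) || nrow(pts) == 0L)
    stop_fd4d("cannot count boxes of empty set")
  count_boxes_kernel(pts, as.integer(r))
}

#' Estimate the box-counting (Minkowski-Bouligand) dimension of a cloud
#'
#' Counts occupied boxes over a ladder of dyadic resolutions and fits an
#' unweighted least-squares regression of `log n(r)` on `log r` over the
#' scaling sub-range `fit_range`; the slope is the fractal dimension
#' estimate.  (Regressing on `log r` instead of `log(1/r)` flips the sign of
#' the slope only, so the estimate is reported positive.)  Defaults follow
#' the reference analysis: resolutions 1..128 (powers of two), fit over
#' r = 8..64.
#'
#' An empty cloud yields a curve with `slope = 0` and `NA` counts, with a
#' warning: in the windowed pipeline this keeps series aligned across
#' subjects instead of dropping windows.
#'
#' @inheritParams count_boxes
#' @param resolutions ascending powers of two.
#' @param fit_range length-2 vector `c(r_min, r_max)`; both endpoints must
#'   be members of `resolutions` and enclose at least 3 of them.
#' @return a `boxcount_curve`: `resolutions`, `counts`, `fit_range`, `slope`
#'   (the FD estimate), `r2`, `dim`, `n_points`.
#' @examples
#' line <- point_cloud(matrix(rep((0:999) / 1000, 3), ncol = 3), dedupe = FALSE)
#' fd_estimate(line)$slope  # close to 1
#' @export
fd_estimate <- function(cloud, resolutions = 2^(0:7), fit_range = c(8, 64)) {
  stopifnot(is.numeric(resolutions), length(resolutions) >= 3L)
  if (is.unsorted(resolutions, strictly = TRUE) ||
      any(resolutions != 2^round(log2(resolutions))))
    stop_fd4d("resolutions must be ascending powers of two")
  stopifnot(length(fit_range) == 2L)
  if (!all(fit_range %in% resolutions))
    stop_fd4d("fit_range endpoints must be members of resolutions")
  in_fit <- resolutions >= fit_range[1] & resolutions <= fit_range[2]
  if (sum(in_fit) < 3L)
    stop_fd4d("fit range must contain at least 3 resolutions")

  pts <- if (inherits(cloud, "point_cloud")) cloud$points else cloud
  d <- ncol(pts) %||% NA_integer_
  if (is.null(pts) || nrow(pts) == 0L) {
    warning("empty cloud: FD defined as 0", call. = FALSE)
    return(structure(list(resolutions = resolutions,
                          counts = rep(NA_real_, length(resolutions)),
                          fit_range = fit_range, slope = 0, r2 = NA_real_,
                          dim = d, n_points = 0L),
                     class = "boxcount_curve"))
  }
  counts <- vapply(resolutions, function(r) count_boxes_kernel(pts, as.integer(r)),
                   numeric(1))
  x <- log(resolutions[in_fit])
  y <- log(counts[in_fit])
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  r2 <- if (all(y == y[1])) NA_real_ else {
    suppressWarnings(cor(x, y)^2)
  }
  structure(list(resolutions = resolutions, counts = counts,
                 fit_range = fit_range, slope = slope, r2 = r2,
                 dim = ncol(pts), n_points = nrow(pts)),
            class = "boxcount_curve")
}

#' @export
print.boxcount_curve <- function(x, ...) {
  cat(sprintf("<boxcount_curve> dim %s, %d points, FD = %.3f (fit r %g..%g, R2 %s)\n",
              x$dim, x$n_points, x$slope, x$fit_range[1], x$fit_range[2],
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2))))
  invisible(x)
}

#' Export a box-count curve as TSV for log-log diagnostics
#' @param curve a `boxcount_curve`.
#' @param path output file.
#' @export
write_curve_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "boxcount_curve"))
  data.table::fwrite(data.table::data.table(r = curve$resolutions,
                                            n_r = curve$counts),
                     path, sep = "\t")
  invisible(path)
}

#' Per-window 4D fractal-dimension series of an epoch
#'
#' Thresholds the epoch ([binarize_epoch()]), normalizes source positions
#' once against the subject (or supplied) bounding box, splits the epoch into
#' consecutive non-overlapping windows of `window_seconds` (trailing partial
#' window discarded), builds each window's 4D activation cloud and estimates
#' its box-counting dimension.  A 120-s epoch with 1-s windows yields exactly
#' 120 values regardless of sampling rate.
#'
#' @param epoch a [source_epoch()] at least one window long.
#' @param window_seconds window length in seconds (default 1).
#' @param resolutions,fit_range passed to [fd_estimate()].
#' @param box optional shared bounding box (see [normalize_coords()]).
#' @return an `fd_series`: `subject_id`, `group`, `window_seconds`, `values`
#'   (one FD per window), `mean_fd`.
#' @export
fd_series <- function(epoch, window_seconds = 1, resolutions = 2^(0:7),
                      fit_range = c(8, 64), box = NULL) {
  stopifnot(inherits(epoch, "source_epoch"),
            is.numeric(window_seconds), window_seconds > 0)
  if (epoch_seconds(epoch) < window_seconds)
    stop_fd4d("epoch (%.2f s) shorter than one window (%.2f s)",
              epoch_seconds(epoch), window_seconds)
  am <- binarize_epoch(epoch)
  nc <- normalize_coords(epoch$coords, box = box)$coords
  dedupe <- anyDuplicated(nc) > 0L  # distinct positions => clouds unique
  w <- as.integer(round(epoch$fs * window_seconds))
  n_win <- floor(ncol(epoch$values) / w)
  vals <- numeric(n_win)
  for (k in seq_len(n_win)) {
    cl <- cloud_4d(am, nc, start = (k - 1L) * w + 1L, width = w,
                   dedupe = dedupe)
    if (cl$n_points == 0L) {
      warning(sprintf("window %d: no supra-threshold activations, FD = 0", k),
              call. = FALSE)
      vals[k] <- 0
      next
    }
    est <- tryCatch(
      fd_estimate(cl, resolutions = resolutions, fit_range = fit_range),
      error = function(e) stop_fd4d("window %d: %s", k, conditionMessage(e)))
    if (est$slope < 0 || est$slope > 4)
      stop_fd4d("window %d: FD estimate %.3f outside [0, 4]", k, est$slope)
    vals[k] <- est$slope
  }
  structure(list(subject_id = epoch$subject_id, group = epoch$group,
                 window_seconds = window_seconds, values = vals,
                 mean_fd = mean(vals)),
            class = "fd_series")
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("<fd_series> %s: %d windows of %g s, mean 4DFD = %.3f\n",
              x$subject_id, length(x$values), x$window_seconds, x$mean_fd))
  invisible(x)
}

#' Export an FD series (and a cohort summary) as TSV
#'
#' @param series an `fd_series`.
#' @param path output file.
#' @param header_comment optional `# `-prefixed first line (e.g. config hash).
#' @export
write_fd_series_tsv <- function(series, path, header_comment = NULL) {
  stopifnot(inherits(series, "fd_series"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines("subject_id\twindow_index\tfd", con)
  writeLines(sprintf("%s\t%d\t%.10g", series$subject_id,
                     seq_along(series$values), series$values), con)
  invisible(path)
}
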