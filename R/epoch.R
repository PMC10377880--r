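#' Source-space EEG epoch
#'
#' Container for one subject's source-reconstructed epoch: a real-valued
#' current-amplitude matrix (sources in rows, time samples in columns), the
#' 3D positions of the sources, and acquisition metadata.  This is the entry
#' point of the pipeline; sensor-space preprocessing and inverse modelling
#' happen upstream and are out of scope.
#'
#' @param values numeric matrix, `n_sources x n_samples`, source current
#'   amplitudes in arbitrary units.  Must be finite.
#' @param coords numeric matrix, `n_sources x 3`, source positions in mm.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id subject identifier string.
#' @param group optional group label (e.g. `"groupA"` / `"groupB"`); `NA`
#'   when unknown.
#' @return an object of class `source_epoch` with fields `values`, `coords`,
#'   `fs`, `subject_id`, `group`.
#' @examples
#' ep <- source_epoch(matrix(rnorm(40), 4, 10), matrix(rnorm(12), 4, 3), fs = 10)
#' epoch_seconds(ep)
#' @export
source_epoch <- function(values, coords, fs, subject_id = "subject",
                         group = NA_character_) {
  assert_finite_matrix(values, "values")
  assert_finite_matrix(coords, "coords")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_fd4d("values must have at least one source and one sample")
  if (ncol(coords) != 3L)
    stop_fd4d("coords must have exactly 3 columns (x, y, z in mm)")
  if (nrow(coords) != nrow(values))
    stop_fd4d("coords has %d rows but values has %d sources",
              nrow(coords), nrow(values))
  stopifnot(is.numeric(fs), length(fs) == 1L, is.finite(fs))
  if (fs <= 0) stop_fd4d("fs must be positive")
  dimnames(values) <- NULL
  dimnames(coords) <- NULL
  structure(
    list(values = values, coords = coords, fs = as.numeric(fs),
         subject_id = as.character(subject_id), group = as.character(group)),
    class = "source_epoch")
}

#' @rdname source_epoch
#' @param epoch a `source_epoch`.
#' @export
n_sources <- function(epoch) nrow(epoch$values)

#' @rdname source_epoch
#' @export
n_samples <- function(epoch) ncol(epoch$values)

#' @rdname source_epoch
#' @export
epoch_seconds <- function(epoch) ncol(epoch$values) / epoch$fs

#' @export
print.source_epoch <- function(x, ...) {
  cat(sprintf("<source_epoch> %s%s: %d sources x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id,
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              nrow(x$values), ncol(x$values), x$fs, epoch_seconds(x)))
  invisible(x)
}

#' Read and write source epochs as plain text
#'
#' Plain-text serialization of a [source_epoch()]: `<stem>_values.tsv` (the
#' amplitude matrix, no header, one row per source), `<stem>_coords.tsv`
#' (columns `x`, `y`, `z`, mm) and `<stem>_meta.json` (`fs`, `subject_id`,
#' `group`).
#'
#' @param epoch a `source_epoch`.
#' @param stem path prefix for the three files.
#' @return `write_epoch()` returns `stem` invisibly; `read_epoch()` returns a
#'   `source_epoch`.
#' @export
write_epoch <- function(epoch, stem) {
  stopifnot(inherits(epoch, "source_epoch"))
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(epoch$values),
                     paste0(stem, "_values.tsv"), sep = "\t", col.names = FALSE)
  co <- data.table::as.data.table(epoch$coords)
  data.table::setnames(co, c("x", "y", "z"))
  data.table::fwrite(co, paste0(stem, "_coords.tsv"), sep = "\t")
  jsonlite::write_json(
    list(fs = epoch$fs, subject_id = epoch$subject_id, group = epoch$group),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, null = "null")
  invisible(stem)
}

#' @rdname write_epoch
#' @export
read_epoch <- function(stem) {
  vf <- paste0(stem, "_values.tsv")
  cf <- paste0(stem, "_coords.tsv")
  mf <- paste0(stem, "_meta.json")
  for (f in c(vf, cf, mf))
    if (!file.exists(f)) stop_fd4d("epoch file not found: %s", f)
  values <- as.matrix(data.table::fread(vf, header = FALSE, sep = "\t"))
  dimnames(values) <- NULL
  coords <- as.matrix(data.table::fread(cf, header = TRUE, sep = "\t"))
  dimnames(coords) <- NULL
  meta <- jsonlite::read_json(mf)
  source_epoch(values, coords, fs = meta$fs,
               subject_id = meta$subject_id %||% "subject",
               group = as.character(meta$group %||% NA_character_))
}
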