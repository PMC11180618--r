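# CSV bodies with JSON sidecars for every tabular artifact. The sidecar
# carries calibration/parameters/provenance so that any output can be traced
# back to the command that produced it; the CSV carries only data. Sidecar
# path = CSV path with extension swapped for .json.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(path, kind, meta = list()) {
  meta$artifact <- kind
  meta$package <- "myowave"
  jsonlite::write_json(as_plain_list(meta), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s table is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "myowave_format_error")
  }
  invisible(df)
}

boundary_cols <- c("frame", "column", "upper", "lower", "valid")
annotation_cols <- c("map_id", "ridge_c0", "ridge_t0", "ridge_c1", "ridge_t1",
                     "band_c0", "band_c1", "next_ridge_t")
metric_cols <- c("map_id", "amplitude_um", "period_s", "frequency_hz",
                 "velocity_um_s", "wavelength_um", "direction")

#' Read and write tabular artifacts
#'
#' Every table travels as a UTF-8 comma-separated file with a header row and
#' `.` decimals, next to a JSON sidecar (same stem, `.json`) holding
#' calibration, parameters and provenance. `read_*(write_*(x))` reproduces
#' the table to full numeric precision; missing required columns raise a
#' format error that names the column.
#'
#' @param boundaries,annotations,metrics Tibbles as produced by
#'   [trace_boundaries()], [read_annotations()] / manual marking, and
#'   [compute_metrics()].
#' @param path CSV file path.
#' @param meta Optional named list merged into the JSON sidecar.
#'
#' @return Writers return `path` invisibly; readers return a tibble, with
#'   the parsed sidecar (if present) attached as attribute `"sidecar"`.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_boundaries <- function(boundaries, path, meta = list()) {
  check_columns(boundaries, boundary_cols, "Boundary")
  readr::write_csv(boundaries[boundary_cols], path, progress = FALSE)
  write_sidecar(path, "horn_boundaries", meta)
  invisible(path)
}

#' @rdname table_io
#' @export
read_boundaries <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, boundary_cols, "Boundary")
  attr(df, "sidecar") <- read_sidecar(path)
  df
}

#' @rdname table_io
#' @export
write_annotations <- function(annotations, path, meta = list()) {
  check_columns(annotations, annotation_cols, "Annotation")
  readr::write_csv(annotations[union(annotation_cols, names(annotations))], path,
                   progress = FALSE)
  write_sidecar(path, "wave_annotations", meta)
  invisible(path)
}

#' @rdname table_io
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, annotation_cols, "Annotation")
  attr(df, "sidecar") <- read_sidecar(path)
  df
}

#' @rdname table_io
#' @export
write_metrics <- function(metrics, path, meta = list()) {
  check_columns(metrics, metric_cols, "Metrics")
  readr::write_csv(metrics, path, progress = FALSE)
  write_sidecar(path, "wave_metrics", meta)
  invisible(path)
}

#' @rdname table_io
#' @export
read_metrics <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, metric_cols, "Metrics")
  attr(df, "sidecar") <- read_sidecar(path)
  df
}

#' @rdname table_io
#' @param map An [st_map()].
#' @export
write_st_map <- function(map, path, meta = list()) {
  stopifnot(inherits(map, "myowave_st_map"))
  v <- map$values
  df <- as.data.frame(v)
  names(df) <- sprintf("t%d", seq_len(ncol(v)) - 1L)
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  meta$quantity <- map$quantity
  meta$calibration <- map$calibration
  write_sidecar(path, "st_map", meta)
  invisible(path)
}

#' @rdname table_io
#' @export
read_st_map <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) == 0 || !all(grepl("^t\\d+$", names(df)))) {
    abort("Map table must have columns t0, t1, ... (one per frame).",
          class = "myowave_format_error")
  }
  meta <- read_sidecar(path)
  cal <- calibration()
  if (!is.null(meta$calibration)) {
    cal <- calibration(
      fps = meta$calibration$fps,
      px_per_mm = meta$calibration$px_per_mm,
      orientation = meta$calibration$orientation
    )
  }
  st_map(as.matrix(df), quantity = meta$quantity %||% "mean_intensity", calibration = cal)
}
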