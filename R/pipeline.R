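with_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)),
          class = c("myowave_stage_error", class(e)[1]))
  })
}

#' Run the full map-building pipeline on one recording
#'
#' Loads (or accepts) a frame stack, traces the organ boundaries, builds
#' the raw area and mean-intensity spatiotemporal maps and their enhanced
#' forms, and — when `out_dir` is given — writes every intermediate as CSV
#' with a JSON sidecar recording calibration and parameters, plus rendered
#' Hovmoller plots. Outputs are deterministic: rerunning with the same
#' inputs and configuration reproduces identical CSVs.
#'
#' @param input A [frame_stack()] or a path accepted by [load_frames()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param cal A [calibration()].
#' @param bparams A [boundary_params()].
#' @param eparams An [enhance_params()].
#' @param plots Write Hovmoller PNGs of the enhanced maps. Default `TRUE`
#'   when `out_dir` is given.
#'
#' @return A list: `boundaries` (tibble), `area`, `intensity`,
#'   `enhanced_area`, `enhanced_intensity` (all [st_map()]s).
#' @export
run_pipeline <- function(input, out_dir = NULL, cal = calibration(),
                         bparams = boundary_params(), eparams = enhance_params(),
                         plots = !is.null(out_dir)) {
  stack <- if (inherits(input, "myowave_frame_stack")) {
    input
  } else {
    with_stage("load", load_frames(input, expected_interval = 1 / cal$fps))
  }
  boundaries <- with_stage("boundary", trace_boundaries(stack, bparams))
  area <- with_stage("maps", column_area(boundaries, cal))
  intensity <- with_stage("maps", column_mean_intensity(stack, boundaries, cal))
  enhanced_area <- with_stage("enhance", enhance_map(area, eparams))
  enhanced_intensity <- with_stage("enhance", enhance_map(intensity, eparams))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- list(calibration = cal, boundary_params = bparams,
                 enhance_params = eparams)
    write_boundaries(boundaries, file.path(out_dir, "boundaries.csv"), meta)
    write_st_map(area, file.path(out_dir, "area_map.csv"), meta)
    write_st_map(intensity, file.path(out_dir, "intensity_map.csv"), meta)
    write_st_map(enhanced_area, file.path(out_dir, "enhanced_area_map.csv"), meta)
    write_st_map(enhanced_intensity, file.path(out_dir, "enhanced_intensity_map.csv"), meta)
    if (plots) {
      for (nm in c("enhanced_area", "enhanced_intensity")) {
        m <- if (nm == "enhanced_area") enhanced_area else enhanced_intensity
        ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), autoplot(m),
                        width = 7, height = 5, dpi = 120)
      }
    }
  }
  list(
    boundaries = boundaries, area = area, intensity = intensity,
    enhanced_area = enhanced_area, enhanced_intensity = enhanced_intensity
  )
}

#' Compute (and optionally sample) waveform metrics for one map
#'
#' Joins a spatiotemporal map with its wave annotations, computes waveform
#' metrics with segment labels, optionally applies the
#' 3-waves-per-segment random sampling protocol, and summarises medians.
#'
#' @param map An [st_map()] or path to a map CSV.
#' @param annotations Annotation tibble or path to an annotation CSV.
#' @param cal A [calibration()]; defaults to the map's calibration.
#' @param per_segment If given, sample this many waves per segment (seeded
#'   by `seed`); sampled rows are flagged in column `sampled` and the
#'   summary covers the sampled subset only.
#' @param seed Integer seed for the sampling draw.
#'
#' @return A list: `metrics` (per-annotation tibble, with `segment` and,
#'   when sampling, `sampled`), `summary` (per-metric medians and counts).
#' @export
run_metrics <- function(map, annotations, cal = NULL, per_segment = NULL,
                        seed = NULL) {
  if (!inherits(map, "myowave_st_map")) {
    map <- with_stage("load", read_st_map(map))
  }
  if (!is.data.frame(annotations)) {
    annotations <- with_stage("load", read_annotations(annotations))
  }
  cal <- cal %||% map$calibration
  n_col <- nrow(map$values)
  metrics <- with_stage("metrics",
                        compute_metrics(annotations, cal, n_columns = n_col))
  if (is.null(per_segment)) {
    return(list(metrics = metrics, summary = summarize_metrics(metrics)))
  }
  ann2 <- annotations
  ann2$segment <- metrics$segment
  ann2$.row <- seq_len(nrow(ann2))
  picked <- with_stage("metrics",
                       sample_waves(ann2, per_segment = per_segment, seed = seed))
  metrics$sampled <- seq_len(nrow(metrics)) %in% picked$.row
  list(
    metrics = metrics,
    summary = summarize_metrics(metrics[metrics$sampled, , drop = FALSE])
  )
}
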