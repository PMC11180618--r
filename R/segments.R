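#' Assign waves to horn thirds
#'
#' The horn's spatial axis (oviduct to cervix) is split into oviductal,
#' middle and cervical thirds with boundaries at `floor(n/3)` and
#' `floor(2n/3)` columns, each third a half-open interval, so the three
#' ranges partition `[0, n_columns)` exactly. A wave belongs to the third
#' containing its ridge midpoint column.
#'
#' @param midpoint Ridge midpoint column(s), 0-based, on the
#'   oviduct-to-cervix axis.
#' @param n_columns Number of spatial columns of the map (>= 3).
#'
#' @return A character vector: `"oviductal"`, `"middle"` or `"cervical"`.
#' @examples
#' assign_segment(c(0, 150, 299), 300)
#' @export
assign_segment <- function(midpoint, n_columns) {
  if (n_columns < 3) abort("`n_columns` must be >= 3.", class = "myowave_validation_error")
  if (any(midpoint < 0 | midpoint >= n_columns)) {
    abort("Ridge midpoint lies outside the map's columns.",
          class = "myowave_bounds_error")
  }
  b1 <- floor(n_columns / 3)
  b2 <- floor(2 * n_columns / 3)
  dplyr::case_when(
    midpoint < b1 ~ "oviductal",
    midpoint < b2 ~ "middle",
    TRUE ~ "cervical"
  )
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random per-segment wave sampling
#'
#' Draws a fixed number of annotated waves uniformly at random, without
#' replacement, from each of the three horn segments — the protocol of
#' analysing 3 randomly chosen waves per segment, 9 waves per horn.
#'
#' @param annotations Annotation tibble; a `segment` column is computed
#'   from the ridge midpoints when absent.
#' @param n_columns Map width in columns (needed when `segment` is absent).
#' @param per_segment Waves to draw from each segment. Default 3.
#' @param seed Integer seed making the draw reproducible.
#'
#' @return The sampled annotation rows (with their `segment`), ordered
#'   oviductal, middle, cervical.
#' @export
sample_waves <- function(annotations, n_columns = NULL, per_segment = 3, seed = NULL) {
  if (!("segment" %in% names(annotations))) {
    if (is.null(n_columns)) {
      abort("Provide `n_columns` to derive segments, or a `segment` column.",
            class = "myowave_validation_error")
    }
    mid <- (annotations$ridge_c0 + annotations$ridge_c1) / 2
    annotations$segment <- assign_segment(mid, n_columns)
  }
  segs <- c("oviductal", "middle", "cervical")
  counts <- table(factor(annotations$segment, levels = segs))
  short <- segs[counts < per_segment]
  if (length(short) > 0) {
    abort(sprintf("Segment(s) %s have fewer than %d annotated waves.",
                  paste(short, collapse = ", "), per_segment),
          class = "myowave_validation_error")
  }
  with_local_seed(seed, {
    picked <- lapply(segs, function(s) {
      rows <- which(annotations$segment == s)
      rows[sample.int(length(rows), per_segment)]
    })
    annotations[unlist(picked), , drop = FALSE]
  })
}
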