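#' Embryo positions along the uterine horn
#'
#' Arithmetic for localising pre-implantation embryos from 3D surface
#' centres: all distances use the orthogonal projection onto the XY plane
#' (the z coordinate is ignored) and are normalised by the horn length, so
#' positions are unitless fractions of the horn running from the
#' oviductal-uterine junction (0) toward the cervix (1). Horns with fewer
#' than three embryos are excluded from analysis and raise an error.
#'
#' @param points A data frame with columns `point_type` (`"ouj"` for the
#'   oviductal-uterine junction, `"embryo"` for embryo centres), `x`, `y`,
#'   `z`. Exactly one `ouj` row and at least three `embryo` rows.
#' @param horn_length Horn length in the same spatial units as the
#'   coordinates (positive).
#'
#' @return `normalized_positions()`: ascending numeric vector of
#'   junction-to-embryo (OE) distances divided by horn length.
#'   `ee_distances()`: distances between embryos adjacent in OE order,
#'   divided by horn length. `segment_percentages()`: tibble with the
#'   percentage of embryos in the oviductal, middle and cervical thirds.
#' @examples
#' pts <- tibble::tibble(
#'   point_type = c("ouj", "embryo", "embryo", "embryo"),
#'   x = c(0, 3, 6, 9), y = c(0, 4, 8, 12), z = c(5, 1, 2, 0)
#' )
#' normalized_positions(pts, horn_length = 20)
#' @name embryo_positions
NULL

check_horn_points <- function(points, horn_length) {
  check_columns(points, c("point_type", "x", "y", "z"), "Horn point")
  if (!is.numeric(horn_length) || length(horn_length) != 1 || !is.finite(horn_length) ||
      horn_length <= 0) {
    abort("`horn_length` must be a single positive number.",
          class = "myowave_validation_error")
  }
  if (any(!is.finite(c(points$x, points$y, points$z)))) {
    abort("Point coordinates must be finite.", class = "myowave_validation_error")
  }
  ouj <- points[points$point_type == "ouj", , drop = FALSE]
  emb <- points[points$point_type == "embryo", , drop = FALSE]
  if (nrow(ouj) != 1) {
    abort("Exactly one 'ouj' (oviductal-uterine junction) point is required.",
          class = "myowave_validation_error")
  }
  if (nrow(emb) < 3) {
    abort(sprintf("Horn excluded: %d embryo(s) found but at least 3 are required.",
                  nrow(emb)),
          class = "myowave_exclusion_error")
  }
  list(ouj = ouj, embryos = emb)
}

#' @rdname embryo_positions
#' @export
normalized_positions <- function(points, horn_length) {
  p <- check_horn_points(points, horn_length)
  oe <- sqrt((p$embryos$x - p$ouj$x)^2 + (p$embryos$y - p$ouj$y)^2) / horn_length
  sort(oe)
}

#' @rdname embryo_positions
#' @export
ee_distances <- function(points, horn_length) {
  p <- check_horn_points(points, horn_length)
  oe <- sqrt((p$embryos$x - p$ouj$x)^2 + (p$embryos$y - p$ouj$y)^2)
  ord <- order(oe)
  ex <- p$embryos$x[ord]; ey <- p$embryos$y[ord]
  sqrt(diff(ex)^2 + diff(ey)^2) / horn_length
}

#' @rdname embryo_positions
#' @param norm_positions Normalised OE positions, as from
#'   [normalized_positions()]. Values below 0 count toward the oviductal
#'   segment; values at or above 1 (XY projection can slightly exceed the
#'   measured horn path) count toward the cervical segment.
#' @export
segment_percentages <- function(norm_positions) {
  if (length(norm_positions) == 0) {
    abort("`norm_positions` must be non-empty.", class = "myowave_validation_error")
  }
  seg <- dplyr::case_when(
    norm_positions < 1 / 3 ~ "oviductal",
    norm_positions < 2 / 3 ~ "middle",
    TRUE ~ "cervical"
  )
  counts <- table(factor(seg, levels = c("oviductal", "middle", "cervical")))
  tibble(
    segment = names(counts),
    n = as.integer(counts),
    percent = 100 * as.integer(counts) / length(norm_positions)
  )
}

#' @rdname embryo_positions
#' @param path CSV file with columns `point_type, x, y, z`.
#' @export
read_horn_points <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("point_type", "x", "y", "z"), "Horn point")
  df
}
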