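#' Frame stacks
#'
#' A `frame_stack` holds an ordered grayscale video as a 3D numeric array
#' with dimensions `(height, width, n_frames)`, intensities on the 8-bit
#' scale `[0, 255]`, and the acquisition interval in seconds per frame.
#' Pixel coordinates are 0-based throughout the package: row 0 is the top
#' image row, column 0 the left image column, frame 0 the first frame, and
#' all index intervals are half-open `[start, end)`.
#'
#' @param frames Numeric array `(height, width, n_frames)` with values in
#'   `[0, 255]`.
#' @param frame_interval Seconds per frame (positive).
#'
#' @return A `frame_stack` object.
#' @examples
#' fs <- frame_stack(array(128, dim = c(8, 16, 3)), frame_interval = 0.2)
#' n_frames(fs)
#' @export
frame_stack <- function(frames, frame_interval) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    abort("`frames` must be a 3D array (height, width, n_frames).",
          class = "myowave_validation_error")
  }
  if (dim(frames)[3] < 2) {
    abort("A frame stack needs at least 2 frames.", class = "myowave_validation_error")
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    abort("`frame_interval` must be a single positive number (seconds/frame).",
          class = "myowave_validation_error")
  }
  rng <- range(frames, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 255) {
    abort("Frame intensities must lie within [0, 255].",
          class = "myowave_validation_error")
  }
  structure(
    list(frames = frames, frame_interval = as.numeric(frame_interval)),
    class = "myowave_frame_stack"
  )
}

#' @rdname frame_stack
#' @param x,stack A `frame_stack`.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' @rdname frame_stack
#' @export
stack_height <- function(stack) dim(stack$frames)[1]

#' @rdname frame_stack
#' @export
stack_width <- function(stack) dim(stack$frames)[2]

#' @export
print.myowave_frame_stack <- function(x, ...) {
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px, %.3g s/frame (%.1f s total)\n",
    n_frames(x), stack_height(x), stack_width(x),
    x$frame_interval, n_frames(x) * x$frame_interval
  ))
  invisible(x)
}

#' @method tidy myowave_frame_stack
#' @export
tidy.myowave_frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  tibble(
    frame = rep(seq_len(d[3]) - 1L, each = d[1] * d[2]),
    row = rep(rep(seq_len(d[1]) - 1L, times = d[2]), times = d[3]),
    column = rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
    intensity = as.vector(x$frames)
  )
}

# Rec.601 luma; warns (once per load) because channel mixing can distort a
# single-channel fluorescence signal
to_grayscale <- function(img, quiet = FALSE) {
  if (length(dim(img)) == 2) return(img)
  nc <- dim(img)[3]
  if (nc == 1) return(img[, , 1])
  if (!quiet) {
    warn("Color frames converted to luminance; single-channel input is preferred for fluorescence data.",
         class = "myowave_color_warning")
  }
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# snap values that are within rounding noise of an integer (PNG/TIFF store
# k/255 which is inexact in binary floating point)
snap_integers <- function(x, tol = 1e-9) {
  r <- round(x)
  hit <- abs(x - r) < tol
  x[hit] <- r[hit]
  x
}

read_one_frame <- function(path, quiet = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported frame format '.%s' in '%s'.", ext, basename(path)),
          class = "myowave_format_error")
  )
  snap_integers(to_grayscale(img, quiet = quiet) * 255)
}

#' Load a video as a frame stack
#'
#' Reads a lossless image-sequence directory (PNG or TIFF frames in
#' lexicographic order) into a [frame_stack()]. The frame interval is taken
#' from the directory's `stack.json` sidecar when present (as written by
#' [write_frames()]) and can be overridden with `expected_interval`.
#'
#' Compressed video containers (`.avi`, `.mp4`) cannot be decoded by this
#' package; convert them to a PNG frame sequence first (for example with
#' `ffmpeg -i in.avi frames/frame_%06d.png`) and load the directory.
#'
#' @param path Directory containing the frame images.
#' @param expected_interval Seconds per frame; overrides sidecar metadata.
#'
#' @return A [frame_stack()].
#' @export
load_frames <- function(path, expected_interval = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("avi", "mp4", "mov", "mkv")) {
    abort(
      sprintf(
        "No decoder is available for '.%s' containers; convert the video to a PNG/TIFF frame sequence and load the directory.",
        ext
      ),
      class = "myowave_decode_error"
    )
  }
  if (!dir.exists(path)) {
    abort(sprintf("'%s' is not a readable frame-sequence directory.", path),
          class = "myowave_decode_error")
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) {
    abort(sprintf("No PNG/TIFF frames found in '%s'.", path),
          class = "myowave_decode_error")
  }
  if (length(files) == 1) {
    abort("A video must contain at least 2 frames; found 1.",
          class = "myowave_decode_error")
  }
  first <- read_one_frame(files[1])
  d <- dim(first)
  frames <- array(NA_real_, dim = c(d[1], d[2], length(files)))
  frames[, , 1] <- first
  for (i in seq_along(files)[-1]) {
    f <- read_one_frame(files[i], quiet = TRUE)
    if (!identical(dim(f), d)) {
      abort(sprintf("Frame '%s' is %d x %d but earlier frames are %d x %d.",
                    basename(files[i]), dim(f)[1], dim(f)[2], d[1], d[2]),
            class = "myowave_format_error")
    }
    frames[, , i] <- f
  }
  interval <- expected_interval
  sidecar <- file.path(path, "stack.json")
  if (is.null(interval) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    interval <- meta$frame_interval
  }
  if (is.null(interval)) {
    abort("Frame interval unknown: no stack.json sidecar found; pass `expected_interval`.",
          class = "myowave_format_error")
  }
  frame_stack(frames, frame_interval = interval)
}

#' Write a frame stack as a lossless PNG sequence
#'
#' Writes one 8-bit grayscale PNG per frame plus a `stack.json` sidecar
#' holding the frame interval and dimensions, so that
#' `load_frames(write_frames(x))` round-trips exactly for integer-valued
#' stacks.
#'
#' @param stack A [frame_stack()].
#' @param path Output directory (created if missing).
#'
#' @return `path`, invisibly.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "myowave_frame_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nt <- n_frames(stack)
  for (i in seq_len(nt)) {
    png::writePNG(stack$frames[, , i] / 255,
                  target = file.path(path, sprintf("frame_%06d.png", i - 1L)))
  }
  jsonlite::write_json(
    list(
      frame_interval = stack$frame_interval,
      height = stack_height(stack), width = stack_width(stack), n_frames = nt
    ),
    file.path(path, "stack.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Crop a frame stack
#'
#' Restricts every frame to a rectangle given in 0-based, half-open pixel
#' intervals, mirroring the pre-analysis step of cropping a recording down
#' to a single organ.
#'
#' @param stack A [frame_stack()].
#' @param rows,cols Length-2 integer vectors `c(start, end)` with 0-based
#'   half-open bounds. The cropped height must be at least 2 rows (a
#'   single-row strip cannot contain both an upper and a lower boundary).
#'
#' @return A cropped [frame_stack()]; the frame interval is preserved.
#' @export
crop_frames <- function(stack, rows, cols) {
  stopifnot(inherits(stack, "myowave_frame_stack"))
  h <- stack_height(stack)
  w <- stack_width(stack)
  check_rect <- function(b, n, name) {
    if (length(b) != 2 || any(!is.finite(b)) || b[1] < 0 || b[2] > n || b[1] >= b[2]) {
      abort(sprintf("`%s` must be a non-empty half-open interval within [0, %d).", name, n),
            class = "myowave_bounds_error")
    }
  }
  check_rect(rows, h, "rows")
  check_rect(cols, w, "cols")
  if (rows[2] - rows[1] < 2) {
    abort("Cropped height must be at least 2 rows to contain two boundaries.",
          class = "myowave_bounds_error")
  }
  frame_stack(
    stack$frames[(rows[1] + 1):rows[2], (cols[1] + 1):cols[2], , drop = FALSE],
    frame_interval = stack$frame_interval
  )
}
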