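#' Single-channel microscopy raster with physical calibration
#'
#' A `MicroImage` bundles a 2D intensity matrix with the physical pixel
#' size and (for time-lapse data) the frame interval. Rows index y and
#' columns index x; intensities are non-negative reals (arbitrary units)
#' or integer camera counts.
#'
#' @param data Numeric matrix of intensities (non-negative).
#' @param pixel_size Physical pixel size in micrometres per pixel (> 0).
#' @param channel_name Optional channel label, e.g. `"paxillin"`.
#' @param frame_interval Optional frame interval in seconds (time-lapse).
#'
#' @return An object of class `MicroImage`.
#' @export
#' @examples
#' img <- micro_image(matrix(runif(64), 8, 8), pixel_size = 0.11)
#' pixel_area(img) # um^2 per pixel
micro_image <- function(data, pixel_size, channel_name = NULL,
                        frame_interval = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    fq_stop("'data' must be a numeric matrix", "validation_error")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    fq_stop("'pixel_size' must be a single positive number", "validation_error")
  }
  if (any(data < 0, na.rm = TRUE)) {
    fq_stop("intensities must be non-negative", "validation_error")
  }
  structure(
    list(data = data, pixel_size = as.numeric(pixel_size),
         channel_name = channel_name, frame_interval = frame_interval),
    class = "MicroImage"
  )
}

#' @export
print.MicroImage <- function(x, ...) {
  cat(sprintf(
    "MicroImage%s: %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
    if (is.null(x$channel_name)) "" else paste0(" '", x$channel_name, "'"),
    nrow(x$data), ncol(x$data), x$pixel_size,
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
as.matrix.MicroImage <- function(x, ...) x$data

#' @export
dim.MicroImage <- function(x) dim(x$data)

#' Physical area of one pixel
#'
#' @param x A [micro_image()] or [label_mask()].
#' @return Pixel area in square micrometres.
#' @export
pixel_area <- function(x) x$pixel_size^2

# Accept either a MicroImage or a bare matrix (with an explicit pixel size)
# at the entry of every image operation.
as_micro <- function(img, pixel_size = NULL) {
  if (inherits(img, "MicroImage")) return(img)
  if (is.matrix(img)) {
    if (is.null(pixel_size)) pixel_size <- 1
    return(micro_image(img, pixel_size))
  }
  fq_stop("expected a MicroImage or a numeric matrix", "validation_error")
}

#' Integer-labelled segmentation mask
#'
#' A `LabelMask` shares geometry with its source image. Label 0 is
#' background; object labels are the contiguous set `1..K`.
#'
#' @param labels Matrix of non-negative integers.
#' @param pixel_size Micrometres per pixel (> 0).
#'
#' @return An object of class `LabelMask`.
#' @export
label_mask <- function(labels, pixel_size) {
  if (!is.matrix(labels)) {
    fq_stop("'labels' must be a matrix", "validation_error")
  }
  labels <- structure(as.integer(round(labels)), dim = dim(labels))
  if (any(labels < 0L)) {
    fq_stop("labels must be non-negative", "validation_error")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    fq_stop("'pixel_size' must be positive", "validation_error")
  }
  structure(list(labels = labels, pixel_size = as.numeric(pixel_size)),
            class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  cat(sprintf("LabelMask: %d x %d px, %d object(s), %.4g um/px\n",
              nrow(x$labels), ncol(x$labels), n_objects(x), x$pixel_size))
  invisible(x)
}

#' @export
as.matrix.LabelMask <- function(x, ...) x$labels

#' Number of labelled objects in a mask
#' @param x A [label_mask()].
#' @return Integer count `K` (labels run `1..K`).
#' @export
n_objects <- function(x) {
  stopifnot(inherits(x, "LabelMask"))
  max(x$labels, 0L)
}

check_same_geometry <- function(a, b, what = "images") {
  da <- dim(as.matrix(a)); db <- dim(as.matrix(b))
  if (!identical(da, db)) {
    fq_stop(sprintf("%s have mismatched geometry (%dx%d vs %dx%d)",
                    what, da[1], da[2], db[1], db[2]),
            "validation_error")
  }
  invisible(TRUE)
}
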