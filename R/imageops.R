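#' Local background subtraction (white top-hat)
#'
#' Estimates the local background as a grayscale morphological opening
#' with a disc structuring element and subtracts it (a rolling-ball
#' equivalent). Structures smaller than the disc radius are preserved;
#' smooth background on scales larger than the radius is removed. Output
#' is clipped at zero.
#'
#' @param img A [micro_image()] (or matrix).
#' @param radius Disc radius in pixels (>= 1); choose it larger than the
#'   largest structure of interest.
#' @return A `MicroImage` with the background removed.
#' @export
subtract_background <- function(img, radius = 50) {
  img <- as_micro(img)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1) {
    fq_stop("'radius' must be >= 1", "validation_error")
  }
  radius <- as.integer(round(radius))
  if (2L * radius + 1L > min(dim(img$data))) {
    fq_stop("background radius exceeds the image extent", "validation_error")
  }
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  bg <- as.matrix(EBImage::opening(img$data, brush))
  out <- pmax(img$data - bg, 0)
  dim(out) <- dim(img$data)
  micro_image(out, img$pixel_size, img$channel_name, img$frame_interval)
}

# Reflect-pad a matrix by r rows/cols on every side.
reflect_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) fq_stop("pad radius exceeds image size", "validation_error")
  ri <- c(rev(seq_len(r) + 1L) , seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L) , seq_len(nc), nc - seq_len(r))
  m[ri, ci, drop = FALSE]
}

#' Median filter with reflective edge handling
#'
#' Replaces each pixel by the exact median of its `(2*radius+1)^2`
#' square neighbourhood. Edges are handled by mirror reflection, so the
#' output never contains values absent from the input neighbourhoods and
#' constant images are fixed points.
#'
#' The sliding windows are sorted by a vectorised exchange network, so
#' the result is the exact sample median (no histogram quantisation).
#'
#' @inheritParams subtract_background
#' @param radius Neighbourhood radius in pixels (>= 1).
#' @return A filtered `MicroImage`.
#' @export
median_filter <- function(img, radius = 1) {
  img <- as_micro(img)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1) {
    fq_stop("'radius' must be >= 1", "validation_error")
  }
  r <- as.integer(round(radius))
  m <- img$data
  nr <- nrow(m); nc <- ncol(m)
  pm <- reflect_pad(m, r)
  k <- (2L * r + 1L)^2L
  # columns of 'win' are the k shifted copies covering each window
  win <- matrix(0, nr * nc, k)
  j <- 1L
  for (dc in 0:(2L * r)) {
    for (dr in 0:(2L * r)) {
      win[, j] <- pm[dr + seq_len(nr), dc + seq_len(nc)]
      j <- j + 1L
    }
  }
  # odd-even transposition sort across the k columns (exact, vectorised)
  for (pass in seq_len(k)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    for (a in seq(start, k - 1L, by = 2L)) {
      lo <- pmin(win[, a], win[, a + 1L])
      hi <- pmax(win[, a], win[, a + 1L])
      win[, a] <- lo; win[, a + 1L] <- hi
    }
  }
  mid <- (k + 1L) %/% 2L   # k is odd
  out <- matrix(win[, mid], nr, nc)
  micro_image(out, img$pixel_size, img$channel_name, img$frame_interval)
}

# Otsu's criterion on a histogram of counts: returns the 0-based index t
# of the last bin of the background class, maximising the between-class
# variance; ties resolved to the lowest index.
otsu_from_histogram <- function(counts) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  nb <- length(counts)
  p <- counts / n
  omega <- cumsum(p)                    # class-0 mass up to bin t
  mu <- cumsum(p * (seq_len(nb) - 1L))  # first moment up to bin t
  mu_t <- mu[nb]
  # between-class variance for t = 0 .. nb-2 (both classes non-empty)
  t_idx <- seq_len(nb - 1L)
  w0 <- omega[t_idx]
  num <- (mu_t * w0 - mu[t_idx])^2
  den <- w0 * (1 - w0)
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  if (all(!is.finite(sigma_b))) {
    fq_stop("histogram has no contrast", "no_contrast_error")
  }
  which.max(sigma_b) - 1L
}

#' Otsu threshold of an image
#'
#' Computes the global threshold maximising the between-class variance of
#' the intensity histogram. Float images are binned into 256 equal-width
#' bins over `[min, max]` (matching 8-bit behaviour); 8-bit integer data
#' use the native 0..255 bins. Foreground is defined as pixels *strictly
#' above* the returned threshold, and the returned value is chosen so
#' that this rule reproduces the optimal histogram split exactly.
#'
#' @inheritParams subtract_background
#' @param levels Number of histogram bins for float data (default 256).
#' @return The threshold intensity (a single number).
#' @export
#' @examples
#' img <- micro_image(matrix(c(rep(10, 32), rep(200, 32)), 8, 8), 0.11)
#' otsu_threshold(img)
otsu_threshold <- function(img, levels = 256L) {
  img <- as_micro(img)
  x <- as.vector(img$data)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) {
    fq_stop("image is constant: Otsu threshold undefined", "no_contrast_error")
  }
  is_8bit <- is.integer(img$data) ||
    (all(x == round(x)) && lo >= 0 && hi <= 255)
  if (is_8bit) {
    bins <- as.integer(x)              # native 8-bit bins
    counts <- tabulate(bins + 1L, nbins = 256L)
    t_bin <- otsu_from_histogram(counts)
    return(max(x[bins <= t_bin]))
  }
  w <- (hi - lo) / levels
  bins <- pmin(floor((x - lo) / w), levels - 1L)
  counts <- tabulate(bins + 1L, nbins = levels)
  t_bin <- otsu_from_histogram(counts)
  # largest observed class-0 value: 'strictly above' then reproduces the
  # histogram partition exactly on this image
  max(x[bins <= t_bin])
}

#' Label connected components of a binary mask
#'
#' Labels maximal connected foreground components `1..K` under
#' 4- or 8-connectivity. Labels are assigned in raster (column-major)
#' order of each component's first pixel, so the labelling is independent
#' of how the mask was produced.
#'
#' @param mask Logical/0-1 matrix (or `MicroImage` of 0/1).
#' @param connectivity 4 or 8 (default 8, the particle-analysis default in
#'   ImageJ).
#' @param pixel_size Micrometres per pixel for the returned mask.
#' @return A [label_mask()].
#' @export
label_connected <- function(mask, connectivity = 8, pixel_size = 1) {
  if (inherits(mask, "MicroImage")) {
    pixel_size <- mask$pixel_size
    mask <- mask$data
  }
  if (!is.matrix(mask)) fq_stop("'mask' must be a matrix", "validation_error")
  if (!all(mask %in% c(0, 1, TRUE, FALSE))) {
    fq_stop("'mask' must be binary", "validation_error")
  }
  if (!connectivity %in% c(4, 8)) {
    fq_stop("'connectivity' must be 4 or 8", "validation_error")
  }
  bin <- matrix(as.numeric(as.logical(mask)), nrow(mask), ncol(mask))
  lab <- as.matrix(EBImage::bwlabel(bin))   # 4-connected components
  storage.mode(lab) <- "integer"
  k4 <- max(lab, 0L)
  if (connectivity == 8 && k4 > 1L) {
    lab <- merge_diagonal_labels(lab, k4)
  }
  lab <- relabel_raster_order(lab)
  label_mask(lab, pixel_size)
}

# Union-find merge of 4-connected labels that touch diagonally,
# upgrading a 4-connected labelling to 8-connectivity.
merge_diagonal_labels <- function(lab, k) {
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2],
                 , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  out <- lab
  nz <- lab > 0L
  out[nz] <- root[lab[nz]]
  out
}

# Relabel to contiguous 1..K in column-major order of first appearance.
relabel_raster_order <- function(lab) {
  nz <- which(lab > 0L)
  if (!length(nz)) return(lab)
  first_seen <- unique(lab[nz])
  map <- integer(max(first_seen))
  map[first_seen] <- seq_along(first_seen)
  lab[nz] <- map[lab[nz]]
  lab
}
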