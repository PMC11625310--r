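#' Extract an averaged line-scan intensity profile
#'
#' Samples each channel by bilinear interpolation at unit-pixel spacing
#' along the segment `p0 -> p1`, averaging `width` parallel lines offset
#' perpendicular to the scan at unit spacing (width must be odd). This
#' is the cross-adhesion line scan used to compare the placement of two
#' markers across a focal adhesion.
#'
#' @param channels Named list of [micro_image()]s (or a single one).
#' @param p0,p1 Endpoints as `(row, col)` pixel coordinates (may be
#'   fractional, 1-based).
#' @param width Number of averaged parallel lines (odd, >= 1).
#' @return A `LineProfile`: list with `positions` (um along the scan,
#'   strictly increasing from 0), `intensities` (matrix, one column per
#'   channel), `normalized = FALSE`, `pixel_size`.
#' @export
extract_line_profile <- function(channels, p0, p1, width = 1L) {
  if (inherits(channels, "MicroImage")) channels <- list(intensity = channels)
  if (!length(channels)) fq_stop("no channels supplied", "validation_error")
  channels <- lapply(channels, as_micro)
  if (width < 1 || width %% 2 == 0) {
    fq_stop("'width' must be odd and >= 1", "validation_error")
  }
  d <- dim(channels[[1]]$data)
  for (ch in channels) check_same_geometry(ch, channels[[1]], "channels")
  inside <- function(p) p[1] >= 1 && p[1] <= d[1] && p[2] >= 1 && p[2] <= d[2]
  if (!inside(p0) || !inside(p1)) {
    fq_stop("line endpoints must lie inside the image", "validation_error")
  }
  v <- c(p1[1] - p0[1], p1[2] - p0[2])
  len <- sqrt(sum(v^2))
  if (len == 0) fq_stop("endpoints coincide", "validation_error")
  u <- v / len
  perp <- c(-u[2], u[1])
  n <- floor(len) + 1L
  t <- seq_len(n) - 1L
  offsets <- seq_len(width) - (width + 1) / 2
  rows <- outer(p0[1] + t * u[1], offsets * perp[1], `+`)
  cols <- outer(p0[2] + t * u[2], offsets * perp[2], `+`)
  if (any(rows < 1 | rows > d[1] | cols < 1 | cols > d[2])) {
    fq_stop("offset lines leave the image; reduce width or move endpoints",
            "validation_error")
  }
  inten <- vapply(channels, function(ch) {
    rowMeans(matrix(bilinear_at(ch$data, rows, cols), nrow = n))
  }, numeric(n))
  inten <- matrix(inten, nrow = n,
                  dimnames = list(NULL, names(channels)))
  structure(list(positions = t * channels[[1]]$pixel_size,
                 intensities = inten, normalized = FALSE,
                 pixel_size = channels[[1]]$pixel_size),
            class = "LineProfile")
}

# Vectorised bilinear interpolation at fractional (row, col) positions.
bilinear_at <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(rows), 1), nr - 1L)
  c0 <- pmin(pmax(floor(cols), 1), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- (c0 - 1) * nr + r0
  m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1L] * fr * (1 - fc) +
    m[i00 + nr] * (1 - fr) * fc + m[i00 + nr + 1L] * fr * fc
}

#' Min-max normalize a line profile
#'
#' Maps each channel independently to `(i - min) / (max - min)`, so
#' every normalized channel spans exactly \[0, 1\]. Idempotent. A
#' constant channel has no dynamic range and raises a
#' `degenerate_profile_error`.
#'
#' @param profile A [extract_line_profile()] result.
#' @return The profile with normalized intensities and
#'   `normalized = TRUE`.
#' @export
#' @examples
#' pr <- structure(list(positions = 0:2, normalized = FALSE,
#'                      intensities = cbind(ch = c(2, 5, 10))),
#'                 class = "LineProfile")
#' normalize_profile(pr)$intensities # 0, 0.375, 1
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "LineProfile"))
  inten <- profile$intensities
  for (j in seq_len(ncol(inten))) {
    lo <- min(inten[, j]); hi <- max(inten[, j])
    if (hi <= lo) {
      fq_stop(sprintf("channel %d is constant: cannot min-max normalize", j),
              "degenerate_profile_error")
    }
    inten[, j] <- (inten[, j] - lo) / (hi - lo)
  }
  profile$intensities <- inten
  profile$normalized <- TRUE
  profile
}

#' Align profiles on a reference peak and average
#'
#' Shifts each normalized profile so that the reference channel's
#' maximum sits at position 0 (the convention that places other markers
#' relative to the reference marker's peak within the adhesion),
#' resamples all profiles onto a common grid (step = one
#' pixel-equivalent), and returns the pointwise mean and SD per channel.
#' Grid points outside a profile's support are ignored for that
#' profile.
#'
#' @param profiles List of normalized `LineProfile`s sharing channel
#'   names.
#' @param reference_channel Channel whose peak defines position 0.
#' @return List with `positions`, `mean`, `sd` (matrices, one column per
#'   channel), and `n` (profiles contributing per grid point).
#' @export
align_and_average <- function(profiles, reference_channel) {
  if (!length(profiles)) fq_stop("need at least one profile", "validation_error")
  chs <- colnames(profiles[[1]]$intensities)
  if (!reference_channel %in% chs) {
    fq_stop("reference channel absent from profiles", "validation_error")
  }
  for (pr in profiles) {
    if (!isTRUE(pr$normalized)) {
      fq_stop("profiles must be normalized before alignment", "validation_error")
    }
    if (!identical(colnames(pr$intensities), chs)) {
      fq_stop("profiles have mismatched channels", "validation_error")
    }
  }
  step <- median(diff(profiles[[1]]$positions))
  shifted <- lapply(profiles, function(pr) {
    peak <- pr$positions[which.max(pr$intensities[, reference_channel])]
    list(pos = pr$positions - peak, inten = pr$intensities)
  })
  lo <- min(vapply(shifted, function(s) min(s$pos), numeric(1)))
  hi <- max(vapply(shifted, function(s) max(s$pos), numeric(1)))
  grid <- seq(floor(lo / step), ceiling(hi / step)) * step
  acc_n <- matrix(0L, length(grid), length(chs))
  acc_s <- matrix(0, length(grid), length(chs))
  acc_ss <- matrix(0, length(grid), length(chs))
  for (s in shifted) {
    ok <- grid >= min(s$pos) - 1e-9 & grid <= max(s$pos) + 1e-9
    for (j in seq_along(chs)) {
      yi <- stats::approx(s$pos, s$inten[, j], xout = grid[ok], rule = 1)$y
      acc_n[ok, j] <- acc_n[ok, j] + 1L
      acc_s[ok, j] <- acc_s[ok, j] + yi
      acc_ss[ok, j] <- acc_ss[ok, j] + yi^2
    }
  }
  mu <- ifelse(acc_n > 0, acc_s / acc_n, NA_real_)
  vr <- ifelse(acc_n > 1, pmax(acc_ss - acc_n * mu^2, 0) / (acc_n - 1L), 0)
  vr[acc_n == 0] <- NA_real_
  colnames(mu) <- colnames(vr) <- chs
  list(positions = grid, mean = mu, sd = sqrt(vr), n = acc_n[, 1])
}

#' LOESS smoothing of a profile or scatter
#'
#' Locally estimated scatterplot smoothing with tricube weights and a
#' local quadratic fit (degree 2), evaluated at the input abscissae —
#' the standard smoother for averaged line-scan curves.
#'
#' @param x,y Numeric vectors (>= 5 points).
#' @param span Smoothing span in (0, 1\] (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @return Numeric vector of smoothed values at `x`.
#' @export
loess_smooth <- function(x, y, span = 0.75, degree = 2) {
  if (length(x) != length(y) || length(x) < 5) {
    fq_stop("need >= 5 (x, y) points", "validation_error")
  }
  if (span <= 0 || span > 1) fq_stop("span must lie in (0, 1]", "validation_error")
  fit <- stats::loess(y ~ x, data = data.frame(x = x, y = y),
                      span = span, degree = degree, family = "gaussian",
                      surface = "direct")
  as.numeric(predict(fit, newdata = data.frame(x = x)))
}
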