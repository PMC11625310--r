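test_that("line profiles sample by bilinear interpolation with width averaging", {
  ramp <- micro_image(matrix(rep(0:9, each = 10), 10, 10), 1)
  pr <- extract_line_profile(ramp, p0 = c(5, 1), p1 = c(5, 10), width = 1)
  expect_equal(as.vector(pr$intensities), 0:9)
  expect_equal(pr$positions, 0:9)

  # width 3 over a field constant along the perpendicular: identical
  pr3 <- extract_line_profile(ramp, c(5, 1), c(5, 10), width = 3)
  expect_equal(pr3$intensities, pr$intensities)

  # width 3 over a 2D ramp equals the hand-computed mean of the three
  # offset scans (explicit interpolation oracle)
  m <- outer(1:12, 1:12, function(r, c) 0.3 * r + 0.7 * c)
  img <- micro_image(m, 1)
  prw <- extract_line_profile(img, c(6, 2), c(6, 11), width = 3)
  oracle <- sapply(0:9, function(t) {
    mean(sapply(c(-1, 0, 1), function(o) 0.3 * (6 + o) + 0.7 * (2 + t)))
  })
  expect_equal(as.vector(prw$intensities), oracle, tolerance = 1e-12)

  expect_error(extract_line_profile(ramp, c(0, 1), c(5, 10)),
               class = "validation_error")
  expect_error(extract_line_profile(ramp, c(5, 1), c(5, 10), width = 2),
               class = "validation_error")
})

test_that("min-max normalization is exact and idempotent", {
  pr <- structure(list(positions = c(0, 1, 2), normalized = FALSE,
                       intensities = cbind(ch = c(2, 5, 10))),
                  class = "LineProfile")
  np <- normalize_profile(pr)
  expect_equal(as.vector(np$intensities), c(0, 0.375, 1))
  expect_identical(normalize_profile(np)$intensities, np$intensities)
  expect_true(np$normalized)

  set.seed(1)
  pr2 <- structure(list(positions = 0:19, normalized = FALSE,
                        intensities = cbind(a = runif(20), b = rnorm(20))),
                   class = "LineProfile")
  np2 <- normalize_profile(pr2)
  expect_equal(apply(np2$intensities, 2, min), c(a = 0, b = 0))
  expect_equal(apply(np2$intensities, 2, max), c(a = 1, b = 1))

  const <- structure(list(positions = 0:2, normalized = FALSE,
                          intensities = cbind(ch = c(3, 3, 3))),
                     class = "LineProfile")
  expect_error(normalize_profile(const), class = "degenerate_profile_error")
})

test_that("alignment centres the reference peak and averages correctly", {
  gauss_profile <- function(shift, n = 41) {
    x <- seq_len(n) - 1
    ref <- exp(-(x - 20 - shift)^2 / 18)
    oth <- exp(-(x - 23 - shift)^2 / 30)
    structure(list(positions = as.numeric(x),
                   intensities = cbind(paxillin = ref, septin = oth),
                   normalized = FALSE, pixel_size = 1),
              class = "LineProfile")
  }
  p1 <- normalize_profile(gauss_profile(0))
  avg1 <- align_and_average(list(p1, p1), "paxillin")
  i0 <- which(avg1$positions == 0)
  expect_equal(avg1$mean[, "paxillin"], p1$intensities[, "paxillin"],
               ignore_attr = TRUE)
  expect_true(all(avg1$sd == 0, na.rm = TRUE))

  # profiles identical up to integer shift: SD ~ 0 after alignment
  # (window truncation makes the normalised tails differ at ~1e-7)
  shifts <- c(-4, 0, 3, 6)
  prs <- lapply(shifts, function(s) normalize_profile(gauss_profile(s)))
  avg <- align_and_average(prs, "paxillin")
  common <- avg$n == length(shifts)
  expect_true(any(common))
  expect_true(all(avg$sd[common, ] < 1e-6))
  # reference peak at position 0 (within one grid step)
  peak_pos <- avg$positions[which.max(avg$mean[common, "paxillin"]) +
                              which(common)[1] - 1]
  expect_lte(abs(peak_pos), 1)
  # averaging preserves [0, 1]
  expect_true(all(avg$mean >= 0 & avg$mean <= 1, na.rm = TRUE))

  expect_error(align_and_average(prs, "actin"), class = "validation_error")
  expect_error(align_and_average(list(gauss_profile(0)), "paxillin"),
               class = "validation_error")   # unnormalized input
})

test_that("LOESS reproduces polynomials and beats noise on a sine", {
  x <- seq(0, 10, length.out = 60)
  y_lin <- 2 * x - 3
  expect_equal(loess_smooth(x, y_lin, span = 0.5), y_lin, tolerance = 1e-8)
  expect_equal(loess_smooth(x, rep(2, 60)), rep(2, 60), tolerance = 1e-8)

  set.seed(8)
  xs <- seq(0, 2 * pi, length.out = 200)
  sigma <- 0.3
  noisy <- sin(xs) + rnorm(200, 0, sigma)
  sm <- loess_smooth(xs, noisy, span = 0.3)
  rmse <- sqrt(mean((sm - sin(xs))^2))
  expect_lt(rmse, sigma)

  expect_error(loess_smooth(1:4, 1:4), class = "validation_error")
  expect_error(loess_smooth(x, y_lin, span = 1.2), class = "validation_error")
})
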