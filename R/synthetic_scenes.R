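#' Parameters for a synthetic focal-adhesion scene
#'
#' Describes a TIRF-like two-channel scene: elongated elliptical
#' adhesions placed in an inner (perinuclear) and an outer (peripheral)
#' cell compartment, with a tunable shared-signal component between the
#' two channels that sets the true per-object Pearson correlation.
#'
#' Objects are rendered as plateau ellipses with a short anti-aliased
#' rim (peak-normalised to 1); the second channel within each object is
#' built as `rho * z(A) + sqrt(1-rho^2) * eps` on the standardised first
#' channel, so the expected pixel-wise Pearson r inside the object
#' equals `rho` for any signal-to-noise ratio. Setting `inner_offset_um`
#' > 0 switches inner objects to a spatial-displacement construction
#' (the second-channel ellipse is shifted towards the cell centre) and
#' their true correlation is recorded as `NA`.
#'
#' @param image_shape Integer (rows, cols) in pixels.
#' @param pixel_size Micrometres per pixel (default 0.11, a 100x
#'   TIRF-like sampling).
#' @param n_objects_inner,n_objects_outer Object counts per compartment.
#' @param area_range True object areas, uniform in this range (um^2).
#' @param axis_ratio_range Major/minor axis ratio range (dimensionless).
#' @param rho_inner,rho_outer Target per-object Pearson correlation in
#'   \[-1, 1\].
#' @param snr Peak signal over noise sigma (> 0).
#' @param background_level Constant background intensity.
#' @param inner_offset_um Spatial displacement of the inner-object
#'   second-channel signal (um); 0 uses the correlation construction.
#' @param edge_softness Fraction of the squared elliptical radius over
#'   which the plateau ramps to zero (anti-aliasing rim).
#' @param poisson If `TRUE`, shot noise is applied (at `photons` per
#'   intensity unit) in addition to Gaussian read noise.
#' @param photons Photon scale for the Poisson option.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   scenes.
#' @return A `SceneParams` list.
#' @export
scene_params <- function(image_shape = c(512L, 512L),
                         pixel_size = 0.11,
                         n_objects_inner = 6L,
                         n_objects_outer = 6L,
                         area_range = c(0.5, 4),
                         axis_ratio_range = c(1.5, 3.5),
                         rho_inner = 0.2,
                         rho_outer = 0.7,
                         snr = 10,
                         background_level = 0.2,
                         inner_offset_um = 0,
                         edge_softness = 0.2,
                         poisson = FALSE,
                         photons = 100,
                         seed = 1L) {
  p <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
            n_objects_inner = as.integer(n_objects_inner),
            n_objects_outer = as.integer(n_objects_outer),
            area_range = area_range, axis_ratio_range = axis_ratio_range,
            rho_inner = rho_inner, rho_outer = rho_outer, snr = snr,
            background_level = background_level,
            inner_offset_um = inner_offset_um,
            edge_softness = edge_softness,
            poisson = poisson, photons = photons, seed = as.integer(seed))
  validate_scene_params(p)
  structure(p, class = "SceneParams")
}

validate_scene_params <- function(p) {
  if (length(p$image_shape) != 2L || any(p$image_shape < 16L)) {
    fq_stop("image_shape must be two integers >= 16", "validation_error")
  }
  if (p$pixel_size <= 0) fq_stop("pixel_size must be > 0", "validation_error")
  if (abs(p$rho_inner) > 1 || abs(p$rho_outer) > 1) {
    fq_stop("rho values must lie in [-1, 1]", "validation_error")
  }
  if (p$snr <= 0) fq_stop("snr must be > 0", "validation_error")
  if (p$area_range[1] >= p$area_range[2]) {
    fq_stop("area_range must satisfy min < max", "validation_error")
  }
  if (p$axis_ratio_range[1] < 1) {
    fq_stop("axis ratios must be >= 1", "validation_error")
  }
  invisible(p)
}

# Pixels of an ellipse (centre in fractional pixel coords, semi-axes in
# px, orientation theta). Returns linear indices and the squared
# normalised elliptical radius d2 <= 1 of each pixel.
ellipse_pixels <- function(center, a, b, theta, nr, nc) {
  ext <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(center[1] - ext)):min(nr, ceiling(center[1] + ext))
  cols <- max(1L, floor(center[2] - ext)):min(nc, ceiling(center[2] + ext))
  dy <- rows - center[1]
  dx <- cols - center[2]
  ct <- cos(theta); st <- sin(theta)
  u <- (outer(dy, dx, function(y, x) x * ct + y * st)) / a
  v <- (outer(dy, dx, function(y, x) -x * st + y * ct)) / b
  d2 <- u^2 + v^2
  keep <- which(d2 <= 1)
  ri <- rows[(keep - 1L) %% length(rows) + 1L]
  ci <- cols[(keep - 1L) %/% length(rows) + 1L]
  list(idx = (ci - 1L) * nr + ri, d2 = d2[keep])
}

# Plateau profile with an anti-aliased rim: 1 on most of the ellipse,
# linear roll-off over the last 'soft' fraction of the squared radius.
plateau_profile <- function(d2, soft) {
  pmin(1, pmax(0, (1 - d2) / soft))
}

# Elliptical cell mask covering most of the frame.
default_cell_mask <- function(nr, nc) {
  dy <- (seq_len(nr) - (nr + 1) / 2) / (0.46 * nr)
  dx <- (seq_len(nc) - (nc + 1) / 2) / (0.46 * nc)
  outer(dy, dx, function(y, x) x^2 + y^2) <= 1
}

#' Generate a two-channel focal-adhesion scene with ground truth
#'
#' Places non-overlapping elliptical objects inside the inner and outer
#' compartments of a synthetic cell, renders the first channel
#' ("paxillin"), constructs the second channel ("septin") at the target
#' per-object correlation (see [scene_params()]), adds background and
#' Gaussian noise, and returns the images together with the full ground
#' truth: a label mask, the compartment masks, and per-object true
#' correlation and area.
#'
#' @param params A [scene_params()] object.
#' @return A `SyntheticScene`: list with `channels` (named
#'   [micro_image()]s `paxillin` and `septin`), `truth_labels`
#'   ([label_mask()]), `truth_regions` (`cell`, `inner`, `outer` logical
#'   masks), and `truth` (data frame: `label`, `region`, `rho`,
#'   `area_px`, `area_um2`, `centroid_row`, `centroid_col`).
#' @export
#' @examples
#' sc <- generate_fa_scene(scene_params(image_shape = c(128, 128),
#'                                      n_objects_inner = 2, n_objects_outer = 2))
#' sc$truth
generate_fa_scene <- function(params) {
  p <- validate_scene_params(params)
  set.seed(p$seed)
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  ps <- p$pixel_size
  cell <- default_cell_mask(nr, nc)
  part <- partition_regions(cell, fraction = 0.5)
  region_masks <- list(inner = part$inner_mask, outer = part$outer_mask)

  occupied <- matrix(FALSE, nr, nc)
  sigA <- matrix(0, nr, nc)
  sigB_offset <- matrix(0, nr, nc)
  truth <- list()
  obj_px <- list()
  labels <- matrix(0L, nr, nc)

  spec <- rbind(
    data.frame(region = rep("inner", p$n_objects_inner), rho = p$rho_inner),
    data.frame(region = rep("outer", p$n_objects_outer), rho = p$rho_outer)
  )
  n_obj <- nrow(spec)
  offset_px <- p$inner_offset_um / ps
  center_rc <- c((nr + 1) / 2, (nc + 1) / 2)

  for (i in seq_len(n_obj)) {
    rmask <- region_masks[[spec$region[i]]]
    cand <- which(rmask)
    placed <- FALSE
    for (attempt in seq_len(10000L)) {
      area_um2 <- runif(1, p$area_range[1], p$area_range[2])
      area_px <- area_um2 / ps^2
      q <- runif(1, p$axis_ratio_range[1], p$axis_ratio_range[2])
      b <- sqrt(area_px / (pi * q)); a <- q * b
      theta <- runif(1, 0, pi)
      ctr_lin <- cand[sample.int(length(cand), 1L)]
      ctr <- c((ctr_lin - 1L) %% nr + 1L, (ctr_lin - 1L) %/% nr + 1L)
      ep <- ellipse_pixels(ctr, a, b, theta, nr, nc)
      # margin ellipse keeps objects separated by >= ~2 px
      em <- ellipse_pixels(ctr, a + 2, b + 2, theta, nr, nc)
      if (!all(rmask[ep$idx]) || any(occupied[em$idx])) next
      if (length(ep$idx) < 5L) next
      occupied[em$idx] <- TRUE
      # ground-truth footprint = half-maximum support of the profile
      prof <- plateau_profile(ep$d2, p$edge_softness)
      core <- ep$idx[prof >= 0.5]
      if (length(core) < 5L) next
      labels[core] <- i
      sigA[ep$idx] <- pmax(sigA[ep$idx], prof)
      use_offset <- spec$region[i] == "inner" && offset_px > 0
      if (use_offset) {
        # displace the second-channel ellipse towards the cell centre
        dirv <- center_rc - ctr
        dirv <- dirv / max(sqrt(sum(dirv^2)), 1e-9)
        ctr2 <- ctr + dirv * offset_px
        ep2 <- ellipse_pixels(ctr2, a, b, theta, nr, nc)
        sigB_offset[ep2$idx] <- pmax(sigB_offset[ep2$idx],
                                     plateau_profile(ep2$d2, p$edge_softness))
      }
      obj_px[[i]] <- list(support = ep$idx, core = core)
      truth[[i]] <- data.frame(
        label = i, region = spec$region[i],
        rho = if (use_offset) NA_real_ else spec$rho[i],
        area_px = length(core), area_um2 = length(core) * ps^2,
        centroid_row = mean((core - 1L) %% nr + 1L),
        centroid_col = mean((core - 1L) %/% nr + 1L)
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      fq_stop(sprintf(
        "could not place object %d after 10000 attempts (scene at capacity)", i),
        "capacity_error")
    }
  }

  sigma_n <- 1 / p$snr
  chA <- sigA + p$background_level + rnorm(nr * nc, 0, sigma_n)
  if (p$poisson) {
    chA <- rpois(nr * nc, pmax(chA, 0) * p$photons) / p$photons
  }
  chA <- matrix(pmax(chA, 0), nr, nc)

  chB <- sigB_offset + p$background_level + rnorm(nr * nc, 0, sigma_n)
  chB <- matrix(chB, nr, nc)
  # Shared-signal construction: B = rho * z(A) + sqrt(1-rho^2) * eps on the
  # standardized (noisy) A, so the expected per-object Pearson r equals rho
  # at any snr. Applied over the rendered support for appearance, then
  # re-applied on the ground-truth footprint with its own standardization,
  # which is the pixel set the correlation is measured on.
  correlate_px <- function(img_b, px, rho) {
    av <- chA[px]
    sA <- sd(av)
    if (!is.finite(sA) || sA == 0) return(img_b)
    z <- (av - mean(av)) / sA
    w <- rho * z + sqrt(1 - rho^2) * rnorm(length(px))
    img_b[px] <- mean(av) + sA * w
    img_b
  }
  for (i in seq_len(n_obj)) {
    rho <- truth[[i]]$rho
    if (is.na(rho)) next
    chB <- correlate_px(chB, obj_px[[i]]$support, rho)
    chB <- correlate_px(chB, obj_px[[i]]$core, rho)
  }
  chB <- pmax(chB, 0)
  dim(chB) <- c(nr, nc)

  truth <- do.call(rbind, truth)
  structure(list(
    channels = list(
      paxillin = micro_image(chA, ps, "paxillin"),
      septin   = micro_image(chB, ps, "septin")
    ),
    truth_labels = label_mask(labels, ps),
    truth_regions = list(cell = cell, inner = part$inner_mask,
                         outer = part$outer_mask),
    truth = truth,
    params = p
  ), class = "SyntheticScene")
}

#' @export
print.SyntheticScene <- function(x, ...) {
  cat(sprintf("SyntheticScene: %d x %d px, %d object(s), channels: %s\n",
              nrow(x$channels[[1]]$data), ncol(x$channels[[1]]$data),
              nrow(x$truth), paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Parameters for a synthetic time-lapse
#'
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame interval in seconds (> 0); the default 10 s matches
#'   live TIRF acquisition cadences of 10-30 s.
#' @param image_shape,pixel_size,snr,background_level As in
#'   [scene_params()].
#' @param spot_sigma_um Gaussian sigma of the rendered spots (um).
#' @param seed RNG seed.
#' @return A `TimelapseParams` list.
#' @export
timelapse_params <- function(n_frames = 120L, dt = 10,
                             image_shape = c(128L, 128L), pixel_size = 0.11,
                             snr = 10, background_level = 0.2,
                             spot_sigma_um = 0.33, seed = 1L) {
  if (dt <= 0) fq_stop("dt must be > 0", "validation_error")
  if (n_frames < 2L) fq_stop("need at least 2 frames", "validation_error")
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, snr = snr,
                 background_level = background_level,
                 spot_sigma_um = spot_sigma_um, seed = as.integer(seed)),
            class = "TimelapseParams")
}

#' Generate a time-lapse with known object lifetimes
#'
#' Renders Gaussian spots that exist exactly from `appear` to
#' `disappear` (1-based frame indices, inclusive), on a noisy
#' background. The ground truth records, per object, the first and last
#' frame, the censoring flags (an event touching the first or last frame
#' of the movie only bounds the true lifetime from below), and the
#' lifetime under the frames-present convention
#' `lifetime = n_frames_present * dt`.
#'
#' @param params A [timelapse_params()] object.
#' @param events_spec Data frame with columns `appear`, `disappear`
#'   (frames, 1-based) and `row`, `col` (spot centre, pixels). May have
#'   zero rows (pure background movie).
#' @param seed Optional override of `params$seed`.
#' @return A `SyntheticTimelapse`: list with `stack` (rows x cols x
#'   frames array), `dt`, `pixel_size`, `truth_events` (data frame:
#'   `id`, `first_frame`, `last_frame`, `censored_start`,
#'   `censored_end`, `lifetime_s`), `truth_presence` (objects x frames
#'   logical matrix).
#' @export
generate_timelapse <- function(params, events_spec, seed = params$seed) {
  p <- params
  ev <- events_spec
  if (is.null(ev)) ev <- data.frame(appear = integer(), disappear = integer(),
                                    row = numeric(), col = numeric())
  if (nrow(ev) > 0) {
    if (any(ev$appear < 1L | ev$disappear > p$n_frames |
            ev$appear > ev$disappear)) {
      fq_stop("event frames outside stack range", "validation_error")
    }
  }
  set.seed(seed)
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  sigma_n <- 1 / p$snr
  spot_sigma_px <- p$spot_sigma_um / p$pixel_size
  stack <- array(0, dim = c(nr, nc, p$n_frames))
  presence <- matrix(FALSE, nrow(ev), p$n_frames)
  spots <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    ext <- ceiling(3 * spot_sigma_px)
    rows <- max(1L, floor(ev$row[i] - ext)):min(nr, ceiling(ev$row[i] + ext))
    cols <- max(1L, floor(ev$col[i] - ext)):min(nc, ceiling(ev$col[i] + ext))
    g <- outer(exp(-(rows - ev$row[i])^2 / (2 * spot_sigma_px^2)),
               exp(-(cols - ev$col[i])^2 / (2 * spot_sigma_px^2)))
    spots[[i]] <- list(rows = rows, cols = cols, g = g)
    presence[i, ev$appear[i]:ev$disappear[i]] <- TRUE
  }
  for (t in seq_len(p$n_frames)) {
    fr <- matrix(p$background_level + rnorm(nr * nc, 0, sigma_n), nr, nc)
    for (i in which(presence[, t])) {
      s <- spots[[i]]
      fr[s$rows, s$cols] <- fr[s$rows, s$cols] + s$g
    }
    stack[, , t] <- pmax(fr, 0)
  }
  truth_events <- if (nrow(ev)) data.frame(
    id = seq_len(nrow(ev)),
    first_frame = ev$appear, last_frame = ev$disappear,
    censored_start = ev$appear == 1L,
    censored_end = ev$disappear == p$n_frames,
    lifetime_s = (ev$disappear - ev$appear + 1L) * p$dt
  ) else data.frame(id = integer(), first_frame = integer(),
                    last_frame = integer(), censored_start = logical(),
                    censored_end = logical(), lifetime_s = numeric())
  structure(list(stack = stack, dt = p$dt, pixel_size = p$pixel_size,
                 truth_events = truth_events, truth_presence = presence,
                 params = p),
            class = "SyntheticTimelapse")
}

#' Generate a fibronectin-clearance scene with ground truth
#'
#' A wide-field-like scene: a bright fibronectin channel with dark
#' "holes" of exactly specified pixel areas (regions cleared by cells),
#' and a nuclei-like marker channel holding a countable number of cell
#' blobs. Hole areas are exact by construction (each hole is the set of
#' the N pixels of a disc closest to its centre).
#'
#' @param hole_areas_px Integer vector: pixel area of each hole.
#' @param n_cells Number of cell blobs (>= 1).
#' @param image_shape Pixels (rows, cols).
#' @param pixel_size Micrometres per pixel (default 0.325, a 20x
#'   wide-field sampling).
#' @param snr Peak/noise ratio; `Inf` gives a noise-free binary scene.
#' @param seed RNG seed.
#' @return A `SyntheticScene`-like list with channels `fibronectin` and
#'   `nuclei`, plus `truth` (`hole_area_px`, `hole_area_um2`, `n_cells`,
#'   `clearance_per_cell_um2`).
#' @export
generate_clearance_scene <- function(hole_areas_px, n_cells,
                                     image_shape = c(512L, 512L),
                                     pixel_size = 0.325, snr = Inf,
                                     seed = 1L) {
  if (n_cells < 1L) fq_stop("n_cells must be >= 1", "validation_error")
  nr <- image_shape[1]; nc <- image_shape[2]
  if (sum(hole_areas_px) > 0.5 * nr * nc) {
    fq_stop("holes exceed half the image area", "validation_error")
  }
  set.seed(seed)
  fn <- matrix(1, nr, nc)
  margin <- ceiling(sqrt(max(c(hole_areas_px, 25)) / pi)) + 4L
  taken <- matrix(FALSE, nr, nc)
  for (a_px in hole_areas_px) {
    if (a_px <= 0) next
    for (attempt in seq_len(10000L)) {
      ctr <- c(sample(margin:(nr - margin), 1L), sample(margin:(nc - margin), 1L))
      r_out <- ceiling(sqrt(a_px / pi)) + 2L
      rows <- (ctr[1] - r_out):(ctr[1] + r_out)
      cols <- (ctr[2] - r_out):(ctr[2] + r_out)
      d2 <- outer((rows - ctr[1])^2, (cols - ctr[2])^2, `+`)
      ord <- order(d2)[seq_len(a_px)]         # exactly a_px pixels
      ri <- rows[(ord - 1L) %% length(rows) + 1L]
      ci <- cols[(ord - 1L) %/% length(rows) + 1L]
      idx <- (ci - 1L) * nr + ri
      if (any(taken[idx])) next
      taken[idx] <- TRUE
      fn[idx] <- 0
      break
    }
  }
  nuc <- matrix(0, nr, nc)
  nuc_sigma <- 6
  ctrs <- cbind(runif(n_cells, margin, nr - margin),
                runif(n_cells, margin, nc - margin))
  # keep nuclei apart so they count as separate components
  for (i in seq_len(n_cells)) {
    for (attempt in seq_len(10000L)) {
      ok <- i == 1L ||
        all(sqrt(rowSums((ctrs[seq_len(i - 1L), , drop = FALSE] -
                          matrix(ctrs[i, ], i - 1L, 2, byrow = TRUE))^2)) >
              8 * nuc_sigma)
      if (ok) break
      ctrs[i, ] <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
    }
    rows <- max(1L, floor(ctrs[i, 1] - 3 * nuc_sigma)):min(nr, ceiling(ctrs[i, 1] + 3 * nuc_sigma))
    cols <- max(1L, floor(ctrs[i, 2] - 3 * nuc_sigma)):min(nc, ceiling(ctrs[i, 2] + 3 * nuc_sigma))
    g <- outer(exp(-(rows - ctrs[i, 1])^2 / (2 * nuc_sigma^2)),
               exp(-(cols - ctrs[i, 2])^2 / (2 * nuc_sigma^2)))
    nuc[rows, cols] <- pmax(nuc[rows, cols], g)
  }
  if (is.finite(snr)) {
    fn <- pmax(fn + rnorm(nr * nc, 0, 1 / snr), 0)
    nuc <- pmax(nuc + rnorm(nr * nc, 0, 1 / snr), 0)
    dim(fn) <- dim(nuc) <- c(nr, nc)
  }
  hole_px <- sum(hole_areas_px)
  structure(list(
    channels = list(fibronectin = micro_image(fn, pixel_size, "fibronectin"),
                    nuclei = micro_image(nuc, pixel_size, "nuclei")),
    truth = data.frame(hole_area_px = hole_px,
                       hole_area_um2 = hole_px * pixel_size^2,
                       n_cells = n_cells,
                       clearance_per_cell_um2 = hole_px * pixel_size^2 / n_cells)
  ), class = c("ClearanceScene", "SyntheticScene"))
}

#' Generate synthetic migration tracks and detections
#'
#' Seeded 2D tracks under three step models: `straight` (constant step
#' in a fixed random direction per track), `random_walk` (constant step
#' length, uniform random direction each frame), and `biased_walk`
#' (direction = track bias angle + Gaussian angular noise). Detections
#' are the exact per-frame positions pooled over tracks, the form a
#' point tracker consumes.
#'
#' @param n_tracks Number of tracks (>= 0).
#' @param n_frames Frames per track (>= 2).
#' @param dt Frame interval in seconds (default 300 s, a 5-min
#'   wide-field cadence).
#' @param step_model One of `"straight"`, `"random_walk"`,
#'   `"biased_walk"`.
#' @param step_um Step length per frame (um).
#' @param angle_sd Angular noise (radians) for `biased_walk`.
#' @param start_spacing_um Spacing of track starting positions (um).
#' @param seed RNG seed.
#' @return List with `tracks` (list of data frames `frame`, `x`, `y` in
#'   um, each with attribute `dt`) and `detections` (data frame `frame`,
#'   `x`, `y`), plus `dt`.
#' @export
generate_tracks <- function(n_tracks, n_frames, dt = 300,
                            step_model = c("random_walk", "straight",
                                           "biased_walk"),
                            step_um = 1, angle_sd = 0.5,
                            start_spacing_um = 200, seed = 1L) {
  step_model <- match.arg(step_model)
  if (n_tracks < 0 || n_frames < 2) {
    fq_stop("need n_tracks >= 0 and n_frames >= 2", "validation_error")
  }
  set.seed(seed)
  tracks <- vector("list", n_tracks)
  grid_n <- max(1L, ceiling(sqrt(max(n_tracks, 1L))))
  for (i in seq_len(n_tracks)) {
    gx <- ((i - 1L) %% grid_n) * start_spacing_um
    gy <- ((i - 1L) %/% grid_n) * start_spacing_um
    ang0 <- runif(1, 0, 2 * pi)
    ang <- switch(step_model,
      straight = rep(ang0, n_frames - 1L),
      random_walk = runif(n_frames - 1L, 0, 2 * pi),
      biased_walk = ang0 + rnorm(n_frames - 1L, 0, angle_sd)
    )
    x <- gx + cumsum(c(0, step_um * cos(ang)))
    y <- gy + cumsum(c(0, step_um * sin(ang)))
    tr <- data.frame(frame = seq_len(n_frames), x = x, y = y)
    attr(tr, "dt") <- dt
    tracks[[i]] <- tr
  }
  detections <- if (n_tracks > 0) {
    do.call(rbind, lapply(tracks, function(tr) tr[, c("frame", "x", "y")]))
  } else {
    data.frame(frame = integer(), x = numeric(), y = numeric())
  }
  detections <- detections[order(detections$frame), , drop = FALSE]
  rownames(detections) <- NULL
  list(tracks = tracks, detections = detections, dt = dt)
}
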