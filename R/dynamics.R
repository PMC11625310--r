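#' Build a kymograph along a line
#'
#' Samples every frame of a time-lapse along the segment `p0 -> p1`
#' (width-averaged, bilinear interpolation) and stacks the profiles as
#' columns: rows are positions along the line, columns are frames.
#'
#' @param stack 3D array (rows x cols x frames) or list of
#'   [micro_image()] frames.
#' @param p0,p1 Line endpoints, `(row, col)` pixels.
#' @param width Averaged parallel lines (odd, >= 1).
#' @param pixel_size Micrometres per pixel (taken from `MicroImage`
#'   frames when available).
#' @param dt Frame interval in seconds.
#' @return A `Kymograph`: list with `data` (space x time matrix),
#'   `space_step` (um), `time_step` (s), `source_line`.
#' @export
build_kymograph <- function(stack, p0, p1, width = 1L, pixel_size = 1,
                            dt = 1) {
  if (is.list(stack) && !is.array(stack)) {
    frames <- lapply(stack, as_micro)
    pixel_size <- frames[[1]]$pixel_size
    if (!is.null(frames[[1]]$frame_interval)) dt <- frames[[1]]$frame_interval
  } else if (is.array(stack) && length(dim(stack)) == 3L) {
    frames <- lapply(seq_len(dim(stack)[3]),
                     function(t) micro_image(stack[, , t], pixel_size))
  } else {
    fq_stop("'stack' must be a 3D array or a list of frames", "validation_error")
  }
  if (length(frames) < 2L) fq_stop("need at least 2 frames", "validation_error")
  cols <- lapply(frames, function(fr) {
    extract_line_profile(fr, p0, p1, width)$intensities[, 1]
  })
  km <- do.call(cbind, cols)
  structure(list(data = km, space_step = pixel_size, time_step = dt,
                 source_line = list(p0 = p0, p1 = p1, width = width)),
            class = "Kymograph")
}

#' @export
print.Kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d positions x %d frames (%.3g um/px, %g s/frame)\n",
              nrow(x$data), ncol(x$data), x$space_step, x$time_step))
  invisible(x)
}

#' Detect per-frame object presence in a time-lapse
#'
#' Builds stable object identities from the maximum-intensity
#' projection of the movie (one fixed global threshold, so threshold
#' flicker cannot inflate apparent turnover), then scores an object as
#' present in a frame when at least `min_fraction` of its reference
#' footprint is above the threshold in that frame.
#'
#' @param stack 3D array (rows x cols x frames) or a
#'   [generate_timelapse()] result.
#' @param threshold Fixed intensity threshold; `NULL` uses the Otsu
#'   threshold of the maximum projection.
#' @param min_fraction Fraction of the footprint that must be above
#'   threshold for presence (default 0.5).
#' @param connectivity Component connectivity for the footprints.
#' @param pixel_size Micrometres per pixel for the returned mask.
#' @return List with `presence` (objects x frames logical matrix),
#'   `labels` (reference [label_mask()]), `threshold`.
#' @export
detect_presence <- function(stack, threshold = NULL, min_fraction = 0.5,
                            connectivity = 8, pixel_size = 1) {
  if (inherits(stack, "SyntheticTimelapse")) {
    pixel_size <- stack$pixel_size
    stack <- stack$stack
  }
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    fq_stop("'stack' must be a 3D array", "validation_error")
  }
  n_frames <- dim(stack)[3]
  maxproj <- apply(stack, c(1, 2), max)
  if (is.null(threshold)) {
    threshold <- otsu_threshold(micro_image(maxproj, pixel_size))
  }
  ref <- label_connected(maxproj > threshold, connectivity = connectivity,
                         pixel_size = pixel_size)
  k <- n_objects(ref)
  px <- split(which(ref$labels > 0L), ref$labels[ref$labels > 0L])
  presence <- matrix(FALSE, k, n_frames)
  npix <- dim(stack)[1] * dim(stack)[2]
  for (t in seq_len(n_frames)) {
    fr <- stack[, , t]
    for (i in seq_len(k)) {
      presence[i, t] <- mean(fr[px[[i]]] > threshold) >= min_fraction
    }
  }
  list(presence = presence, labels = ref, threshold = threshold)
}

# Coerce presence input to an objects x frames logical matrix.
presence_matrix <- function(presence) {
  if (is.matrix(presence) && is.logical(presence)) return(presence)
  if (is.list(presence)) {
    # list of per-frame label masks/matrices with consistent labels
    labs <- lapply(presence, function(m) {
      if (inherits(m, "LabelMask")) m$labels else m
    })
    k <- max(vapply(labs, max, numeric(1)), 0)
    out <- matrix(FALSE, k, length(labs))
    for (t in seq_along(labs)) {
      pres <- unique(labs[[t]][labs[[t]] > 0])
      out[pres, t] <- TRUE
    }
    return(out)
  }
  fq_stop("'presence' must be a logical matrix or list of label masks",
          "validation_error")
}

#' Minimum lifetimes and formation rate from presence data
#'
#' Scores each object's contiguous presence run in a time-lapse. The
#' observed ("minimum") lifetime is `frames present x dt`: for an
#' object whose presence touches the first or last frame the true
#' lifetime is only bounded from below, and the record is flagged
#' censored. Presence interruptions up to `gap_tolerance` frames are
#' bridged (blinking robustness; set 0 for strict runs). An object
#' re-appearing after a longer gap yields a separate record. The
#' formation rate counts objects whose first appearance is after the
#' first frame, per minute of observation.
#'
#' @param presence Objects x frames logical matrix, or list of per-frame
#'   [label_mask()]s with consistent object labels.
#' @param dt Frame interval in seconds (> 0).
#' @param gap_tolerance Frames of absence bridged within a run
#'   (default 1).
#' @return List with `records` (data frame: `id`, `first_frame`,
#'   `last_frame`, `min_lifetime_s`, `censored_start`, `censored_end`,
#'   `censored`, `formation_frame`) and `formation_rate_per_min`.
#' @export
measure_lifetimes <- function(presence, dt, gap_tolerance = 1L) {
  if (dt <= 0) fq_stop("dt must be > 0", "validation_error")
  pm <- presence_matrix(presence)
  n_frames <- ncol(pm)
  if (n_frames < 1L) fq_stop("empty stack", "validation_error")
  recs <- list()
  for (i in seq_len(nrow(pm))) {
    fr <- which(pm[i, ])
    if (!length(fr)) next
    breaks <- which(diff(fr) > gap_tolerance + 1L)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, length(fr))
    for (j in seq_along(starts)) {
      f0 <- fr[starts[j]]; f1 <- fr[ends[j]]
      recs[[length(recs) + 1L]] <- data.frame(
        id = if (length(starts) > 1L) sprintf("%d.%d", i, j) else as.character(i),
        first_frame = f0, last_frame = f1,
        min_lifetime_s = (f1 - f0 + 1L) * dt,
        censored_start = f0 == 1L,
        censored_end = f1 == n_frames,
        formation_frame = if (f0 > 1L) f0 else NA_integer_
      )
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else data.frame(
    id = character(), first_frame = integer(), last_frame = integer(),
    min_lifetime_s = numeric(), censored_start = logical(),
    censored_end = logical(), formation_frame = integer())
  records$censored <- records$censored_start | records$censored_end
  n_formed <- sum(!is.na(records$formation_frame))
  list(records = records,
       formation_rate_per_min = n_formed / (n_frames * dt / 60))
}

#' Greedy nearest-neighbour track linking
#'
#' Links per-frame point detections into tracks by greedy
#' nearest-neighbour assignment between consecutive frames: candidate
#' (track end, detection) pairs are taken in order of increasing
#' distance, pairs farther than `max_disp` are rejected, unmatched
#' detections start new tracks. No gap closing — a miss terminates the
#' track. Adequate for sparse, slowly moving nuclei; not an optimal
#' (assignment-problem) tracker.
#'
#' @param detections Data frame with columns `frame`, `x`, `y`
#'   (positions in um).
#' @param max_disp Maximum frame-to-frame displacement (um, > 0).
#' @param dt Frame interval in seconds (attached to each track).
#' @return List of tracks (data frames `frame`, `x`, `y`, each with
#'   attribute `dt`).
#' @export
link_tracks <- function(detections, max_disp, dt = 1) {
  if (max_disp <= 0) fq_stop("max_disp must be > 0", "validation_error")
  if (!all(c("frame", "x", "y") %in% names(detections))) {
    fq_stop("detections need columns frame, x, y", "validation_error")
  }
  if (!nrow(detections)) return(list())
  frames <- sort(unique(detections$frame))
  tracks <- list()
  active <- integer(0)   # indices into tracks whose end is in prev frame
  prev_pos <- NULL
  for (f in frames) {
    det <- detections[detections$frame == f, c("x", "y"), drop = FALSE]
    nd <- nrow(det)
    assigned_det <- rep(FALSE, nd)
    new_active <- integer(0)
    if (length(active) && nd) {
      dmat <- outer(prev_pos[, 1], det$x, `-`)^2 +
              outer(prev_pos[, 2], det$y, `-`)^2
      ord <- order(dmat)
      used_tr <- rep(FALSE, length(active))
      for (o in ord) {
        if (dmat[o] > max_disp^2) break
        ti <- (o - 1L) %% length(active) + 1L
        di <- (o - 1L) %/% length(active) + 1L
        if (used_tr[ti] || assigned_det[di]) next
        used_tr[ti] <- TRUE; assigned_det[di] <- TRUE
        k <- active[ti]
        tracks[[k]] <- rbind(tracks[[k]],
                             data.frame(frame = f, x = det$x[di], y = det$y[di]))
        new_active <- c(new_active, k)
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <-
        data.frame(frame = f, x = det$x[di], y = det$y[di])
      new_active <- c(new_active, length(tracks))
    }
    active <- new_active
    prev_pos <- do.call(rbind, lapply(tracks[active], function(tr) {
      as.numeric(tail(tr, 1L)[, c("x", "y")])
    }))
  }
  lapply(tracks, function(tr) {
    rownames(tr) <- NULL
    attr(tr, "dt") <- dt
    tr
  })
}

#' Migration metrics of one track
#'
#' Computes, for a track spanning at least `min_duration` hours:
#' `speed` = path length / duration, `persistence` = net displacement /
#' path length (in \[0, 1\]), and `forward_progress` = net displacement
#' / duration. Shorter tracks are excluded (the continually-tracked
#' minimum-duration filter); they return `excluded = TRUE` with `NA`
#' metrics.
#'
#' @param track Data frame `frame`, `x`, `y` (um) with attribute `dt`,
#'   or pass `dt` explicitly.
#' @param min_duration Minimum track duration in hours (default 8).
#' @param dt Frame interval in seconds (overrides the attribute).
#' @return List with `speed_um_min`, `persistence`,
#'   `forward_progress_um_min`, `duration_h`, `excluded`.
#' @export
migration_metrics <- function(track, min_duration = 8, dt = NULL) {
  if (is.null(dt)) dt <- attr(track, "dt")
  if (is.null(dt) || dt <= 0) fq_stop("frame interval dt unknown", "validation_error")
  if (nrow(track) < 2L) fq_stop("track needs >= 2 points", "validation_error")
  dx <- diff(track$x); dy <- diff(track$y)
  steps <- sqrt(dx^2 + dy^2)
  path <- sum(steps)
  net <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
              (track$y[nrow(track)] - track$y[1])^2)
  duration_s <- (nrow(track) - 1L) * dt
  duration_h <- duration_s / 3600
  if (duration_h < min_duration) {
    return(list(speed_um_min = NA_real_, persistence = NA_real_,
                forward_progress_um_min = NA_real_,
                duration_h = duration_h, excluded = TRUE))
  }
  list(speed_um_min = path / (duration_s / 60),
       persistence = if (path > 0) net / path else 0,
       forward_progress_um_min = net / (duration_s / 60),
       duration_h = duration_h, excluded = FALSE)
}
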