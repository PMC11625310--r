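test_that("kymographs stack line profiles over time", {
  # static stack: all columns identical, zero temporal variance per row
  fr <- matrix(runif(64 * 64), 64, 64)
  stack <- array(rep(fr, 5), dim = c(64, 64, 5))
  km <- build_kymograph(stack, c(32, 5), c(32, 54), pixel_size = 0.11, dt = 10)
  expect_identical(dim(km$data), c(50L, 5L))
  expect_true(all(apply(km$data, 1, var) == 0))

  # a spot moving along the line produces a sloped bright streak
  n_fr <- 20
  stack2 <- array(0, dim = c(64, 64, n_fr))
  v <- 2                                  # px per frame
  for (t in seq_len(n_fr)) {
    ctr <- 5 + v * (t - 1)
    stack2[32, , t] <- exp(-((1:64) - ctr)^2 / 8)
  }
  km2 <- build_kymograph(stack2, c(32, 1), c(32, 64), pixel_size = 1, dt = 1)
  peaks <- apply(km2$data, 2, which.max)
  expect_equal(unname(diff(peaks)), rep(v, n_fr - 1))

  expect_error(build_kymograph(stack, c(32, 0), c(32, 54)),
               class = "validation_error")
})

test_that("lifetimes and formation rate follow the frames-present convention", {
  presence <- matrix(FALSE, 3, 60)
  presence[1, 3:14] <- TRUE                 # 12 frames -> 120 s
  presence[2, 1:60] <- TRUE                 # censored both ends
  presence[3, 40:60] <- TRUE                # censored at end
  lt <- measure_lifetimes(presence, dt = 10)
  expect_equal(lt$records$min_lifetime_s, c(120, 600, 210))
  expect_equal(lt$records$censored, c(FALSE, TRUE, TRUE))
  # formations: objects 1 and 3 appear after the first frame; 600 s movie
  expect_equal(lt$formation_rate_per_min, 2 / 10)

  # 1-frame gaps are bridged by default but not in strict mode
  blink <- matrix(FALSE, 1, 30)
  blink[1, c(5:10, 12:20)] <- TRUE
  expect_equal(measure_lifetimes(blink, dt = 10)$records$min_lifetime_s, 160)
  strict <- measure_lifetimes(blink, dt = 10, gap_tolerance = 0)$records
  expect_equal(strict$min_lifetime_s, c(60, 90))

  expect_error(measure_lifetimes(presence, dt = 0), class = "validation_error")
})

test_that("presence detected from a noise-free movie recovers truth exactly", {
  tp <- timelapse_params(n_frames = 40, dt = 15, snr = Inf, seed = 6)
  ev <- data.frame(appear = c(5, 1, 18), disappear = c(20, 40, 33),
                   row = c(30, 70, 100), col = c(35, 90, 60))
  tl <- generate_timelapse(tp, ev)
  det <- detect_presence(tl)
  expect_identical(nrow(det$presence), 3L)
  lt <- measure_lifetimes(det$presence, dt = tl$dt)
  # match records to truth via first frames
  ord <- order(lt$records$first_frame)
  truth_ord <- order(tl$truth_events$first_frame)
  expect_equal(lt$records$min_lifetime_s[ord],
               tl$truth_events$lifetime_s[truth_ord])
  expect_equal(lt$records$censored[ord],
               (tl$truth_events$censored_start |
                  tl$truth_events$censored_end)[truth_ord])
})

test_that("greedy linking keeps well-separated tracks apart", {
  tr <- generate_tracks(4, 30, dt = 300, step_model = "random_walk",
                        step_um = 1.5, start_spacing_um = 300, seed = 2)
  linked <- link_tracks(tr$detections, max_disp = 10, dt = 300)
  expect_length(linked, 4)
  expect_true(all(vapply(linked, nrow, integer(1)) == 30))

  # displacement beyond max_disp splits a track
  det <- data.frame(frame = 1:6, x = c(0, 1, 2, 50, 51, 52), y = 0)
  split_tr <- link_tracks(det, max_disp = 5)
  expect_length(split_tr, 2)
  expect_equal(vapply(split_tr, nrow, integer(1)), c(3L, 3L))
})

test_that("migration metrics satisfy their geometric identities", {
  # straight track: persistence exactly 1, speed = step / dt
  straight <- data.frame(frame = 1:97, x = 2 * (0:96), y = 0)
  attr(straight, "dt") <- 300
  m <- migration_metrics(straight)
  expect_false(m$excluded)
  expect_equal(m$persistence, 1, tolerance = 1e-9)
  expect_equal(m$speed_um_min, 2 / 5)
  expect_equal(m$forward_progress_um_min, m$speed_um_min)

  # closed loop: persistence and forward progress are zero
  th <- seq(0, 2 * pi, length.out = 101)
  loop <- data.frame(frame = 1:101, x = 10 * cos(th), y = 10 * sin(th))
  attr(loop, "dt") <- 300
  ml <- migration_metrics(loop)
  expect_equal(ml$persistence, 0, tolerance = 1e-9)
  expect_equal(ml$forward_progress_um_min, 0, tolerance = 1e-9)

  # the 8-hour continuous-tracking filter excludes a 7 h track
  short <- straight[1:85, ]                  # 84 * 300 s = 7 h
  attr(short, "dt") <- 300
  expect_true(migration_metrics(short)$excluded)

  # triangle inequality: speed >= forward progress on random walks;
  # persistence in [0,1] and decreasing with duration
  pers <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    w <- generate_tracks(1, 2001, dt = 300, step_model = "random_walk",
                         seed = 100 + s)$tracks[[1]]
    for (j in 1:3) {
      seg <- w[seq_len(c(500, 1000, 2001)[j]), ]
      attr(seg, "dt") <- 300
      mm <- migration_metrics(seg, min_duration = 0)
      expect_gte(mm$speed_um_min, mm$forward_progress_um_min)
      expect_true(mm$persistence >= 0 && mm$persistence <= 1)
      pers[s, j] <- mm$persistence
    }
  }
  mp <- colMeans(pers)
  expect_true(mp[1] > mp[2] && mp[2] > mp[3])
})
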