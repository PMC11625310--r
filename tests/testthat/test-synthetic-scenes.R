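test_that("scenes are deterministic and geometrically consistent", {
  p <- scene_params(image_shape = c(256, 256), n_objects_inner = 3,
                    n_objects_outer = 3, seed = 5)
  a <- generate_fa_scene(p)
  b <- generate_fa_scene(p)
  expect_identical(a$channels$paxillin$data, b$channels$paxillin$data)
  expect_identical(a$channels$septin$data, b$channels$septin$data)
  expect_identical(a$truth_labels$labels, b$truth_labels$labels)

  # every truth object lies entirely inside its assigned compartment
  lab <- a$truth_labels$labels
  for (i in seq_len(nrow(a$truth))) {
    region_mask <- a$truth_regions[[a$truth$region[i]]]
    expect_true(all(region_mask[lab == i]))
  }
  # each labelled object has a truth row
  expect_setequal(unique(lab[lab > 0]), a$truth$label)
  expect_identical(dim(lab), dim(a$channels$septin$data))
})

test_that("perfect correlation gives r = 1 and rho = 0 averages near zero", {
  p1 <- scene_params(image_shape = c(256, 256), n_objects_inner = 2,
                     n_objects_outer = 2, rho_inner = 1, rho_outer = 1,
                     seed = 2)
  sc <- generate_fa_scene(p1)
  r <- pearson_per_object(sc$truth_labels, sc$channels$paxillin,
                          sc$channels$septin)$pearson
  expect_equal(r, rep(1, 4), tolerance = 1e-10)

  rs <- c()
  for (s in 1:20) {
    p0 <- scene_params(area_range = c(7, 9), n_objects_inner = 2,
                       n_objects_outer = 2, rho_inner = 0, rho_outer = 0,
                       seed = s)
    sc <- generate_fa_scene(p0)
    expect_true(all(sc$truth$area_px >= 500))
    rs <- c(rs, pearson_per_object(sc$truth_labels, sc$channels$paxillin,
                                   sc$channels$septin)$pearson)
  }
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("scene parameter validation and capacity errors fire", {
  expect_error(scene_params(rho_inner = 1.5), class = "validation_error")
  expect_error(scene_params(snr = 0), class = "validation_error")
  expect_error(scene_params(area_range = c(4, 2)), class = "validation_error")
  # far too many large objects for a small frame
  expect_error(
    generate_fa_scene(scene_params(image_shape = c(64, 64),
                                   n_objects_inner = 40, n_objects_outer = 40,
                                   area_range = c(3, 4))),
    class = "capacity_error")
})

test_that("time-lapse truth follows the frames-present convention", {
  tp <- timelapse_params(n_frames = 20, dt = 10, seed = 1)
  ev <- data.frame(appear = c(3, 1), disappear = c(14, 20),
                   row = c(30, 80), col = c(30, 80))
  tl <- generate_timelapse(tp, ev)
  expect_equal(tl$truth_events$lifetime_s, c(120, 200))
  expect_equal(tl$truth_events$censored_start, c(FALSE, TRUE))
  expect_equal(tl$truth_events$censored_end, c(FALSE, TRUE))
  expect_identical(dim(tl$stack), c(128L, 128L, 20L))
  # presence exactly in [appear, disappear]
  expect_identical(which(tl$truth_presence[1, ]), 3:14)

  # empty spec -> pure background
  tl0 <- generate_timelapse(tp, NULL)
  expect_identical(nrow(tl0$truth_events), 0L)
  expect_lt(max(tl0$stack), 0.2 + 6 / tp$snr)

  expect_error(
    generate_timelapse(tp, data.frame(appear = 0, disappear = 5,
                                      row = 10, col = 10)),
    class = "validation_error")
})

test_that("clearance scenes carry exact hole areas and countable cells", {
  sc <- generate_clearance_scene(c(100), n_cells = 1,
                                 image_shape = c(200, 200), pixel_size = 0.5)
  expect_equal(sc$truth$clearance_per_cell_um2, 100 * 0.25)
  expect_identical(sum(sc$channels$fibronectin$data == 0), 100L)

  sc0 <- generate_clearance_scene(integer(0), n_cells = 3,
                                  image_shape = c(128, 128))
  expect_equal(sc0$truth$hole_area_px, 0)
  expect_error(generate_clearance_scene(rep(1e5, 3), n_cells = 1,
                                        image_shape = c(128, 128)),
               class = "validation_error")
})

test_that("track generator matches 2D random-walk statistics", {
  tr <- generate_tracks(2, 50, dt = 300, step_model = "straight",
                        step_um = 2, seed = 3)
  d <- tr$tracks[[1]]
  steps <- sqrt(diff(d$x)^2 + diff(d$y)^2)
  expect_equal(steps, rep(2, 49), tolerance = 1e-12)
  net <- sqrt((d$x[50] - d$x[1])^2 + (d$y[50] - d$y[1])^2)
  expect_equal(net, sum(steps), tolerance = 1e-9)   # collinear

  # random walk: net displacement far below path length, and near the
  # sqrt(n) scaling of an isotropic walk
  nets <- paths <- c()
  for (s in 1:20) {
    w <- generate_tracks(1, 2001, dt = 300, step_model = "random_walk",
                         step_um = 1, seed = s)$tracks[[1]]
    nets <- c(nets, sqrt((w$x[2001] - w$x[1])^2 + (w$y[2001] - w$y[1])^2))
    paths <- c(paths, sum(sqrt(diff(w$x)^2 + diff(w$y)^2)))
  }
  expect_true(all(nets < 0.2 * paths))
  # E[net] for an isotropic unit-step walk is ~ sqrt(pi * n) / 2 ~ 39.6
  expect_gt(mean(nets), 15)
  expect_lt(mean(nets), 80)

  expect_identical(nrow(generate_tracks(0, 10)$detections), 0L)
})
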