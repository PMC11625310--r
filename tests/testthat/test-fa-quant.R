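test_that("segmentation recovers ground-truth objects on a synthetic scene", {
  sc <- generate_fa_scene(scene_params(seed = 21))
  seg <- segment_fas(sc$channels$paxillin, morphology_config())
  expect_identical(nrow(seg$objects), nrow(sc$truth))
  m <- match_truth_to_detected(sc$truth_labels$labels, seg$mask$labels)
  expect_true(all(m$iou >= 0.7))
  expect_true(all(m$area_rel_err <= 0.10))
  # morphometrics sanity: roundness in (0, 1], axes ordered
  expect_true(all(seg$objects$roundness > 0 & seg$objects$roundness <= 1))
  expect_true(all(seg$objects$major_axis >= seg$objects$minor_axis))
})

test_that("area filter bounds are exclusive and exact", {
  ps <- 0.11
  # 8 px ~ 0.097 um^2 (< 0.20) and 579 px ~ 7.006 um^2 (> 6): rejected;
  # 21 px ~ 0.254 and 454 px ~ 5.493: retained
  lab <- matrix(0L, 120, 120)
  lab[2:3, 2:5] <- 1L                       #   8 px
  lab[10:30, 10:36] <- 2L                   # 567 px -> 6.86 um^2
  lab[50:52, 50:56] <- 3L                   #  21 px
  lab[60:81, 60:80] <- 4L                   # 462 px -> 5.59 um^2
  kept <- filter_labels_by_area(label_mask(lab, ps), 0.20, 6)
  kept_ids <- sort(unique(lab[kept$labels > 0]))
  expect_identical(kept_ids, c(3L, 4L))
  expect_identical(n_objects(kept), 2L)

  # exactly-at-bound areas are rejected (exclusive interval)
  n_min <- round(0.20 / ps^2)               # 17 px -> 0.2057: retained
  lab2 <- matrix(0L, 40, 40)
  lab2[2:18, 2] <- 1L                       # 17 px
  expect_identical(n_objects(filter_labels_by_area(label_mask(lab2, ps),
                                                   17 * ps^2, 6)), 0L)
  expect_identical(n_objects(filter_labels_by_area(label_mask(lab2, ps),
                                                   0.20, 6)), 1L)

  # the full pipeline never returns out-of-bounds objects
  sc <- generate_fa_scene(scene_params(seed = 4, area_range = c(0.3, 5)))
  seg <- segment_fas(sc$channels$paxillin, morphology_config())
  expect_true(all(seg$objects$area > 0.20 & seg$objects$area < 6))
})

test_that("region partition is disjoint, exhaustive and matches the disk analytic", {
  # circular mask radius R: inner at fraction 0.5 is the concentric
  # R/2 disk within 1 px discretisation
  R <- 40
  d2 <- outer((1:101 - 51)^2, (1:101 - 51)^2, `+`)
  cell <- d2 <= R^2
  part <- partition_regions(cell, fraction = 0.5)
  expect_true(all(d2[part$inner_mask] <= (R / 2 + 1.5)^2))
  expect_true(all(part$inner_mask[d2 <= (R / 2 - 1.5)^2]))
  expect_false(any(part$inner_mask & part$outer_mask))
  expect_identical(part$inner_mask | part$outer_mask, cell)

  p0 <- partition_regions(cell, fraction = 0)
  expect_identical(p0$inner_mask, cell)
  expect_false(any(p0$outer_mask))
  p1 <- partition_regions(cell, fraction = 1)
  expect_true(sum(p1$inner_mask) >= 1 && sum(p1$inner_mask) <= 9)

  expect_error(partition_regions(matrix(FALSE, 5, 5)), class = "validation_error")
})

test_that("region classification follows centroids and the generator truth", {
  R <- 40
  d2 <- outer((1:101 - 51)^2, (1:101 - 51)^2, `+`)
  part <- partition_regions(d2 <= R^2, fraction = 0.5)
  ctr <- data.frame(centroid_row = 51, centroid_col = 51)
  expect_identical(classify_region(ctr, part)$region, "inner")
  edge <- data.frame(centroid_row = 51, centroid_col = 51 + R)
  expect_identical(classify_region(edge, part)$region, "outer")
  out <- data.frame(centroid_row = 1, centroid_col = 1)
  expect_error(classify_region(out, part), class = "unassigned_error")

  sc <- generate_fa_scene(scene_params(seed = 9))
  seg <- segment_fas(sc$channels$paxillin, morphology_config())
  part <- partition_regions(sc$truth_regions$cell, fraction = 0.5)
  objs <- classify_region(seg$objects, part)
  m <- match_truth_to_detected(sc$truth_labels$labels, seg$mask$labels)
  # detected objects inherit the compartment of their truth object
  det_of_truth <- vapply(seq_len(nrow(sc$truth)), function(i) {
    tp <- sc$truth_labels$labels == i
    hit <- seg$mask$labels[tp]
    as.integer(names(sort(table(hit[hit > 0]), decreasing = TRUE))[1])
  }, integer(1))
  expect_identical(objs$region[det_of_truth], sc$truth$region)
})

test_that("per-object Pearson equals the naive two-pass oracle", {
  sc <- generate_fa_scene(scene_params(image_shape = c(256, 256),
                                       n_objects_inner = 3,
                                       n_objects_outer = 3, seed = 13))
  a <- sc$channels$paxillin; b <- sc$channels$septin
  r <- pearson_per_object(sc$truth_labels, a, b)
  r_oracle <- oracle_pearson_per_object(sc$truth_labels$labels, a$data, b$data)
  expect_equal(r$pearson, r_oracle, tolerance = 1e-12)

  # trivial identities
  expect_true(all(pearson_per_object(sc$truth_labels, a, a)$pearson == 1))
  neg <- micro_image(max(a$data) - a$data, a$pixel_size)
  expect_true(all(abs(pearson_per_object(sc$truth_labels, a, neg)$pearson + 1) < 1e-12))

  # constant channel within objects -> undefined, flagged
  const <- micro_image(matrix(0.5, 256, 256), a$pixel_size)
  rc <- pearson_per_object(sc$truth_labels, a, const)
  expect_true(all(!rc$defined))
  expect_true(all(is.na(rc$pearson)))

  small <- label_mask(matrix(c(1L, rep(0L, 15)), 4, 4), 0.11)
  expect_error(pearson_per_object(small, micro_image(matrix(1:16 / 16, 4, 4), 0.11),
                                  micro_image(matrix(1:16 / 16, 4, 4), 0.11)),
               class = "validation_error")
})

test_that("random binning drops remainders, excludes NA, and is seeded", {
  expect_equal(bin_random(rep(4, 20), 10, seed = 1), c(4, 4))
  v <- rnorm(25)
  b1 <- bin_random(v, 10, seed = 3)
  expect_length(b1, 2)
  expect_identical(b1, bin_random(v, 10, seed = 3))
  expect_false(identical(b1, bin_random(v, 10, seed = 4)))
  # bin size 5 on 25 values: the 5 bin means average to the grand mean
  expect_equal(mean(bin_random(v, 5, seed = 2)), mean(v), tolerance = 1e-12)
  expect_warning(out <- bin_random(rnorm(5), 10), "fewer")
  expect_length(out, 0)
  vna <- c(rnorm(12), NA, NA)
  expect_length(bin_random(vna, 10, seed = 1), 1)
})
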