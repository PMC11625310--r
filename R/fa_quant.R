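#' Morphology and colocalization configuration
#'
#' Defaults follow common focal-adhesion quantification practice:
#' adhesions are retained only in the open interval 0.20 um^2 < area <
#' 6 um^2 (smaller components are unresolvable speckle, larger ones are
#' merged structures), and per-adhesion values are averaged in random
#' bins of 10 before plotting/testing.
#'
#' @param min_area,max_area Exclusive area bounds in um^2 (defaults 0.20
#'   and 6).
#' @param median_radius Median-filter radius in pixels.
#' @param bg_radius Background-subtraction disc radius in pixels.
#' @param bin_size Number of objects averaged per random bin.
#' @param connectivity Component connectivity, 4 or 8.
#' @param seed RNG seed used by [bin_random()].
#' @return A `MorphologyConfig` list.
#' @export
morphology_config <- function(min_area = 0.20, max_area = 6,
                              median_radius = 1, bg_radius = 50,
                              bin_size = 10, connectivity = 8, seed = 1L) {
  if (min_area >= max_area) {
    fq_stop("min_area must be < max_area", "validation_error")
  }
  if (bin_size < 1) fq_stop("bin_size must be >= 1", "validation_error")
  structure(list(min_area = min_area, max_area = max_area,
                 median_radius = median_radius, bg_radius = bg_radius,
                 bin_size = as.integer(bin_size),
                 connectivity = connectivity, seed = as.integer(seed)),
            class = "MorphologyConfig")
}

# Per-object morphometrics from a label mask: area, centroid,
# second-moment ellipse axes, roundness, border flag.
object_morphometrics <- function(mask) {
  lab <- mask$labels
  ps <- mask$pixel_size
  k <- n_objects(mask)
  if (k == 0L) {
    return(data.frame(label = integer(), area = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      major_axis = numeric(), minor_axis = numeric(),
                      roundness = numeric(), on_border = logical()))
  }
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0L)
  lv <- lab[idx]
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  n_px <- tabulate(lv, k)
  sr <- rowsum(as.numeric(ri), lv)[, 1]
  sc <- rowsum(as.numeric(ci), lv)[, 1]
  mr <- sr / n_px; mc <- sc / n_px
  # central second moments (per object, vectorised over pixels)
  drr <- ri - mr[lv]; dcc <- ci - mc[lv]
  mu_rr <- rowsum(drr * drr, lv)[, 1] / n_px
  mu_cc <- rowsum(dcc * dcc, lv)[, 1] / n_px
  mu_rc <- rowsum(drr * dcc, lv)[, 1] / n_px
  # eigenvalues of the 2x2 covariance -> moment-ellipse axes
  tr <- mu_rr + mu_cc
  disc <- sqrt(pmax((mu_rr - mu_cc)^2 + 4 * mu_rc^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- pmax((tr - disc) / 2, 0)
  major_px <- 4 * sqrt(l1)
  minor_px <- 4 * sqrt(l2)
  area_px <- n_px
  roundness <- ifelse(major_px > 0,
                      pmin(4 * area_px / (pi * major_px^2), 1), 1)
  on_border <- as.logical(
    tabulate(lv[ri == 1L | ri == nr | ci == 1L | ci == nc], k) > 0L)
  data.frame(label = seq_len(k), area = area_px * ps^2,
             centroid_row = mr, centroid_col = mc,
             major_axis = major_px * ps, minor_axis = minor_px * ps,
             roundness = roundness, on_border = on_border)
}

#' Segment focal adhesions (or septin structures) in one channel
#'
#' The segmentation pipeline of the package: local background
#' subtraction (top-hat), median filter, global Otsu threshold
#' (foreground strictly above), connected-component labelling, then an
#' exclusive area filter discarding components with area `<= min_area`
#' or `>= max_area`. Surviving objects are relabelled `1..K` and their
#' morphometrics computed (area, centroid, moment-ellipse axes,
#' roundness = 4 area / (pi major_axis^2), border flag). Objects
#' touching the image border are retained but flagged.
#'
#' @param img A [micro_image()] with a physical pixel size.
#' @param cfg A [morphology_config()].
#' @return List with `mask` (filtered [label_mask()]), `objects` (data
#'   frame of per-object morphometrics), and `threshold` (the Otsu
#'   intensity used). Zero surviving objects is a valid empty result.
#' @export
#' @examples
#' sc <- generate_fa_scene(scene_params(image_shape = c(192, 192),
#'                                      n_objects_inner = 2, n_objects_outer = 3))
#' seg <- segment_fas(sc$channels$paxillin, morphology_config(bg_radius = 20))
#' seg$objects
segment_fas <- function(img, cfg = morphology_config()) {
  img <- as_micro(img)
  bgless <- subtract_background(img, cfg$bg_radius)
  smoothed <- median_filter(bgless, cfg$median_radius)
  thr <- otsu_threshold(smoothed)
  mask <- smoothed$data > thr
  lab <- label_connected(mask, connectivity = cfg$connectivity,
                         pixel_size = img$pixel_size)
  lab <- filter_labels_by_area(lab, cfg$min_area, cfg$max_area)
  objs <- object_morphometrics(lab)
  list(mask = lab, objects = objs, threshold = thr)
}

#' Exclusive area filter on a label mask
#'
#' Drops every labelled object whose physical area is `<= min_area` or
#' `>= max_area` (um^2, exclusive bounds on both sides) and relabels
#' the survivors `1..K`. With the defaults of [morphology_config()]
#' this is the 0.20 um^2 < area < 6 um^2 adhesion size filter.
#'
#' @param mask A [label_mask()].
#' @param min_area,max_area Exclusive bounds in um^2.
#' @return The filtered [label_mask()].
#' @export
filter_labels_by_area <- function(mask, min_area, max_area) {
  lab <- mask$labels
  k <- n_objects(mask)
  if (k == 0L) return(mask)
  area_um2 <- tabulate(lab[lab > 0L], k) * mask$pixel_size^2
  keep <- area_um2 > min_area & area_um2 < max_area
  map <- integer(k)
  map[keep] <- seq_len(sum(keep))
  out <- lab
  nz <- lab > 0L
  out[nz] <- map[lab[nz]]
  label_mask(out, mask$pixel_size)
}

#' Partition a cell mask into inner and outer regions
#'
#' A reproducible surrogate for manually drawn inner (perinuclear) /
#' outer (peripheral) regions: the inner region is the set of cell
#' pixels whose Euclidean distance to the cell edge is at least
#' `fraction` times the maximum such distance; the outer region is the
#' remainder of the cell. `fraction = 0` makes the whole cell inner;
#' `fraction = 1` keeps only the deepest pixel(s).
#'
#' @param cell_mask Logical/0-1 matrix marking the cell.
#' @param fraction Edge-distance fraction in \[0, 1\] (default 0.5).
#' @return A `RegionPartition`: list with `inner_mask`, `outer_mask`
#'   (logical matrices, disjoint, union = cell), `method`, `fraction`.
#' @export
partition_regions <- function(cell_mask, fraction = 0.5) {
  if (inherits(cell_mask, "MicroImage")) cell_mask <- cell_mask$data > 0
  if (!is.matrix(cell_mask)) fq_stop("'cell_mask' must be a matrix", "validation_error")
  cell <- matrix(as.logical(cell_mask), nrow(cell_mask), ncol(cell_mask))
  if (!any(cell)) fq_stop("cell mask is empty", "validation_error")
  if (fraction < 0 || fraction > 1) {
    fq_stop("'fraction' must lie in [0, 1]", "validation_error")
  }
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(cell), nrow(cell), ncol(cell))))
  inner <- cell & (d >= fraction * max(d))
  outer <- cell & !inner
  structure(list(inner_mask = inner, outer_mask = outer,
                 method = "edge_distance_fraction", fraction = fraction),
            class = "RegionPartition")
}

#' Classify objects as inner or outer by centroid
#'
#' An object belongs to the inner region iff its centroid pixel (nearest
#' integer) falls in the partition's inner mask; otherwise outer. A
#' centroid outside the cell altogether is an error.
#'
#' @param objects Data frame with `centroid_row`, `centroid_col` (as
#'   returned by [segment_fas()]), or a single FA row.
#' @param part A [partition_regions()] result.
#' @return `objects` with a `region` factor column (`"inner"`/`"outer"`).
#' @export
classify_region <- function(objects, part) {
  if (!nrow(objects)) {
    objects$region <- character(0)
    return(objects)
  }
  ri <- pmin(pmax(round(objects$centroid_row), 1L), nrow(part$inner_mask))
  ci <- pmin(pmax(round(objects$centroid_col), 1L), ncol(part$inner_mask))
  lin <- cbind(ri, ci)
  in_inner <- part$inner_mask[lin]
  in_outer <- part$outer_mask[lin]
  if (any(!in_inner & !in_outer)) {
    fq_stop("object centroid lies outside the cell mask", "unassigned_error")
  }
  objects$region <- ifelse(in_inner, "inner", "outer")
  objects
}

#' Per-object pixel-wise Pearson colocalization
#'
#' For every labelled object (the segmentation of the reference
#' channel, typically paxillin), computes the Pearson correlation of the
#' two channels' intensities over that object's pixels only. Objects in
#' which either channel is constant carry no correlation information and
#' are returned as `NA` with `defined = FALSE`.
#'
#' @param labels A [label_mask()].
#' @param chan_a,chan_b [micro_image()]s sharing the mask's geometry.
#' @return Data frame: `label`, `n_px`, `pearson`, `defined`.
#' @export
#' @examples
#' sc <- generate_fa_scene(scene_params(image_shape = c(192, 192),
#'                                      n_objects_inner = 2, n_objects_outer = 3))
#' pearson_per_object(sc$truth_labels, sc$channels$paxillin, sc$channels$septin)
pearson_per_object <- function(labels, chan_a, chan_b) {
  stopifnot(inherits(labels, "LabelMask"))
  chan_a <- as_micro(chan_a, labels$pixel_size)
  chan_b <- as_micro(chan_b, labels$pixel_size)
  check_same_geometry(labels, chan_a, "label mask and channel A")
  check_same_geometry(labels, chan_b, "label mask and channel B")
  k <- n_objects(labels)
  idx <- which(labels$labels > 0L)
  lv <- labels$labels[idx]
  a <- chan_a$data[idx]; b <- chan_b$data[idx]
  n <- tabulate(lv, k)
  if (any(n < 2L)) {
    fq_stop("every object needs at least 2 pixels", "validation_error")
  }
  sa <- rowsum(a, lv)[, 1]; sb <- rowsum(b, lv)[, 1]
  saa <- rowsum(a * a, lv)[, 1]; sbb <- rowsum(b * b, lv)[, 1]
  sab <- rowsum(a * b, lv)[, 1]
  cov_ab <- sab - sa * sb / n
  var_a <- saa - sa^2 / n
  var_b <- sbb - sb^2 / n
  defined <- var_a > 0 & var_b > 0
  r <- rep(NA_real_, k)
  r[defined] <- cov_ab[defined] / sqrt(var_a[defined] * var_b[defined])
  r[defined] <- pmin(pmax(r[defined], -1), 1)
  data.frame(label = seq_len(k), n_px = n, pearson = r, defined = defined)
}

#' Random binning of per-object values
#'
#' Shuffles the values with the configured seed, partitions them into
#' consecutive groups of `bin_size`, drops the remainder, and returns
#' the group means — the "each point represents the average of 10 random
#' FAs" convention. `NA` values (e.g. undefined correlations) are
#' removed before binning.
#'
#' @param values Numeric vector.
#' @param bin_size Objects per bin (default 10).
#' @param seed RNG seed for the shuffle.
#' @return Numeric vector of bin means (possibly empty, with a warning,
#'   when fewer than `bin_size` values remain).
#' @export
#' @examples
#' bin_random(rnorm(25), bin_size = 10, seed = 1) # 2 means, 5 values dropped
bin_random <- function(values, bin_size = 10, seed = 1L) {
  if (bin_size < 1) fq_stop("bin_size must be >= 1", "validation_error")
  values <- values[!is.na(values)]
  if (length(values) < bin_size) {
    warning("fewer values than bin_size: no bins formed")
    return(numeric(0))
  }
  # seeded shuffle without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
  )
  set.seed(seed)
  perm <- sample(values)
  n_bins <- length(values) %/% bin_size
  colMeans(matrix(perm[seq_len(n_bins * bin_size)], nrow = bin_size))
}

#' Segment, classify and correlate in one call
#'
#' Convenience wrapper chaining [segment_fas()], [classify_region()]
#' and [pearson_per_object()] for one cell: returns a tidy per-adhesion
#' table with morphometrics, region and Pearson r.
#'
#' @param ref_channel Reference channel used for segmentation (paxillin).
#' @param other_channel Channel correlated against the reference within
#'   each adhesion (septin, F-actin, ...).
#' @param cell_mask Logical matrix; defaults to Otsu foreground of the
#'   reference channel dilated is NOT applied — supply a mask for region
#'   classification, or a [partition_regions()] result via `partition`.
#' @param partition Optional precomputed [partition_regions()] result.
#' @param cfg A [morphology_config()].
#' @param fraction Edge-distance fraction when a partition is derived
#'   from `cell_mask`.
#' @return List with `objects` (tidy data frame: label, area, roundness,
#'   region, pearson, ...), `mask`, `partition`.
#' @export
quantify_adhesions <- function(ref_channel, other_channel,
                               cell_mask = NULL, partition = NULL,
                               cfg = morphology_config(), fraction = 0.5) {
  seg <- segment_fas(ref_channel, cfg)
  objs <- seg$objects
  if (is.null(partition)) {
    if (is.null(cell_mask)) {
      fq_stop("supply 'cell_mask' or 'partition' for region classification",
              "validation_error")
    }
    partition <- partition_regions(cell_mask, fraction)
  }
  if (nrow(objs)) {
    objs <- classify_region(objs, partition)
    pr <- pearson_per_object(seg$mask, ref_channel, other_channel)
    objs$pearson <- pr$pearson[match(objs$label, pr$label)]
  } else {
    objs$region <- character(0)
    objs$pearson <- numeric(0)
  }
  list(objects = objs, mask = seg$mask, partition = partition,
       threshold = seg$threshold)
}
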