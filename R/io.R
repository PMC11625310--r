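#' Read a TIFF image or stack as MicroImage(s)
#'
#' Reads a single- or multi-page TIFF. A single page yields one
#' [micro_image()]; a multi-page file yields a list of them (one per
#' page), suitable for [build_kymograph()].
#'
#' @param path TIFF file path.
#' @param pixel_size Micrometres per pixel to attach.
#' @param frame_interval Optional frame interval in seconds.
#' @return A `MicroImage` or list of them.
#' @export
read_micro_tiff <- function(path, pixel_size, frame_interval = NULL) {
  arr <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(arr)) == 2L) {
    return(micro_image(t(arr), pixel_size, frame_interval = frame_interval))
  }
  lapply(seq_len(dim(arr)[3]), function(i) {
    micro_image(t(arr[, , i]), pixel_size, frame_interval = frame_interval)
  })
}

#' Write MicroImage(s) to a (multi-page) TIFF
#'
#' Intensities are scaled by the joint maximum into \[0, 1\] and written
#' as 16-bit TIFF pages.
#'
#' @param imgs A [micro_image()] or list of them (pages).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_micro_tiff <- function(imgs, path) {
  if (inherits(imgs, "MicroImage")) imgs <- list(imgs)
  hi <- max(vapply(imgs, function(im) max(im$data), numeric(1)), 1e-12)
  pages <- lapply(imgs, function(im) t(im$data / hi))
  arr <- EBImage::Image(simplify2array(pages))
  EBImage::writeImage(arr, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' Write a synthetic scene to disk
#'
#' Saves each channel as a TIFF and the complete ground truth
#' (per-object table, parameters, compartment assignment) as a sidecar
#' JSON file, so scenes can be consumed by external tools.
#'
#' @param scene A [generate_fa_scene()] or [generate_clearance_scene()]
#'   result.
#' @param dir Output directory (created if missing).
#' @param name Base file name.
#' @return The directory, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ch in names(scene$channels)) {
    write_micro_tiff(scene$channels[[ch]],
                     file.path(dir, sprintf("%s_%s.tif", name, ch)))
  }
  truth <- list(truth = scene$truth)
  if (!is.null(scene$params)) truth$params <- unclass(scene$params)
  if (!is.null(scene$truth_labels)) {
    write_micro_tiff(
      micro_image(scene$truth_labels$labels / max(max(scene$truth_labels$labels), 1L),
                  scene$truth_labels$pixel_size),
      file.path(dir, sprintf("%s_labels.tif", name)))
  }
  jsonlite::write_json(truth, file.path(dir, sprintf("%s_truth.json", name)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Export per-object results as tidy CSV
#'
#' @param objects Data frame (e.g. from [quantify_adhesions()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_objects_csv <- function(objects, path) {
  utils::write.csv(objects, path, row.names = FALSE)
  invisible(path)
}
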