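#' Write an image stack as multi-frame TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF scaled to \code{[0, 1]}; the scale
#' factor, physical calibration and any ground-truth metadata go to a JSON
#' sidecar next to the TIFF (same path with extension `.json`).
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(stack$frames, 1e-12)
  frames <- lapply(seq_len(n_frames(stack)),
                   function(t) stack$frames[, , t] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  sidecar <- list(pixel_size_um = stack$pixel_size,
                  frame_interval_s = stack$frame_interval,
                  prebleach_count = stack$prebleach_count,
                  intensity_scale = scale,
                  truth = stack$metadata$truth)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (the JSON sidecar is read from the matching
#'   `.json` path).
#' @return an [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  sc <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  arr <- simplify2array(frames) * sc$intensity_scale
  image_stack(arr, pixel_size = sc$pixel_size_um,
              frame_interval = sc$frame_interval_s,
              prebleach_count = sc$prebleach_count,
              metadata = list(truth = sc$truth))
}
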