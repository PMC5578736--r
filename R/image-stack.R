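#' Time-lapse image stack with physical calibration
#'
#' @param frames ny x nx x nt numeric array (rows = y, columns = x) or a
#'   list of equally-sized matrices.
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval s per frame.
#' @param prebleach_count number of leading pre-bleach frames.
#' @param metadata free-form list (synthetic generators store ground truth
#'   here).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval,
                        prebleach_count = 0L, metadata = list()) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) != 3) stop("frames must be a 3-D array")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 prebleach_count = as.integer(prebleach_count),
                 metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d x %d px (%.3g um/px), %d frames (%g s apart), %d pre-bleach\n",
              d[2], d[1], x$pixel_size, d[3], x$frame_interval, x$prebleach_count))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

# times in s relative to the bleach (first post-bleach frame = 0)
stack_times <- function(stack) {
  (seq_len(n_frames(stack)) - stack$prebleach_count - 1L) * stack$frame_interval
}

# logical mask of pixels whose centres lie within a disk; positions in um
pixel_disk_mask <- function(stack, center, diameter) {
  d <- dim(stack$frames)
  px <- stack$pixel_size
  x <- (seq_len(d[2]) - 0.5) * px
  y <- (seq_len(d[1]) - 0.5) * px
  outer((y - center[2])^2, (x - center[1])^2, `+`) <= (diameter / 2)^2
}

# mean intensity inside a mask for every frame
mask_means <- function(stack, mask) {
  nt <- n_frames(stack)
  vapply(seq_len(nt), function(t) mean(stack$frames[, , t][mask]), numeric(1))
}

# convert a frap_sim into a noiseless image_stack with uniform pre-bleach
# frames prepended (intensity = concentration)
sim_to_stack <- function(sim, prebleach_frames = 2L) {
  d <- dim(sim$frames)
  pre <- array(1, dim = c(d[1], d[2], prebleach_frames))
  image_stack(array(c(pre, sim$frames), dim = c(d[1], d[2], prebleach_frames + d[3])),
              pixel_size = sim$grid$spacing,
              frame_interval = sim$times[2] - sim$times[1],
              prebleach_count = prebleach_frames,
              metadata = list(params = sim$params, spec = sim$spec,
                              center = sim$center, mode = sim$mode))
}
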