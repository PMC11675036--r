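#' Construct a frame stack
#'
#' A `frame_stack` is the common in-memory representation of a time-lapse
#' microscopy movie used by all analysis pipelines: a numeric `T x H x W`
#' array of non-negative intensities plus a frame rate. Intensities are in
#' arbitrary camera units; coordinates are 0-based `(row, col)` with row
#' increasing downward (pixel-center convention).
#'
#' @param frames numeric array of dimension `c(T, H, W)` (T >= 2), or a list
#'   of `H x W` matrices that will be stacked along time.
#' @param fps frame rate in Hz (> 0).
#' @param pixel_size micrometers per pixel, or `NULL` for pixel units.
#' @param source free-text provenance string.
#' @return An object of class `frame_stack` with fields `frames`, `fps`,
#'   `pixel_size`, `source`.
#' @examples
#' st <- frame_stack(array(1, c(2, 4, 4)), fps = 100)
#' stack_duration(st)
#' @export
frame_stack <- function(frames, fps, pixel_size = NULL, source = "") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share the same dimensions")
    arr <- array(0, c(length(frames), dims[[1L]][1L], dims[[1L]][2L]))
    for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
    frames <- arr
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a T x H x W array")
  storage.mode(frames) <- "double"
  d <- dim(frames)
  if (d[1L] < 2L || d[2L] < 1L || d[3L] < 1L)
    stop("need T >= 2 frames of at least 1 x 1 pixels")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("intensities must be finite and non-negative")
  structure(
    list(frames = frames, fps = as.numeric(fps),
         pixel_size = pixel_size, source = as.character(source)[1L]),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d px at %g fps (%.3f s)\n",
              d[1L], d[2L], d[3L], x$fps, stack_duration(x)))
  if (!is.null(x$pixel_size))
    cat(sprintf("  pixel size: %g um/px\n", x$pixel_size))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Recording duration in seconds
#'
#' @param stack a [frame_stack()].
#' @return `T / fps` in seconds.
#' @export
stack_duration <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[1L] / stack$fps
}

#' Number of frames
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1L]

#' Extract one frame as an H x W matrix
#' @param stack a [frame_stack()].
#' @param t 0-based frame index.
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(stack, t) {
  stopifnot(inherits(stack, "frame_stack"))
  t <- as.integer(t)
  if (t < 0L || t >= n_frames(stack)) stop("frame index out of range")
  m <- stack$frames[t + 1L, , ]
  dim(m) <- dim(stack$frames)[2:3]
  m
}

# Reshape the movie to a T x (H*W) matrix; column j+1 holds the time trace of
# the pixel with 0-based linear index j = row + col * H (column-major).
.stack_matrix <- function(stack) {
  d <- dim(stack$frames)
  m <- stack$frames
  dim(m) <- c(d[1L], d[2L] * d[3L])
  m
}
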