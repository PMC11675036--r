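#' Load a movie from a multi-page TIFF
#'
#' Reads a multi-page grayscale or RGB TIFF stack into a [frame_stack()].
#' Integer pages are returned on their native scale (0..255 for 8-bit,
#' 0..65535 for 16-bit); floating-point pages are read as stored. RGB pages
#' are converted to grayscale with ITU-R BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B). Frame rate is taken from the JSON
#' sidecar `<path>.json` written by [save_stack()] when present; otherwise
#' `fps_override` is required (baseline TIFF carries no frame-rate tag).
#'
#' AVI/MP4 containers are not readable here; convert such recordings to a
#' multi-page TIFF upstream (e.g. with `ffmpeg` or Fiji) before loading.
#'
#' @param path path to a multi-page TIFF file.
#' @param fps_override frame rate in Hz, used when the file carries none.
#' @param pixel_size optional micrometers per pixel.
#' @return A [frame_stack()].
#' @export
load_stack <- function(path, fps_override = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("avi", "mp4", "mov", "mkv"))
    stop("video containers are not supported; convert '", path,
         "' to a multi-page TIFF first")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("zero-frame container: ", path)
  meta <- .read_sidecar(path)
  fps <- if (!is.null(meta$fps)) meta$fps else fps_override
  if (is.null(fps))
    stop("no frame rate in file metadata; supply fps_override")
  if (is.null(pixel_size) && !is.null(meta$pixel_size))
    pixel_size <- meta$pixel_size
  mats <- lapply(pages, function(p) {
    scale <- meta$scale
    if (is.null(scale)) {
      # foreign TIFF: restore the native integer scale; 32-bit pages are
      # float and already carry their stored values
      bits <- attr(p, "bits.per.sample")
      scale <- if (!is.null(bits) && bits <= 16L) 2^bits - 1 else 1
    }
    v <- unclass(p) * scale
    # integer-typed pages: undo the x/(2^bits-1) normalization exactly
    if (scale %in% c(255, 65535)) v <- round(v)
    .to_grayscale(v)
  })
  frame_stack(mats, fps = fps, pixel_size = pixel_size, source = path)
}

#' Save a movie as a multi-page TIFF
#'
#' Integer-valued stacks within 0..65535 are written as 16-bit pages and
#' round-trip exactly through [load_stack()]. Fractional stacks are scaled
#' into [0, 1] by a power of two and written as 32-bit pages, which
#' quantizes intensities to a relative precision of about `2^-32`. Frame
#' rate, pixel size, and the scale go into a JSON sidecar `<path>.json`
#' (baseline TIFF has no standard frame-rate tag).
#'
#' @param stack a [frame_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  mats <- lapply(seq_len(d[1L]), function(t) get_frame(stack, t - 1L))
  mx <- max(stack$frames)
  integral <- mx <= 65535 && all(stack$frames == round(stack$frames))
  meta <- list(fps = stack$fps)
  if (!is.null(stack$pixel_size)) meta$pixel_size <- stack$pixel_size
  if (integral) {
    tiff::writeTIFF(lapply(mats, `/`, 65535), path,
                    bits.per.sample = 16L, reduce = FALSE)
    meta$scale <- 65535
  } else {
    scale <- 2^max(0, ceiling(log2(mx)))  # power of two keeps division exact
    tiff::writeTIFF(lapply(mats, `/`, scale), path,
                    bits.per.sample = 32L, reduce = FALSE)
    meta$scale <- scale
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) return(list())
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

# BT.601 luma conversion; grayscale input passes through unchanged, so the
# conversion is idempotent. Alpha channels are ignored.
.to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    d <- dim(img)
    g <- if (d[3L] == 1L) img[, , 1L]
         else 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    if (!is.matrix(g)) g <- matrix(g, d[1L], d[2L])
    return(g)
  }
  stop("unsupported image dimensionality: ", paste(dim(img), collapse = "x"))
}

#' Convert an RGB array to grayscale
#'
#' ITU-R BT.601 luma weights; a 2-D matrix is returned unchanged.
#'
#' @param img `H x W` matrix or `H x W x C` array (C = 3 or 4; alpha ignored).
#' @return `H x W` matrix.
#' @export
rgb_to_gray <- function(img) .to_grayscale(img)

#' Write a 2-D map as a tidy CSV
#'
#' One `row,col,value` triplet per pixel (0-based indices, row-major order).
#' Missing values are omitted.
#'
#' @param map2d `H x W` numeric matrix; `NA` marks undefined pixels.
#' @param path output CSV path.
#' @param na_omit drop `NA` cells (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map2d, path, na_omit = TRUE) {
  stopifnot(is.matrix(map2d))
  h <- nrow(map2d); w <- ncol(map2d)
  df <- data.frame(
    row = rep(seq_len(h) - 1L, times = w),
    col = rep(seq_len(w) - 1L, each = h),
    value = as.vector(map2d))
  df <- df[order(df$row, df$col), , drop = FALSE]  # row-major
  if (na_omit) df <- df[!is.na(df$value), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write trajectories as CSV
#'
#' One detection per row: `track_id,frame,row,col` with sub-pixel 0-based
#' coordinates, ordered by track then frame.
#'
#' @param tracks data frame with columns `track_id`, `frame`, `row`, `col`
#'   (as produced by [link_trajectories()] / [track_video()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  need <- c("track_id", "frame", "row", "col")
  stopifnot(all(need %in% names(tracks)))
  df <- tracks[order(tracks$track_id, tracks$frame), need, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a 2-D map as a PNG heat map
#'
#' Values are mapped onto a blue-to-red color ramp over `zlim`; missing
#' pixels are rendered in a neutral gray. Written directly as a raster PNG
#' (one image pixel per map pixel).
#'
#' @param map2d `H x W` numeric matrix, `NA` = missing.
#' @param path output PNG path.
#' @param zlim color scale limits; default the finite data range.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(map2d, path, zlim = NULL) {
  stopifnot(is.matrix(map2d))
  vals <- map2d[is.finite(map2d)]
  if (is.null(zlim))
    zlim <- if (length(vals)) range(vals) else c(0, 1)
  if (zlim[2L] <= zlim[1L]) zlim[2L] <- zlim[1L] + 1
  ramp <- grDevices::colorRamp(c("#2c2c7c", "#00b0e0", "#ffe000", "#d01010"))
  z <- (map2d - zlim[1L]) / (zlim[2L] - zlim[1L])
  z[z < 0] <- 0; z[z > 1] <- 1
  rgb <- array(0.5, c(nrow(map2d), ncol(map2d), 3L))  # neutral gray for NA
  ok <- is.finite(z)
  if (any(ok)) {
    cols <- ramp(z[ok]) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[ok] <- cols[, ch]
      rgb[, , ch] <- plane
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
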