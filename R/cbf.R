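#' Per-pixel activity map by frame differencing
#'
#' Localizes beating regions: each frame in `window` is subtracted from the
#' reference frame (frame 0) and the absolute grayscale changes are averaged
#' per pixel. By default the window is the 2nd through 100th frames of the
#' recording (0-based indices 1..99), which is enough to localize motion from
#' a small amount of data before the full recording is analyzed.
#'
#' @param stack a [frame_stack()].
#' @param window integer vector of 0-based frame indices within `[1, T-1]`;
#'   default `1:min(99, T-1)`.
#' @return An `activity_map`: list with `values` (`H x W`, >= 0, intensity
#'   units), `ref_frame_index` (0), and `window` (the indices used).
#' @export
compute_activity_map <- function(stack, window = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  nt <- n_frames(stack)
  if (is.null(window)) window <- seq_len(min(99L, nt - 1L))
  window <- as.integer(window)
  if (length(window) == 0L) stop("window is empty")
  if (any(window < 1L) || any(window > nt - 1L))
    stop("window indices must lie in [1, T-1]")
  x <- .stack_matrix(stack)
  ref <- x[1L, ]
  dif <- abs(x[window + 1L, , drop = FALSE] -
               matrix(ref, length(window), length(ref), byrow = TRUE))
  vals <- colMeans(dif)
  d <- dim(stack$frames)
  structure(
    list(values = matrix(vals, d[2L], d[3L]),
         ref_frame_index = 0L, window = window),
    class = "activity_map")
}

#' Threshold an activity map into a beating-region mask
#'
#' The threshold is the mean of all activity values; pixels strictly below
#' it are eliminated, the remaining positions are the ciliary beating areas
#' (ties at the mean are retained).
#'
#' @param activity an `activity_map` from [compute_activity_map()], or a
#'   plain numeric matrix of activities.
#' @param threshold optional explicit threshold overriding the mean.
#' @return A `beat_mask`: list with `mask` (`H x W` logical) and
#'   `threshold_value`.
#' @export
threshold_activity <- function(activity, threshold = NULL) {
  vals <- if (inherits(activity, "activity_map")) activity$values else activity
  stopifnot(is.matrix(vals), all(is.finite(vals)))
  thr <- if (is.null(threshold)) mean(vals) else threshold
  structure(list(mask = vals >= thr, threshold_value = thr),
            class = "beat_mask")
}

# Steady-state initial conditions for a transposed direct-form-II filter,
# so that filtering a constant yields the steady-state response immediately
# (no startup transient).
.lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  comp <- rbind(-a[-1L] / a[1L], cbind(diag(1, n - 1L), rep(0, n - 1L)))
  B <- b[-1L] / a[1L] - a[-1L] / a[1L] * b[1L] / a[1L]
  solve(diag(n) - t(comp), B)
}

# IIR filtering of each column of x (order-2, transposed DF-II) with initial
# state zi scaled by the first sample of each column.
.lfilter_cols <- function(b, a, x, zi) {
  nt <- nrow(x)
  y <- x
  z1 <- zi[1L] * x[1L, ]
  z2 <- zi[2L] * x[1L, ]
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1L] * xt + z1
    z1 <- b[2L] * xt - a[2L] * yt + z2
    z2 <- b[3L] * xt - a[3L] * yt
    y[t, ] <- yt
  }
  y
}

# Zero-phase forward-backward filtering of each column with odd-reflection
# end padding; constant columns map to (numerically) zero for a high-pass.
.filtfilt_cols <- function(b, a, x) {
  nt <- nrow(x)
  padlen <- 3L * max(length(a), length(b))
  if (nt <= padlen + 1L)
    stop("trace too short for zero-phase filtering (need > ",
         padlen + 1L, " samples)")
  zi <- .lfilter_zi(b, a)
  first <- matrix(x[1L, ], padlen, ncol(x), byrow = TRUE)
  last <- matrix(x[nt, ], padlen, ncol(x), byrow = TRUE)
  ext <- rbind(2 * first - x[(padlen + 1L):2L, , drop = FALSE],
               x,
               2 * last - x[(nt - 1L):(nt - padlen), , drop = FALSE])
  y <- .lfilter_cols(b, a, ext, zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- .lfilter_cols(b, a, y, zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(padlen + 1L):(padlen + nt), , drop = FALSE]
}

#' Zero-phase high-pass filter a pixel intensity trace
#'
#' Removes baseline drift and illumination trends below `cutoff` before peak
#' counting, without shifting peak positions (forward-backward 2nd-order
#' Butterworth). A constant trace maps to numerical zero; an oscillation
#' well above the cutoff keeps its peak count.
#'
#' @param trace numeric vector (>= 8 samples).
#' @param fps sampling rate in Hz.
#' @param cutoff high-pass cutoff in Hz, `0 < cutoff < fps/2`.
#' @return Filtered trace, same length.
#' @export
highpass_trace <- function(trace, fps, cutoff = 1) {
  if (length(trace) < 8L) stop("trace must have at least 8 samples")
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fps / 2)
    stop("cutoff must satisfy 0 < cutoff < fps/2")
  bf <- signal::butter(2, cutoff / (fps / 2), type = "high")
  drop(.filtfilt_cols(bf$b, bf$a, matrix(trace, ncol = 1L)))
}

# 0-based indices of strict local maxima of x.
.strict_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  which(x[i] > x[i - 1L] & x[i] > x[i + 1L])  # positions within i (1-based-1)
}

# Topographic prominence of the peak at 1-based index p: height above the
# higher of the two valley floors separating it from higher ground (or the
# trace ends).
.prominence <- function(x, p) {
  h <- x[p]
  lmin <- h
  i <- p - 1L
  while (i >= 1L && x[i] <= h) {
    if (x[i] < lmin) lmin <- x[i]
    i <- i - 1L
  }
  rmin <- h
  i <- p + 1L
  n <- length(x)
  while (i <= n && x[i] <= h) {
    if (x[i] < rmin) rmin <- x[i]
    i <- i + 1L
  }
  h - max(lmin, rmin)
}

# Reference peak counter (pure R): strict local maxima with prominence
# >= k * sd(trace) and a minimum spacing, highest peaks claimed first.
.count_peaks_ref <- function(x, prominence_k = 0.5, minsep = 1L) {
  cand <- .strict_maxima(x) + 1L
  if (length(cand) == 0L) return(0L)
  s <- stats::sd(x)
  # an SD at numerical-noise level means a motionless pixel, not a beat
  if (!is.finite(s) || s < 1e-8) return(0L)
  thr <- prominence_k * s
  keep <- cand[vapply(cand, function(p) .prominence(x, p) >= thr, logical(1))]
  if (length(keep) == 0L || minsep <= 1L) return(length(keep))
  ord <- keep[order(-x[keep], keep)]
  taken <- integer(0)
  for (p in ord)
    if (all(abs(taken - p) >= minsep)) taken <- c(taken, p)
  length(taken)
}

#' Estimate frequency of one trace by peak counting
#'
#' Counts intensity peaks over the recording and divides by the recording
#' time. A sample is a peak if it is a strict local maximum with topographic
#' prominence at least `prominence_k` standard deviations of the trace, and
#' at least `ceiling(fps / (2 * f_max))` samples from any higher accepted
#' peak. The result is capped at the Nyquist frequency `fps/2`.
#'
#' @param trace numeric vector (typically high-pass filtered first; >= 3
#'   samples).
#' @param fps sampling rate in Hz.
#' @param prominence_k prominence threshold in units of the trace SD.
#' @param f_max highest resolvable frequency used to set the minimum peak
#'   spacing; default `fps/2`.
#' @return Frequency in Hz (`peak count / duration`, capped at `fps/2`).
#' @export
count_peaks <- function(trace, fps, prominence_k = 0.5, f_max = fps / 2) {
  if (length(trace) < 3L) stop("trace must have at least 3 samples")
  minsep <- as.integer(ceiling(fps / (2 * f_max)))
  n <- .count_peaks_ref(trace, prominence_k = prominence_k, minsep = minsep)
  duration <- length(trace) / fps
  min(n / duration, fps / 2)
}

#' Per-pixel ciliary beat frequency map
#'
#' For every pixel inside the beating mask, the full-length raw intensity
#' trace is high-pass filtered and its peaks counted; the count divided by
#' the recording duration is the pixel's CBF (each pixel treated as one
#' cilium). Pixels outside the mask are `NA`. The whole recording is used
#' for counting, independent of the (shorter) localization window.
#'
#' @param stack a [frame_stack()].
#' @param mask a `beat_mask` from [threshold_activity()], or an `H x W`
#'   logical matrix.
#' @param cutoff high-pass cutoff in Hz (default 1); `NA` to skip filtering.
#' @param prominence_k peak prominence threshold in trace-SD units.
#' @return A `cbf_map`: list with `frequency` (`H x W` Hz, `NA` off-mask),
#'   `fps`, `duration` (s).
#' @export
compute_cbf_map <- function(stack, mask, cutoff = 1, prominence_k = 0.5) {
  stopifnot(inherits(stack, "frame_stack"))
  m <- if (inherits(mask, "beat_mask")) mask$mask else mask
  d <- dim(stack$frames)
  if (!is.logical(m) || !identical(dim(m), d[2:3]))
    stop("mask shape does not match stack frames")
  fps <- stack$fps
  duration <- stack_duration(stack)
  freq <- matrix(NA_real_, d[2L], d[3L])
  sel <- which(m)
  if (length(sel)) {
    x <- .stack_matrix(stack)[, sel, drop = FALSE]
    if (!is.na(cutoff)) {
      bf <- signal::butter(2, cutoff / (fps / 2), type = "high")
      x <- .filtfilt_cols(bf$b, bf$a, x)
    }
    counts <- count_peaks_bulk(x, prominence_k, 1L)
    freq[sel] <- pmin(counts / duration, fps / 2)
  }
  structure(list(frequency = freq, fps = fps, duration = duration),
            class = "cbf_map")
}

#' Frequency-distribution histogram of a CBF map
#'
#' Percentage of beating pixels (cilia) per frequency bin; bins cover
#' `[0, fps/2]`, left-closed, with the last bin closed on both sides.
#'
#' @param cbf a `cbf_map` from [compute_cbf_map()].
#' @param bin_width bin width in Hz (> 0).
#' @return A `cbf_distribution`: list with `bin_edges`, `counts`, `percent`,
#'   `n_pixels`.
#' @export
cbf_histogram <- function(cbf, bin_width = 1) {
  stopifnot(inherits(cbf, "cbf_map"))
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin width must be positive")
  nyq <- cbf$fps / 2
  edges <- seq(0, by = bin_width, length.out = ceiling(nyq / bin_width) + 1L)
  if (edges[length(edges)] < nyq) edges <- c(edges, edges[length(edges)] + bin_width)
  f <- cbf$frequency[!is.na(cbf$frequency)]
  idx <- findInterval(f, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  n <- length(f)
  pct <- if (n > 0) 100 * counts / n else rep(0, length(counts))
  structure(list(bin_edges = edges, counts = counts, percent = pct,
                 n_pixels = n),
            class = "cbf_distribution")
}

#' Modal frequency of a CBF map
#'
#' Most frequent defined CBF value, optionally restricted to a region;
#' ties resolved toward the lowest frequency.
#'
#' @param cbf a `cbf_map`.
#' @param region optional `H x W` logical matrix restricting the pixels.
#' @return Modal frequency in Hz, or `NA` if no pixels are defined.
#' @export
modal_frequency <- function(cbf, region = NULL) {
  f <- cbf$frequency
  if (!is.null(region)) f <- f[region]
  f <- f[!is.na(f)]
  if (length(f) == 0L) return(NA_real_)
  tab <- table(f)
  as.numeric(names(tab)[which.max(tab)])
}

#' Render a CBF map as a PNG heat map with a Hz color scale
#'
#' @param cbf a `cbf_map`.
#' @param path output PNG path.
#' @param zlim color scale limits in Hz; the fixed default `c(0, 30)` keeps
#'   heat maps comparable across videos.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
render_cbf_heatmap <- function(cbf, path, zlim = c(0, 30),
                               width = 640, height = 560) {
  stopifnot(inherits(cbf, "cbf_map"))
  f <- cbf$frequency
  pal <- grDevices::colorRampPalette(
    c("#2c2c7c", "#00b0e0", "#ffe000", "#d01010"))(64)
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::layout(matrix(1:2, 1, 2), widths = c(5, 1))
  graphics::par(mar = c(2, 2, 2, 1))
  z <- t(f)[, nrow(f):1, drop = FALSE]  # image() draws x right, y up
  z[z < zlim[1L]] <- zlim[1L]; z[z > zlim[2L]] <- zlim[2L]
  graphics::image(z, col = pal, zlim = zlim, axes = FALSE,
                  main = "Ciliary beat frequency", useRaster = TRUE)
  graphics::par(mar = c(2, 1, 2, 3))
  graphics::image(1, seq(zlim[1L], zlim[2L], length.out = 64),
                  matrix(seq(zlim[1L], zlim[2L], length.out = 64), 1),
                  col = pal, axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("Hz", side = 3, line = 0.2, cex = 0.9)
  invisible(path)
}

#' Run the full CBF pipeline on a movie
#'
#' Localize beating regions (activity map + mean threshold), compute the
#' per-pixel CBF map over the full recording, and summarize the frequency
#' distribution.
#'
#' @param stack a [frame_stack()].
#' @param loc_window 0-based frame indices for localization (default
#'   frames 1..99).
#' @param cutoff high-pass cutoff in Hz.
#' @param prominence_k peak prominence threshold in trace-SD units.
#' @param bin_width histogram bin width in Hz.
#' @return List with `activity`, `mask`, `cbf`, `histogram`, and `summary`
#'   (threshold value, number of beating pixels, modal/mean/median CBF in Hz).
#' @export
analyze_cbf <- function(stack, loc_window = NULL, cutoff = 1,
                        prominence_k = 0.5, bin_width = 1) {
  act <- compute_activity_map(stack, window = loc_window)
  mask <- threshold_activity(act)
  cbf <- compute_cbf_map(stack, mask, cutoff = cutoff,
                         prominence_k = prominence_k)
  hist <- cbf_histogram(cbf, bin_width = bin_width)
  f <- cbf$frequency[!is.na(cbf$frequency)]
  summary <- list(
    threshold_value = mask$threshold_value,
    n_beating_pixels = length(f),
    modal_cbf_hz = modal_frequency(cbf),
    mean_cbf_hz = if (length(f)) mean(f) else NA_real_,
    median_cbf_hz = if (length(f)) stats::median(f) else NA_real_)
  list(activity = act, mask = mask, cbf = cbf, histogram = hist,
       summary = summary)
}
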