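# Mucociliary-clearance particle tracking: detect fluorescent particle
# centroids per frame, link them into trajectories by nearest neighbor,
# drop low-movement (cilia-stuck) trajectories, and summarize clearance
# speed and directionality.

# 8-connected component labeling of a logical matrix (the detection rule
# groups each foreground pixel with its eight surrounding pixel positions).
.label8 <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  todo <- which(fg)
  nlab <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    nlab <- nlab + 1L
    frontier <- seed
    lab[seed] <- nlab
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L
      cc <- (frontier - 1L) %/% h + 1L
      nb <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        nr <- r + dr; nc <- cc + dc
        ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
        if (any(ok)) nb <- c(nb, (nc[ok] - 1L) * h + nr[ok])
      }
      nb <- unique(nb)
      nb <- nb[fg[nb] & lab[nb] == 0L]
      lab[nb] <- nlab
      frontier <- nb
    }
  }
  lab
}

#' Detect fluorescent particles in one frame
#'
#' Binarizes the frame, groups foreground pixels into 8-connected
#' components, discards components smaller than `min_area`, and returns the
#' intensity-weighted center of mass of each component at sub-pixel
#' precision (0-based row/col, pixel-center convention).
#'
#' @param frame `H x W` grayscale matrix.
#' @param threshold `"otsu"` (Otsu's method on the frame histogram, the
#'   default), `"percentile"` (see `percentile`), or a numeric intensity
#'   cutoff. Pixels strictly above the cutoff are foreground.
#' @param min_area minimum component area in pixels.
#' @param percentile used when `threshold = "percentile"`.
#' @return data frame with columns `row`, `col`, `mass` (summed intensity),
#'   `area` (pixel count); zero rows when nothing is detected.
#' @export
detect_particles <- function(frame, threshold = "otsu", min_area = 2,
                             percentile = 0.995) {
  stopifnot(is.matrix(frame))
  thr <- particle_threshold(frame, threshold, percentile)
  fg <- frame > thr
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      mass = numeric(0), area = integer(0))
  if (!any(fg)) return(empty)
  lab <- .label8(fg)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  h <- nrow(frame)
  r0 <- (idx - 1L) %% h        # 0-based row
  c0 <- (idx - 1L) %/% h       # 0-based col
  wgt <- frame[idx]
  mass <- as.vector(tapply(wgt, labs, sum))
  area <- as.vector(tapply(wgt, labs, length))
  row <- as.vector(tapply(wgt * r0, labs, sum)) / mass
  col <- as.vector(tapply(wgt * c0, labs, sum)) / mass
  keep <- area >= min_area
  out <- data.frame(row = row, col = col, mass = mass,
                    area = as.integer(area))[keep, , drop = FALSE]
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve a detection threshold for a frame
#'
#' @param frame `H x W` matrix.
#' @param threshold `"otsu"`, `"percentile"`, or a numeric cutoff.
#' @param percentile quantile used for `"percentile"`.
#' @return Numeric intensity cutoff.
#' @export
particle_threshold <- function(frame, threshold = "otsu",
                               percentile = 0.995) {
  if (is.numeric(threshold)) return(threshold)
  if (identical(threshold, "percentile"))
    return(as.numeric(stats::quantile(frame, percentile)))
  if (identical(threshold, "otsu")) {
    mx <- max(frame)
    if (mx <= 0) return(0)
    EBImage::otsu(frame / mx, range = c(0, 1), levels = 256L) * mx
  } else stop("unknown threshold mode: ", threshold)
}

#' Link per-frame detections into trajectories
#'
#' Greedy mutually-exclusive nearest-neighbor assignment from each frame to
#' the next within `search_radius`; unmatched detections seed new tracks; a
#' track unmatched for more than `max_gap` consecutive frames is closed.
#' Ties (equidistant candidates) are resolved toward the lowest `(row, col)`
#' so linking is deterministic.
#'
#' @param detections data frame with columns `frame` (integer), `row`,
#'   `col`, and optionally `mass`, `area`.
#' @param search_radius maximum per-step displacement in px.
#' @param max_gap frames a track may go undetected before it is closed
#'   (default 0: strictly consecutive).
#' @return data frame `track_id, frame, row, col, mass, area`, ordered by
#'   track then frame.
#' @export
link_trajectories <- function(detections, search_radius = 10, max_gap = 0) {
  if (nrow(detections) == 0L)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      row = numeric(0), col = numeric(0),
                      mass = numeric(0), area = integer(0)))
  if (is.unsorted(detections$frame))
    detections <- detections[order(detections$frame), , drop = FALSE]
  if (any(detections$frame != floor(detections$frame)) ||
      any(detections$frame < 0))
    stop("frame indices must be non-negative integers")
  if (!"mass" %in% names(detections)) detections$mass <- NA_real_
  if (!"area" %in% names(detections)) detections$area <- NA_integer_
  frames <- sort(unique(detections$frame))
  # active track state
  tr_id <- integer(0); tr_row <- numeric(0); tr_col <- numeric(0)
  tr_last <- integer(0)
  next_id <- 1L
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    det <- detections[detections$frame == f, , drop = FALSE]
    det <- det[order(det$row, det$col), , drop = FALSE]
    nd <- nrow(det)
    alive <- which(tr_last >= f - 1L - max_gap)
    assigned <- rep(NA_integer_, nd)
    if (length(alive) && nd) {
      dr <- outer(tr_row[alive], det$row, "-")
      dc <- outer(tr_col[alive], det$col, "-")
      dist <- sqrt(dr * dr + dc * dc)
      cand <- which(dist <= search_radius, arr.ind = TRUE)
      if (nrow(cand)) {
        o <- order(dist[cand],
                   tr_row[alive][cand[, 1L]], tr_col[alive][cand[, 1L]],
                   det$row[cand[, 2L]], det$col[cand[, 2L]])
        used_t <- logical(length(alive)); used_d <- logical(nd)
        for (i in o) {
          ti <- cand[i, 1L]; dj <- cand[i, 2L]
          if (used_t[ti] || used_d[dj]) next
          used_t[ti] <- TRUE; used_d[dj] <- TRUE
          assigned[dj] <- alive[ti]
        }
      }
    }
    new <- which(is.na(assigned))
    for (j in new) {
      tr_id <- c(tr_id, next_id)
      tr_row <- c(tr_row, 0); tr_col <- c(tr_col, 0); tr_last <- c(tr_last, 0L)
      assigned[j] <- length(tr_id)
      next_id <- next_id + 1L
    }
    tr_row[assigned] <- det$row
    tr_col[assigned] <- det$col
    tr_last[assigned] <- f
    out[[k]] <- data.frame(track_id = tr_id[assigned], frame = det$frame,
                           row = det$row, col = det$col,
                           mass = det$mass, area = det$area)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$track_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-trajectory summary statistics
#'
#' Computes, for each track: path length (sum of step distances, px), net
#' displacement and its direction, mean speed (path length over the spanned
#' duration) and net speed (net displacement over the spanned duration).
#' Directions are degrees counterclockwise with 0 deg = +col (right) after
#' flipping the row axis, so 90 deg = up on screen.
#'
#' @param tracks data frame from [link_trajectories()].
#' @param fps frame rate in Hz.
#' @param dims optional `c(H, W)` for border flagging.
#' @param border_margin px from the edge within which a detection counts as
#'   border-touching.
#' @return data frame with one row per track: `track_id`, `n`,
#'   `first_frame`, `last_frame`, `path_length`, `net_drow`, `net_dcol`,
#'   `net_displacement`, `net_direction`, `mean_speed`, `net_speed`,
#'   `touches_border`.
#' @export
trajectory_stats <- function(tracks, fps, dims = NULL, border_margin = 1) {
  ids <- unique(tracks$track_id)
  res <- lapply(ids, function(id) {
    tt <- tracks[tracks$track_id == id, , drop = FALSE]
    n <- nrow(tt)
    steps <- if (n > 1L)
      sqrt(diff(tt$row)^2 + diff(tt$col)^2) else numeric(0)
    path <- sum(steps)
    drow <- tt$row[n] - tt$row[1L]
    dcol <- tt$col[n] - tt$col[1L]
    net <- sqrt(drow^2 + dcol^2)
    dir <- if (net > 0) (atan2(-drow, dcol) * 180 / pi) %% 360 else NA_real_
    dur <- (tt$frame[n] - tt$frame[1L]) / fps
    border <- if (is.null(dims)) NA else
      any(tt$row < border_margin | tt$col < border_margin |
            tt$row > dims[1L] - 1 - border_margin |
            tt$col > dims[2L] - 1 - border_margin)
    data.frame(track_id = id, n = n,
               first_frame = tt$frame[1L], last_frame = tt$frame[n],
               path_length = path, net_drow = drow, net_dcol = dcol,
               net_displacement = net, net_direction = dir,
               mean_speed = if (dur > 0) path / dur else 0,
               net_speed = if (dur > 0) net / dur else 0,
               touches_border = border)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Partition trajectories into retained and eliminated sets
#'
#' Particles adhered to the cilia beat in place and are spuriously "moving";
#' trajectories whose total path length fails to reach `fraction` of the
#' average path length over all trajectories are eliminated. When the mean
#' movement is zero (a fully static video) everything is retained.
#'
#' @param stats data frame from [trajectory_stats()].
#' @param fraction cutoff as a fraction of the mean path length, in (0, 1);
#'   default 0.5.
#' @return List with `retained`, `eliminated` (with an `reason` column),
#'   `mean_path_length`, `cutoff`.
#' @export
filter_trajectories <- function(stats, fraction = 0.5) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)")
  if (is.null(stats) || nrow(stats) == 0L)
    return(list(retained = stats, eliminated = cbind(stats, reason = character(0)),
                mean_path_length = NA_real_, cutoff = NA_real_))
  mp <- mean(stats$path_length)
  cutoff <- fraction * mp
  drop <- if (mp == 0) rep(FALSE, nrow(stats)) else stats$path_length < cutoff
  eliminated <- stats[drop, , drop = FALSE]
  if (nrow(eliminated))
    eliminated$reason <- sprintf("path_length %.3g < %.3g (%.0f%% of mean %.3g)",
                                 eliminated$path_length, cutoff,
                                 100 * fraction, mp)
  else eliminated$reason <- character(0)
  list(retained = stats[!drop, , drop = FALSE], eliminated = eliminated,
       mean_path_length = mp, cutoff = cutoff)
}

#' Directional rose histogram of retained trajectories
#'
#' Each trajectory contributes its net direction once (or weighted by its
#' net displacement). Angles follow the package convention: degrees
#' counterclockwise, 0 deg = rightward, 90 deg = up on screen. Trajectories
#' with zero net displacement are binned at 0 deg so the rose total always
#' matches the retained set.
#'
#' @param stats retained-trajectory data frame (needs `net_direction`,
#'   `net_displacement`).
#' @param n_bins number of angular sectors (>= 4); default 16 (22.5 deg).
#' @param weighting `"count"` (default) or `"displacement"`.
#' @return List with `breaks` (degrees, length `n_bins + 1`), `weight` (per
#'   sector), `n` (trajectories binned).
#' @export
rose_histogram <- function(stats, n_bins = 16, weighting = c("count", "displacement")) {
  weighting <- match.arg(weighting)
  if (n_bins < 4L) stop("n_bins must be at least 4")
  breaks <- seq(0, 360, length.out = n_bins + 1L)
  width <- 360 / n_bins
  if (is.null(stats) || nrow(stats) == 0L)
    return(list(breaks = breaks, weight = rep(0, n_bins), n = 0L))
  dir <- stats$net_direction
  dir[is.na(dir)] <- 0
  idx <- pmin(floor(dir / width) + 1L, n_bins)
  w <- if (weighting == "count") rep(1, nrow(stats)) else stats$net_displacement
  weight <- vapply(seq_len(n_bins), function(b) sum(w[idx == b]), numeric(1))
  list(breaks = breaks, weight = weight, n = nrow(stats))
}

#' Test whether a rose sector brackets a direction
#'
#' Closed-interval membership on the circle: an angle on a sector edge
#' belongs to both adjacent sectors, and the 0/360 wrap is respected
#' (the sector ending at 360 degrees also brackets 0).
#'
#' @param rose output of [rose_histogram()].
#' @param bin 1-based sector index.
#' @param degrees direction in degrees.
#' @return `TRUE` if the sector brackets the direction.
#' @export
rose_bin_contains <- function(rose, bin, degrees) {
  lo <- rose$breaks[bin]; hi <- rose$breaks[bin + 1L]
  d <- degrees %% 360
  (lo <= d && d <= hi) || (lo <= d + 360 && d + 360 <= hi)
}

#' Track a fluorescent-particle movie end to end
#'
#' The detection threshold is fixed from the first frame (per the standard
#' acquisition where the field is selected before recording), then every
#' frame is segmented, detections are linked into trajectories, low-movement
#' trajectories are eliminated, and the retained set is summarized as
#' displacement-vs-time curves, a rose diagram, and a mean clearance speed.
#'
#' Two speeds are reported: `mean_speed` (clearance transport rate: net
#' displacement over elapsed time, robust to localization jitter) and
#' `mean_path_speed` (total path length over elapsed time).
#'
#' @param stack a [frame_stack()].
#' @param threshold,min_area,percentile see [detect_particles()].
#' @param search_radius,max_gap see [link_trajectories()].
#' @param filter_fraction see [filter_trajectories()].
#' @param rose_bins,rose_weighting see [rose_histogram()].
#' @param drop_border_tracks drop trajectories that touch the image border
#'   (default `FALSE`: kept and flagged).
#' @return A `tracking_summary`: list with `tracks` (all detections with
#'   track ids), `stats`, `retained`, `eliminated`, `rose`,
#'   `displacement_curves` (track_id, time_s, cumulative_px), and `summary`
#'   (counts, mean speeds in px/s and optionally um/s, modal direction).
#' @export
track_video <- function(stack, threshold = "otsu", min_area = 2,
                        percentile = 0.995, search_radius = 10, max_gap = 0,
                        filter_fraction = 0.5, rose_bins = 16,
                        rose_weighting = "count",
                        drop_border_tracks = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  thr <- particle_threshold(get_frame(stack, 0L), threshold, percentile)
  det <- lapply(seq_len(d[1L]) - 1L, function(t) {
    p <- detect_particles(get_frame(stack, t), threshold = thr,
                          min_area = min_area)
    if (nrow(p)) cbind(frame = t, p) else NULL
  })
  det <- do.call(rbind, det)
  empty <- list(tracks = NULL, stats = NULL,
                retained = NULL, eliminated = NULL,
                rose = rose_histogram(NULL, rose_bins),
                displacement_curves = NULL,
                summary = list(threshold_value = thr, n_tracks = 0L,
                               n_retained = 0L, n_eliminated = 0L,
                               mean_speed_px_s = NA_real_,
                               mean_path_speed_px_s = NA_real_,
                               modal_direction_deg = NA_real_))
  class(empty) <- "tracking_summary"
  if (is.null(det) || nrow(det) == 0L) return(empty)
  tracks <- link_trajectories(det, search_radius = search_radius,
                              max_gap = max_gap)
  stats <- trajectory_stats(tracks, fps = stack$fps, dims = d[2:3])
  if (drop_border_tracks) {
    keep_ids <- stats$track_id[!stats$touches_border]
    stats <- stats[!stats$touches_border, , drop = FALSE]
    tracks <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
    if (nrow(stats) == 0L) return(empty)
  }
  part <- filter_trajectories(stats, fraction = filter_fraction)
  rose <- rose_histogram(part$retained, n_bins = rose_bins,
                         weighting = rose_weighting)
  curves <- NULL
  if (nrow(part$retained)) {
    curves <- do.call(rbind, lapply(part$retained$track_id, function(id) {
      tt <- tracks[tracks$track_id == id, , drop = FALSE]
      steps <- c(0, cumsum(sqrt(diff(tt$row)^2 + diff(tt$col)^2)))
      data.frame(track_id = id,
                 time_s = (tt$frame - tt$frame[1L]) / stack$fps,
                 cumulative_px = steps)
    }))
  }
  ret <- part$retained
  modal_dir <- NA_real_
  if (rose$n > 0) {
    b <- which.max(rose$weight)
    modal_dir <- (rose$breaks[b] + rose$breaks[b + 1L]) / 2
  }
  mean_speed <- if (nrow(ret)) mean(ret$net_speed) else NA_real_
  mean_path_speed <- if (nrow(ret)) mean(ret$mean_speed) else NA_real_
  summary <- list(
    threshold_value = thr,
    n_tracks = nrow(stats),
    n_retained = nrow(ret),
    n_eliminated = nrow(part$eliminated),
    mean_path_length_px = part$mean_path_length,
    filter_cutoff_px = part$cutoff,
    mean_speed_px_s = mean_speed,
    mean_path_speed_px_s = mean_path_speed,
    modal_direction_deg = modal_dir)
  if (!is.null(stack$pixel_size)) {
    summary$mean_speed_um_s <- mean_speed * stack$pixel_size
    summary$mean_path_speed_um_s <- mean_path_speed * stack$pixel_size
  }
  structure(list(tracks = tracks, stats = stats, retained = ret,
                 eliminated = part$eliminated, rose = rose,
                 displacement_curves = curves, summary = summary),
            class = "tracking_summary")
}

#' @export
print.tracking_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("tracking_summary: %d tracks (%d retained, %d eliminated)\n",
              s$n_tracks, s$n_retained, s$n_eliminated))
  if (!is.na(s$mean_speed_px_s))
    cat(sprintf("  mean clearance speed: %.2f px/s; modal direction: %.1f deg\n",
                s$mean_speed_px_s, s$modal_direction_deg))
  invisible(x)
}

#' Plot a rose diagram to PNG
#'
#' @param rose output of [rose_histogram()].
#' @param path output PNG path.
#' @param width,height device size in px.
#' @return `path`, invisibly.
#' @export
plot_rose_png <- function(rose, path, width = 480, height = 480) {
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  rmax <- max(rose$weight, 1)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = "Trajectory directionality (0 deg = right, ccw)")
  th <- seq(0, 2 * pi, length.out = 181)
  for (frac in c(0.5, 1))
    graphics::lines(rmax * frac * cos(th), rmax * frac * sin(th),
                    col = "gray80")
  nb <- length(rose$weight)
  for (b in seq_len(nb)) {
    if (rose$weight[b] <= 0) next
    a0 <- rose$breaks[b] * pi / 180
    a1 <- rose$breaks[b + 1L] * pi / 180
    aa <- seq(a0, a1, length.out = 12)
    r <- rose$weight[b]
    graphics::polygon(c(0, r * cos(aa), 0), c(0, r * sin(aa), 0),
                      col = "#00b0e080", border = "#006080")
  }
  invisible(path)
}

#' Plot retained trajectories over the field to PNG
#'
#' @param summary a `tracking_summary` from [track_video()].
#' @param dims `c(H, W)` of the field in px.
#' @param path output PNG path.
#' @param width,height device size in px.
#' @return `path`, invisibly.
#' @export
plot_trajectories_png <- function(summary, dims, path,
                                  width = 560, height = 560) {
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(3, 3, 2, 1))
  graphics::plot(NA, xlim = c(0, dims[2L]), ylim = c(dims[1L], 0),
                 xlab = "col (px)", ylab = "row (px)",
                 main = "Retained particle trajectories")
  if (!is.null(summary$retained) && nrow(summary$retained)) {
    cols <- grDevices::hcl.colors(max(2L, nrow(summary$retained)), "Dark 3")
    for (i in seq_len(nrow(summary$retained))) {
      id <- summary$retained$track_id[i]
      tt <- summary$tracks[summary$tracks$track_id == id, , drop = FALSE]
      graphics::lines(tt$col, tt$row, col = cols[i])
      graphics::points(tt$col[1L], tt$row[1L], pch = 16, cex = 0.5,
                       col = cols[i])
    }
  }
  invisible(path)
}
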