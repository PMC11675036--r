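# Ground-truthed synthetic scenes: spatially patchy pixel-intensity
# oscillations for the CBF pipeline, drifting fluorescent spots with
# stuck-to-cilia decoys for the tracking pipeline, and two-class texture
# tiles for the cross-validation harness. Defaults mirror the acquisition
# conditions of the real recordings (cilia: 100 fps / 10 s; particles:
# 30 fps) at a reduced 256 x 256 field for tractable simulation.

#' Default oscillating-region layout for cilia scenes
#'
#' Three 64 x 64 regions at 9, 14, and 20 Hz, spanning the physiologic
#' ciliary beating range (~9-20 Hz in human airway epithelium).
#'
#' @param amplitude oscillation amplitude in intensity units.
#' @return List of region specs (`rect` = 0-based `c(row0, col0, h, w)`,
#'   `freq` Hz, `amp`, `phase` rad).
#' @export
default_cilia_regions <- function(amplitude = 30) {
  list(
    list(rect = c(32L, 32L, 64L, 64L), freq = 9, amp = amplitude, phase = 0),
    list(rect = c(32L, 160L, 64L, 64L), freq = 14, amp = amplitude,
         phase = pi / 3),
    list(rect = c(160L, 96L, 64L, 64L), freq = 20, amp = amplitude,
         phase = 2 * pi / 3))
}

#' Generate a synthetic ciliary-beating movie with ground truth
#'
#' Pixels inside each region oscillate as
#' `baseline + amp * sin(2 pi f t + phase) + drift + noise`; pixels outside
#' carry baseline, drift, and noise only. The paired ground truth records
#' the true per-pixel frequency map, so the CBF pipeline can be validated
#' by parameter recovery.
#'
#' @param H,W field size in px.
#' @param fps frame rate in Hz.
#' @param duration recording length in s.
#' @param regions list of region specs (see [default_cilia_regions()]).
#' @param baseline background intensity.
#' @param noise_sigma SD of per-pixel Gaussian noise (default 5% of the
#'   first region's amplitude).
#' @param drift_slope linear illumination drift in intensity/s.
#' @param seed RNG seed.
#' @param enforce_nyquist error when a region frequency reaches `fps/2`
#'   (default); disable only to study aliasing behavior.
#' @return List with `stack` (a [frame_stack()]) and `truth` (list:
#'   `frequency_map` H x W Hz with 0 outside regions, `region_masks`,
#'   `regions`).
#' @export
generate_cilia_video <- function(H = 256, W = 256, fps = 100, duration = 10,
                                 regions = default_cilia_regions(),
                                 baseline = 120, noise_sigma = NULL,
                                 drift_slope = 0, seed = 1,
                                 enforce_nyquist = TRUE) {
  if (is.null(noise_sigma))
    noise_sigma <- 0.05 * (if (length(regions)) regions[[1L]]$amp else 1)
  nt <- round(fps * duration)
  tvec <- (seq_len(nt) - 1L) / fps
  freq_map <- matrix(0, H, W)
  masks <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    rg <- regions[[i]]
    rg$rect <- as.integer(unlist(rg$rect))  # tolerate YAML-parsed configs
    regions[[i]] <- rg
    if (enforce_nyquist && rg$freq >= fps / 2)
      stop("region frequency ", rg$freq, " Hz is at or above Nyquist (",
           fps / 2, " Hz)")
    r <- rg$rect
    if (r[1L] < 0 || r[2L] < 0 || r[1L] + r[3L] > H || r[2L] + r[4L] > W)
      stop("region ", i, " exceeds field bounds")
    m <- matrix(FALSE, H, W)
    m[(r[1L] + 1L):(r[1L] + r[3L]), (r[2L] + 1L):(r[2L] + r[4L])] <- TRUE
    masks[[i]] <- m
    freq_map[m] <- rg$freq
  }
  x <- .with_seed(seed, {
    arr <- array(stats::rnorm(nt * H * W, mean = 0, sd = noise_sigma),
                 c(nt, H, W))
    arr <- arr + baseline + drift_slope * tvec  # recycles over time axis
    dim(arr) <- c(nt, H * W)
    for (i in seq_along(regions)) {
      rg <- regions[[i]]
      osc <- rg$amp * sin(2 * pi * rg$freq * tvec + rg$phase)
      sel <- which(masks[[i]])
      arr[, sel] <- arr[, sel] + osc
    }
    dim(arr) <- c(nt, H, W)
    arr[arr < 0] <- 0
    arr
  })
  stack <- frame_stack(x, fps = fps, source = "synthetic cilia scene")
  truth <- list(frequency_map = freq_map, region_masks = masks,
                regions = regions, noise_sigma = noise_sigma,
                baseline = baseline, drift_slope = drift_slope, seed = seed)
  list(stack = stack, truth = truth)
}

# Minimum distance over t in [0, tmax] between two points moving linearly.
.min_pair_dist <- function(p0, v0, p1, v1, tmax) {
  d0 <- p0 - p1
  dv <- v0 - v1
  a <- sum(dv * dv)
  tstar <- if (a == 0) 0 else max(0, min(tmax, -sum(d0 * dv) / a))
  min(sqrt(sum((d0 + 0 * dv)^2)), sqrt(sum((d0 + tstar * dv)^2)),
      sqrt(sum((d0 + tmax * dv)^2)))
}

#' Default mover layout for particle scenes
#'
#' Positions are drawn under `seed` inside a margin that keeps every path
#' in bounds for the whole recording, with pairwise separations kept above
#' `min_sep` at all times so identities cannot swap.
#'
#' @param n_movers,n_decoys particle counts.
#' @param H,W field size (px).
#' @param n_frames recording length in frames.
#' @param speed mover speed in px/frame.
#' @param direction mover heading in degrees (ccw, 0 = right, 90 = up on
#'   screen).
#' @param min_sep minimum pairwise distance (px) maintained throughout.
#' @param seed RNG seed.
#' @return List with data frames `movers` (`row0, col0, speed, direction`)
#'   and `decoys` (`row0, col0`).
#' @export
place_particles <- function(n_movers = 20, n_decoys = 5, H = 256, W = 256,
                            n_frames = 60, speed = 1.5, direction = 45,
                            min_sep = 16, seed = 1) {
  th <- direction * pi / 180
  v <- c(-speed * sin(th), speed * cos(th))  # (drow, dcol) per frame
  tmax <- n_frames - 1L
  margin <- 6
  lo <- c(margin, margin)
  hi <- c(H - 1 - margin, W - 1 - margin)
  # start box such that start + tmax * v stays inside [lo, hi]
  slo <- pmax(lo, lo - tmax * v)
  shi <- pmin(hi, hi - tmax * v)
  if (any(shi <= slo)) stop("field too small for the requested motion")
  pos <- list(); vel <- list()
  .with_seed(seed, {
    draw <- function(box_lo, box_hi, vv) {
      for (try in 1:2000) {
        p <- c(stats::runif(1, box_lo[1L], box_hi[1L]),
               stats::runif(1, box_lo[2L], box_hi[2L]))
        ok <- TRUE
        for (j in seq_along(pos))
          if (.min_pair_dist(p, vv, pos[[j]], vel[[j]], tmax) < min_sep) {
            ok <- FALSE; break
          }
        if (ok) return(p)
      }
      stop("could not place particles with the requested separation")
    }
    for (i in seq_len(n_movers)) {
      p <- draw(slo, shi, v)
      pos[[length(pos) + 1L]] <- p; vel[[length(vel) + 1L]] <- v
    }
    for (i in seq_len(n_decoys)) {
      p <- draw(lo, hi, c(0, 0))
      pos[[length(pos) + 1L]] <- p; vel[[length(vel) + 1L]] <- c(0, 0)
    }
  })
  movers <- if (n_movers > 0)
    data.frame(row0 = vapply(pos[seq_len(n_movers)], `[`, numeric(1), 1L),
               col0 = vapply(pos[seq_len(n_movers)], `[`, numeric(1), 2L),
               speed = speed, direction = direction)
  else data.frame(row0 = numeric(0), col0 = numeric(0),
                  speed = numeric(0), direction = numeric(0))
  decoys <- if (n_decoys > 0)
    data.frame(row0 = vapply(pos[n_movers + seq_len(n_decoys)], `[`,
                             numeric(1), 1L),
               col0 = vapply(pos[n_movers + seq_len(n_decoys)], `[`,
                             numeric(1), 2L))
  else data.frame(row0 = numeric(0), col0 = numeric(0))
  list(movers = movers, decoys = decoys)
}

# Render a Gaussian spot of the given peak intensity into frame (in place
# arithmetic on a local window; sigma in px, center 0-based sub-pixel).
.render_spot <- function(frame, row, col, intensity, sigma) {
  h <- nrow(frame); w <- ncol(frame)
  win <- ceiling(4 * sigma)
  r0 <- max(0L, floor(row) - win); r1 <- min(h - 1L, ceiling(row) + win)
  c0 <- max(0L, floor(col) - win); c1 <- min(w - 1L, ceiling(col) + win)
  if (r1 < r0 || c1 < c0) return(frame)
  rr <- r0:r1; cc <- c0:c1
  g <- intensity *
    exp(-outer((rr - row)^2, (cc - col)^2, "+") / (2 * sigma^2))
  frame[rr + 1L, cc + 1L] <- frame[rr + 1L, cc + 1L] + g
  frame
}

#' Generate a synthetic fluorescent-particle movie with ground truth
#'
#' Movers are Gaussian spots translating at a fixed velocity; decoys
#' ("stuck to cilia") jitter about fixed positions without net transport.
#' Ground truth records every true sub-pixel position per frame plus true
#' speeds and directions.
#'
#' @param H,W field size (px).
#' @param fps frame rate in Hz.
#' @param duration recording length in s (default 2 s: 60 frames at 30 fps).
#' @param movers data frame `row0, col0, speed (px/frame), direction (deg)`;
#'   default from [place_particles()].
#' @param decoys data frame `row0, col0`.
#' @param decoy_jitter_sd per-frame decoy excursion SD in px.
#' @param intensity spot peak intensity above baseline.
#' @param psf_sigma Gaussian spot SD in px (sub-pixel centroiding is only
#'   exercised with a soft spot).
#' @param baseline background intensity.
#' @param noise_sigma background Gaussian noise SD.
#' @param seed RNG seed.
#' @return List with `stack` (a [frame_stack()]) and `truth` (list:
#'   `tracks` data frame `particle, type, frame, row, col`, `movers`,
#'   `decoys`, `speed_px_s` true mover speed in px/s).
#' @export
generate_particle_video <- function(H = 256, W = 256, fps = 30, duration = 2,
                                    movers = NULL, decoys = NULL,
                                    decoy_jitter_sd = 0.3, intensity = 150,
                                    psf_sigma = 1.5, baseline = 10,
                                    noise_sigma = 2, seed = 1) {
  nt <- round(fps * duration)
  if (is.null(movers) || is.null(decoys)) {
    pl <- place_particles(H = H, W = W, n_frames = nt, seed = seed)
    if (is.null(movers)) movers <- pl$movers
    if (is.null(decoys)) decoys <- pl$decoys
  }
  movers <- as.data.frame(movers)  # tolerate YAML-parsed configs
  decoys <- as.data.frame(decoys)
  nm <- nrow(movers); ndc <- nrow(decoys)
  truth_rows <- vector("list", nt)
  frames <- .with_seed(seed + 1L, {
    jit_r <- matrix(stats::rnorm(nt * max(ndc, 1L), sd = decoy_jitter_sd),
                    nt, max(ndc, 1L))
    jit_c <- matrix(stats::rnorm(nt * max(ndc, 1L), sd = decoy_jitter_sd),
                    nt, max(ndc, 1L))
    out <- vector("list", nt)
    for (t in seq_len(nt)) {
      fr <- matrix(baseline, H, W)
      tr <- list()
      if (nm > 0) {
        th <- movers$direction * pi / 180
        r <- movers$row0 - movers$speed * sin(th) * (t - 1L)
        cc <- movers$col0 + movers$speed * cos(th) * (t - 1L)
        for (i in seq_len(nm))
          fr <- .render_spot(fr, r[i], cc[i], intensity, psf_sigma)
        tr[[1L]] <- data.frame(particle = seq_len(nm), type = "mover",
                               frame = t - 1L, row = r, col = cc)
      }
      if (ndc > 0) {
        r <- decoys$row0 + jit_r[t, seq_len(ndc)]
        cc <- decoys$col0 + jit_c[t, seq_len(ndc)]
        for (i in seq_len(ndc))
          fr <- .render_spot(fr, r[i], cc[i], intensity, psf_sigma)
        tr[[2L]] <- data.frame(particle = nm + seq_len(ndc), type = "decoy",
                               frame = t - 1L, row = r, col = cc)
      }
      truth_rows[[t]] <- do.call(rbind, tr)
      if (noise_sigma > 0)
        fr <- fr + matrix(stats::rnorm(H * W, sd = noise_sigma), H, W)
      fr[fr < 0] <- 0
      out[[t]] <- fr
    }
    out
  })
  stack <- frame_stack(frames, fps = fps,
                       source = "synthetic particle scene")
  truth <- list(tracks = do.call(rbind, truth_rows), movers = movers,
                decoys = decoys,
                speed_px_s = if (nm > 0) movers$speed[1L] * fps else NA_real_,
                seed = seed)
  list(stack = stack, truth = truth)
}

#' Generate two-class texture tiles with known labels
#'
#' Class 0 tiles carry a higher mean intensity than class 1 by `contrast`
#' units on top of shared Gaussian texture noise; `contrast = 0` makes the
#' classes indistinguishable (chance-level separability). Output plugs
#' directly into [make_folds()] / [cross_validate()].
#'
#' @param n_per_class tiles per class.
#' @param contrast class-0 mean-intensity offset (intensity units).
#' @param baseline shared mean intensity.
#' @param texture_sd within-tile Gaussian texture SD.
#' @param tile_size patch side in px.
#' @param seed RNG seed.
#' @return A labeled `tile_set` (each tile its own source) with true labels
#'   in `info$label`.
#' @export
generate_texture_tiles <- function(n_per_class = 10, contrast = 30,
                                   baseline = 100, texture_sd = 10,
                                   tile_size = 224, seed = 1) {
  n <- 2L * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  images <- .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      mu <- baseline + if (labels[i] == 0L) contrast else 0
      m <- matrix(stats::rnorm(tile_size^2, mean = mu, sd = texture_sd),
                  tile_size, tile_size)
      m[m < 0] <- 0
      m
    })
  })
  info <- data.frame(tile_id = seq_len(n) - 1L,
                     origin_row = 0L, origin_col = 0L,
                     label = labels, coverage = NA_real_,
                     source_id = seq_len(n) - 1L,
                     provenance = "synthetic_texture")
  structure(list(images = images, info = info, tile_size = tile_size),
            class = "tile_set")
}
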