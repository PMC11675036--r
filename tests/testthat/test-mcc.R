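test_that("particle detection finds symmetric centroids at sub-pixel accuracy", {
  expect_equal(nrow(detect_particles(matrix(0, 20, 20), threshold = 0.5)), 0)
  # 3x3 uniform bright square centered at (10, 10), zero background
  fr <- matrix(0, 21, 21)
  fr[10:12, 10:12] <- 5  # 1-based rows 10..12 = 0-based 9..11, center 10
  det <- detect_particles(fr, threshold = 1, min_area = 2)
  expect_equal(nrow(det), 1)
  expect_equal(det$row, 10)
  expect_equal(det$col, 10)
  expect_equal(det$area, 9L)
  expect_equal(det$mass, 45)
})

test_that("diagonally touching blobs form one 8-connected component", {
  fr <- matrix(0, 12, 12)
  fr[2:3, 2:3] <- 1
  fr[4:5, 4:5] <- 1  # touches only at the (3,3)-(4,4) diagonal
  det <- detect_particles(fr, threshold = 0.5, min_area = 1)
  expect_equal(nrow(det), 1)
  expect_equal(det$area, 8L)
  # min_area discards specks
  fr2 <- matrix(0, 12, 12); fr2[6, 6] <- 1
  expect_equal(nrow(detect_particles(fr2, threshold = 0.5, min_area = 2)), 0)
})

test_that("Otsu threshold separates spot foreground from background", {
  set.seed(7)
  fr <- matrix(rnorm(64 * 64, 10, 2), 64, 64)
  fr[20:24, 30:34] <- 150
  thr <- particle_threshold(fr, "otsu")
  expect_gt(thr, 20); expect_lt(thr, 150)
  det <- detect_particles(fr, threshold = "otsu", min_area = 2)
  expect_equal(nrow(det), 1)
  expect_error(particle_threshold(fr, "bogus"), "unknown")
})

test_that("linking follows a translating particle into one trajectory", {
  det <- straight_track_detections(n = 30, step = 2)
  tracks <- link_trajectories(det, search_radius = 10)
  expect_equal(length(unique(tracks$track_id)), 1)
  expect_equal(nrow(tracks), 30)
  st <- trajectory_stats(tracks, fps = 30)
  expect_equal(st$path_length, 58)  # 29 steps x 2 px
  expect_equal(st$net_displacement, 58)
  expect_equal(st$net_direction, 0)  # +col = rightward = 0 degrees
})

test_that("well-separated parallel particles keep their identities", {
  a <- straight_track_detections(n = 20, step = 2, row0 = 20)
  b <- straight_track_detections(n = 20, step = 2, row0 = 120)
  det <- rbind(a, b)
  tracks <- link_trajectories(det, search_radius = 10)
  expect_equal(length(unique(tracks$track_id)), 2)
  for (id in unique(tracks$track_id)) {
    tt <- tracks[tracks$track_id == id, ]
    expect_equal(length(unique(tt$row)), 1)  # no identity swap across rows
  }
})

test_that("a single-frame detection yields a length-1 trajectory", {
  det <- rbind(straight_track_detections(n = 10),
               data.frame(frame = 4L, row = 200, col = 200))
  tracks <- link_trajectories(det, search_radius = 10)
  st <- trajectory_stats(tracks, fps = 30)
  expect_equal(sort(st$n), c(1L, 10L))
  expect_equal(st$path_length[st$n == 1], 0)
  expect_equal(st$mean_speed[st$n == 1], 0)
})

test_that("movement filter removes trajectories below 50% of mean path", {
  st <- data.frame(track_id = 1:2, n = c(10L, 10L),
                   first_frame = 0L, last_frame = 9L,
                   path_length = c(100, 10), net_drow = 0,
                   net_dcol = c(100, 10), net_displacement = c(100, 10),
                   net_direction = 0, mean_speed = 1, net_speed = 1,
                   touches_border = FALSE)
  part <- filter_trajectories(st)
  expect_equal(part$mean_path_length, 55)
  expect_equal(part$cutoff, 27.5)
  expect_equal(part$eliminated$track_id, 2L)
  expect_equal(part$retained$track_id, 1L)
  expect_match(part$eliminated$reason, "path_length")
  # all-equal path lengths: nothing strictly below fraction * mean
  st$path_length <- 40
  part <- filter_trajectories(st)
  expect_equal(nrow(part$eliminated), 0)
  # zero-movement degenerate video: retain everything
  st$path_length <- 0
  expect_equal(nrow(filter_trajectories(st)$retained), 2)
  # the applied elimination rule defaults to 50% of the average movement
  expect_equal(eval(formals(filter_trajectories)$fraction), 0.5)
  expect_error(filter_trajectories(st, fraction = 1.5), "fraction")
})

test_that("rose histogram follows the screen-up angle convention", {
  mk <- function(dirs) data.frame(
    track_id = seq_along(dirs), net_direction = dirs,
    net_displacement = rep(10, length(dirs)))
  r <- rose_histogram(mk(rep(0, 10)), n_bins = 16)
  expect_equal(r$weight[1], 10)       # bin [0, 22.5) holds 0 degrees
  expect_equal(sum(r$weight), 10)
  r <- rose_histogram(mk(c(rep(0, 5), rep(180, 5))), n_bins = 16)
  expect_equal(r$weight[1], 5)
  expect_equal(r$weight[9], 5)        # opposite sector
  expect_equal(sum(rose_histogram(mk(numeric(0)))$weight), 0)
  # conservation under displacement weighting too
  set.seed(5)
  st <- mk(runif(40, 0, 360)); st$net_displacement <- runif(40, 1, 5)
  expect_equal(sum(rose_histogram(st, weighting = "displacement")$weight),
               sum(st$net_displacement))
  expect_error(rose_histogram(st, n_bins = 3), "at least 4")
})

test_that("upward screen motion maps to 90 degrees", {
  det <- data.frame(frame = 0:9, row = seq(100, 82, by = -2), col = 50)
  st <- trajectory_stats(link_trajectories(det, search_radius = 5), fps = 30)
  expect_equal(st$net_direction, 90)
})

test_that("full tracking run separates movers from stuck decoys", {
  pl <- place_particles(n_movers = 6, n_decoys = 2, H = 160, W = 160,
                        n_frames = 45, seed = 4)
  gp <- generate_particle_video(H = 160, W = 160, duration = 1.5,
                                movers = pl$movers, decoys = pl$decoys,
                                seed = 4)
  res <- track_video(gp$stack)
  expect_equal(res$summary$n_retained, 6)
  expect_equal(res$summary$n_eliminated, 2)
  expect_equal(res$summary$mean_speed_px_s, 45, tolerance = 0.02)
  # partition invariant
  expect_equal(res$summary$n_retained + res$summary$n_eliminated,
               res$summary$n_tracks)
  expect_length(intersect(res$retained$track_id, res$eliminated$track_id), 0)
  # rose conservation
  expect_equal(sum(res$rose$weight), res$summary$n_retained)
  # displacement curves are per retained track, starting at zero
  expect_setequal(unique(res$displacement_curves$track_id),
                  res$retained$track_id)
  first <- tapply(res$displacement_curves$cumulative_px,
                  res$displacement_curves$track_id, `[`, 1L)
  expect_true(all(first == 0))
})

test_that("net-displacement speed stays within 10% under 1-px jitter", {
  set.seed(13)
  n <- 60; fps <- 30
  ok <- replicate(20, {
    det <- data.frame(frame = 0:(n - 1),
                      row = 100 + rnorm(n, sd = 1),
                      col = 20 + 1.5 * (0:(n - 1)) + rnorm(n, sd = 1))
    st <- trajectory_stats(link_trajectories(det, search_radius = 10),
                           fps = fps)
    abs(st$net_speed - 45) / 45 <= 0.10
  })
  expect_true(mean(ok) >= 0.9)
})

test_that("blank video gives an empty summary, not an error", {
  st <- frame_stack(array(1, c(10, 32, 32)), fps = 30)
  res <- track_video(st, threshold = 5)
  expect_equal(res$summary$n_tracks, 0)
  expect_equal(sum(res$rose$weight), 0)
})

test_that("tracking output is deterministic for fixed input and config", {
  gp <- generate_particle_video(H = 128, W = 128, duration = 1,
                                movers = data.frame(row0 = c(90, 40),
                                                    col0 = c(20, 30),
                                                    speed = 1.5,
                                                    direction = 45),
                                decoys = data.frame(row0 = 100, col0 = 100),
                                seed = 8)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(track_video(gp$stack)$tracks, f1)
  write_tracks_csv(track_video(gp$stack)$tracks, f2)
  expect_identical(readLines(f1), readLines(f2))
})
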