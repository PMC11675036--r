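test_that("activity map averages absolute change against frame 0", {
  # constant stack: zero activity everywhere
  st <- frame_stack(array(10, c(5, 4, 4)), fps = 100)
  expect_true(all(compute_activity_map(st)$values == 0))
  # hand-computed: frames 10, 12, 10 -> (|12-10| + |10-10|) / 2 = 1
  fr <- array(0, c(3, 2, 2)); fr[1, , ] <- 10; fr[2, , ] <- 12; fr[3, , ] <- 10
  st <- frame_stack(fr, fps = 100)
  act <- compute_activity_map(st, window = 1:2)
  expect_equal(act$values, matrix(1, 2, 2))
  expect_equal(act$ref_frame_index, 0L)
  # default window on a long stack covers 0-based frames 1..99
  st <- frame_stack(array(runif(120 * 4), c(120, 2, 2)) + 1, fps = 100)
  expect_equal(compute_activity_map(st)$window, 1:99)
  expect_error(compute_activity_map(st, window = 120), "window")
  expect_error(compute_activity_map(st, window = integer(0)), "empty")
})

test_that("mean-activity threshold eliminates strictly lower pixels only", {
  uni <- matrix(5, 3, 3)
  bm <- threshold_activity(uni)
  expect_equal(bm$threshold_value, 5)
  expect_true(all(bm$mask))  # ties at the mean are retained
  half <- matrix(c(0, 2), 4, 4)
  bm <- threshold_activity(half)
  expect_equal(bm$threshold_value, 1)
  expect_identical(bm$mask, half == 2)
  bm <- threshold_activity(matrix(0, 2, 2))
  expect_equal(bm$threshold_value, 0)
  expect_true(all(bm$mask))
})

test_that("masks are nested as the threshold grows", {
  set.seed(42)
  for (i in 1:100) {
    m <- matrix(runif(64, 0, 10), 8, 8)
    thr <- sort(runif(3, 0, 10))
    masks <- lapply(thr, function(v) threshold_activity(m, threshold = v)$mask)
    expect_true(all(masks[[2]] <= masks[[1]]))
    expect_true(all(masks[[3]] <= masks[[2]]))
  }
})

test_that("high-pass filtering removes drift without moving peaks", {
  expect_lt(max(abs(highpass_trace(rep(5, 100), fps = 100))), 1e-9)
  t <- (0:999) / 100
  clean <- sin(2 * pi * 10 * t)
  drifted <- clean + 3 * t + 50
  filt <- highpass_trace(drifted, fps = 100, cutoff = 1)
  expect_equal(count_peaks(filt, 100), count_peaks(clean, 100))
  expect_error(highpass_trace(clean, fps = 100, cutoff = 50), "cutoff")
  expect_error(highpass_trace(clean, fps = 100, cutoff = 0), "cutoff")
  expect_error(highpass_trace(1:5, fps = 100), "8 samples")
})

test_that("peak counting recovers sinusoid frequency and caps at Nyquist", {
  t <- (0:999) / 100
  expect_equal(count_peaks(sin(2 * pi * 10 * t), 100), 10)
  expect_equal(count_peaks(sin(2 * pi * 20 * t), 100), 20)
  expect_equal(count_peaks(rep(3, 100), 100), 0)
  expect_error(count_peaks(c(1, 2), 100), "3 samples")
  # frequency recovery across the resolvable band, against the analytic
  # truth and the FFT oracle (resolution 1/duration = 0.1 Hz)
  for (f in c(2, 5.7, 9, 14, 20, 33.3, 45)) {
    tr <- sin(2 * pi * f * t + 0.7)
    est <- count_peaks(tr, 100)
    expect_lt(abs(est - f), 0.1 + 1e-9)
    expect_lt(abs(est - fft_peak_frequency(tr, 100)), 0.2 + 1e-9)
  }
})

test_that("CBF map recovers region frequencies and respects the mask", {
  g <- small_cilia_scene(freq = 12, duration = 5)
  res <- analyze_cbf(g$stack)
  reg <- g$truth$region_masks[[1]]
  expect_equal(modal_frequency(res$cbf, reg), 12, tolerance = 1 / 5)
  # defined-pixel set equals the beat mask
  expect_identical(!is.na(res$cbf$frequency), res$mask$mask)
  # all-static stack with an all-true mask: CBF 0 everywhere
  st <- frame_stack(array(10, c(50, 6, 6)), fps = 100)
  cbf <- compute_cbf_map(st, matrix(TRUE, 6, 6))
  expect_true(all(cbf$frequency == 0))
  expect_error(compute_cbf_map(st, matrix(TRUE, 3, 3)), "shape")
})

test_that("two regions spanning the physiologic band are both recovered", {
  g <- generate_cilia_video(
    H = 64, W = 64, fps = 100, duration = 5,
    regions = list(
      list(rect = c(4L, 4L, 20L, 20L), freq = 9, amp = 30, phase = 0),
      list(rect = c(36L, 36L, 20L, 20L), freq = 20, amp = 30, phase = 1)),
    noise_sigma = 0, seed = 11)
  res <- analyze_cbf(g$stack)
  expect_equal(modal_frequency(res$cbf, g$truth$region_masks[[1]]), 9,
               tolerance = 1 / 5)
  expect_equal(modal_frequency(res$cbf, g$truth$region_masks[[2]]), 20,
               tolerance = 1 / 5)
  # histogram shows two modes, one per true frequency (1 Hz bins)
  h <- cbf_histogram(res$cbf, bin_width = 1)
  top2 <- sort(h$bin_edges[order(h$counts, decreasing = TRUE)[1:2]])
  expect_true(all(abs(top2 - c(9, 20)) <= 1))
})

test_that("bulk peak counter matches the per-trace reference path", {
  g <- small_cilia_scene(freq = 10, duration = 2, noise_sigma = 2, seed = 9)
  mask <- matrix(FALSE, 48, 48)
  set.seed(1); mask[sample(48 * 48, 60)] <- TRUE
  bulk <- compute_cbf_map(g$stack, mask)$frequency
  ref <- per_trace_cbf(g$stack, mask)
  expect_equal(bulk, ref)
})

test_that("histogram percentages partition the beating pixels", {
  cbf <- structure(list(frequency = matrix(12, 4, 4), fps = 100,
                        duration = 10), class = "cbf_map")
  h <- cbf_histogram(cbf, bin_width = 1)
  expect_equal(sum(h$percent), 100)
  expect_equal(max(h$percent), 100)  # point mass in one bin
  cbf$frequency <- matrix(c(9, 20), 4, 4)
  h <- cbf_histogram(cbf, bin_width = 1)
  expect_equal(sort(h$percent[h$percent > 0]), c(50, 50))
  cbf$frequency <- matrix(NA_real_, 2, 2)
  h <- cbf_histogram(cbf, bin_width = 1)
  expect_equal(h$n_pixels, 0)
  expect_true(all(h$counts == 0))
  expect_error(cbf_histogram(cbf, bin_width = 0), "positive")
})

test_that("CBF analysis is deterministic and robust to 5% noise", {
  clean <- small_cilia_scene(freq = 14, duration = 5, noise_sigma = 0)
  noisy <- small_cilia_scene(freq = 14, duration = 5, noise_sigma = 1.5)
  reg <- clean$truth$region_masks[[1]]
  m_clean <- modal_frequency(analyze_cbf(clean$stack)$cbf, reg)
  m_noisy <- modal_frequency(analyze_cbf(noisy$stack)$cbf, reg)
  expect_lte(abs(m_noisy - m_clean), 1 / 5)
  # bit-for-bit determinism of the full map
  r1 <- analyze_cbf(noisy$stack)$cbf$frequency
  r2 <- analyze_cbf(noisy$stack)$cbf$frequency
  expect_identical(r1, r2)
})

test_that("heatmap rendering writes a labeled PNG", {
  g <- small_cilia_scene(duration = 2)
  res <- analyze_cbf(g$stack)
  tf <- withr::local_tempfile(fileext = ".png")
  render_cbf_heatmap(res$cbf, tf)
  expect_true(file.exists(tf) && file.size(tf) > 0)
})
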