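# Shared fixtures and independent oracles for the test suite.

# FFT-based dominant-frequency oracle (independent of the peak-counting
# implementation; excludes DC).
fft_peak_frequency <- function(trace, fps) {
  n <- length(trace)
  spec <- Mod(stats::fft(trace - mean(trace)))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1L) * fps / n
  keep <- freqs > 0
  freqs[keep][which.max(spec[keep])]
}

# Brute-force per-trace frequency via the exported single-trace path,
# used to cross-check the bulk (C++) counter inside compute_cbf_map.
per_trace_cbf <- function(stack, mask, cutoff = 1, prominence_k = 0.5) {
  d <- dim(stack$frames)
  out <- matrix(NA_real_, d[2L], d[3L])
  dur <- stack_duration(stack)
  for (r in seq_len(d[2L])) for (cc in seq_len(d[3L])) {
    if (!mask[r, cc]) next
    tr <- stack$frames[, r, cc]
    tr <- highpass_trace(tr, stack$fps, cutoff)
    out[r, cc] <- count_peaks(tr, stack$fps, prominence_k = prominence_k)
  }
  out
}

# A minimal single-region oscillation scene for fast unit tests.
small_cilia_scene <- function(freq = 12, duration = 5, noise_sigma = 0,
                              seed = 3, amp = 30) {
  generate_cilia_video(
    H = 48, W = 48, fps = 100, duration = duration,
    regions = list(list(rect = c(8L, 8L, 20L, 20L), freq = freq,
                        amp = amp, phase = 0.4)),
    noise_sigma = noise_sigma, seed = seed)
}

# Tracks data frame for a single straight-line walker.
straight_track_detections <- function(n = 30, step = 2, row0 = 50,
                                      col0 = 10) {
  data.frame(frame = seq_len(n) - 1L,
             row = rep(row0, n),
             col = col0 + step * (seq_len(n) - 1L))
}
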