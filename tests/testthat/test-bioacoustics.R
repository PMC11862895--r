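cfg <- call_config()

test_that("WAV round trip preserves samples to 16-bit precision", {
  set.seed(71)
  rec <- call_recording(runif(5000, -0.9, 0.9), 384000)
  tmp <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, tmp)
  r2 <- read_wav(tmp)
  expect_equal(r2$sample_rate, 384000)
  expect_equal(r2$samples, rec$samples, tolerance = 1 / 32000)
})

test_that("generator preconditions and degenerate trains", {
  expect_error(gen_fm_call(30, 33, 2, 100, 3), "descending")
  expect_error(gen_fm_call(300, 200, 2, 100, 3), "Nyquist")
  noise <- gen_fm_call(33, 30, 2.4, 100, 0, snr_db = 30, seed = 1)
  expect_equal(nrow(attr(noise, "truth")), 0L)
  # same seed twice: identical samples
  r1 <- gen_fm_call(33, 30, 2.4, 50, 2, seed = 4)
  r2 <- gen_fm_call(33, 30, 2.4, 50, 2, seed = 4)
  expect_identical(r1$samples, r2$samples)
})

test_that("pulse detection: counts, IPIs, silence and single pulse", {
  rec <- gen_fm_call(33.15, 29.82, 2.43, 246.57, 5, snr_db = 30, seed = 2)
  det <- detect_pulses(rec, cfg)
  expect_equal(nrow(det), 5L)
  expect_true(all(diff(det$onset_s) > 0))
  expect_equal(diff(det$onset_s) * 1000, rep(246.57, 4), tolerance = 0.005)

  expect_equal(nrow(detect_pulses(call_recording(numeric(4e4), 384000), cfg)), 0L)

  one <- gen_fm_call(33, 30, 2.4, 100, 1, snr_db = 30, seed = 3)
  expect_equal(nrow(detect_pulses(one, cfg)), 1L)
})

test_that("noise-free measurements hit the planted parameters within a bin", {
  rec <- gen_fm_call(33.15, 29.82, 2.43, 246.57, 3, snr_db = Inf, seed = 1)
  p <- measure_all_pulses(rec, cfg)
  bin_khz <- 384000 / cfg$fft_n / 1000
  hop_ms <- cfg$hop / 384000 * 1000
  expect_equal(nrow(p), 3L)
  expect_lt(max(abs(p$start_freq - 33.15)), bin_khz)
  expect_lt(max(abs(p$end_freq - 29.82)), bin_khz)
  expect_lt(max(abs(p$duration - 2.43)), hop_ms)
  expect_true(all(p$peak_freq > 29.82 & p$peak_freq < 33.15))
  expect_true(all(p$start_freq >= p$end_freq))
})

test_that("a constant-frequency tone degenerates to start = end = peak", {
  fs <- 384000
  x <- numeric(fs %/% 10)
  seg <- 0.5 * sin(2 * pi * 31000 * seq_len(round(0.0024 * fs)) / fs)
  ramp <- round(0.05 * length(seg))
  env <- rep(1, length(seg))
  env[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
  env[length(seg) + 1 - seq_len(ramp)] <- seq(0, 1, length.out = ramp)
  x[2001:(2000 + length(seg))] <- seg * env
  rec <- call_recording(x, fs)
  det <- detect_pulses(rec, cfg)
  m <- measure_pulse(rec, det$onset_s, det$offset_s, cfg)
  expect_equal(m$start_freq, 31, tolerance = 0.02)
  expect_equal(m$end_freq, 31, tolerance = 0.02)
  expect_equal(m$peak_freq, 31, tolerance = 0.02)
  expect_lt(m$bandwidth, 0.5)
})

test_that("measurement is deterministic and shifts with the recording", {
  rec <- gen_fm_call(33.15, 29.82, 2.43, 246.57, 4, snr_db = 30, seed = 3)
  p1 <- measure_all_pulses(rec, cfg)
  expect_identical(p1, measure_all_pulses(rec, cfg))
  shifted <- call_recording(c(numeric(38400), rec$samples), rec$sample_rate)
  p2 <- measure_all_pulses(shifted, cfg)
  expect_equal(p2$onset_s - 0.1, p1$onset_s, tolerance = 2e-4)
  expect_equal(p2$start_freq, p1$start_freq, tolerance = 0.05)
  expect_equal(p2$duration, p1$duration, tolerance = 0.02)
})

test_that("summaries report range, mean, sample SD and IPI series", {
  rec <- gen_fm_call(33.15, 29.82, 2.43, 246.57, 4, snr_db = 30, seed = 5)
  p <- measure_all_pulses(rec, cfg)
  s <- summarize_calls(p)
  expect_equal(s$n_pulses, 4L)
  expect_equal(length(s$ipi_ms), 3L)
  expect_equal(s$ipi_ms, rep(246.57, 3), tolerance = 0.01)
  st <- s$stats
  expect_true(all(st$min <= st$mean & st$mean <= st$max))
  expect_true(all(is.na(st$sd) | st$sd >= 0))
  ini <- st[st$parameter == "Initial frequency (kHz)", ]
  expect_equal(ini$sd, sd(p$start_freq))
  # single pulse: SD reported absent, no IPI defined
  s1 <- summarize_calls(p[1, ])
  expect_true(all(is.na(s1$stats$sd)))
  expect_equal(length(s1$ipi_ms), 0L)
  # identical pulses: SD exactly 0
  s0 <- summarize_calls(p[c(1, 1), ])
  expect_equal(s0$stats$sd[1], 0)
  expect_error(summarize_calls(p[0, ]), "no pulses")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_call_summary_tsv(s, tmp)
  tab <- read.delim(tmp, check.names = FALSE)
  expect_equal(nrow(tab), 6L)  # five parameters + interval row
})

test_that("seeded 20-pulse train recovers Table-style means within 2 SE", {
  rec <- gen_fm_call(33.15, 29.82, 2.43, 246.57, 20, snr_db = 25, seed = 12)
  p <- measure_all_pulses(rec, cfg)
  expect_equal(nrow(p), 20L)
  s <- summarize_calls(p)
  st <- s$stats
  m <- function(par) st$mean[st$parameter == par]
  expect_equal(m("Initial frequency (kHz)"), 33.15, tolerance = 0.2)
  expect_equal(m("Terminate frequency (kHz)"), 29.82, tolerance = 0.2)
  expect_equal(m("Duration time (ms)"), 2.43, tolerance = 0.06)
  expect_equal(m("Interval time (ms)"), 246.57, tolerance = 0.05)
})
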