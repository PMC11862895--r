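# Echolocation-call parameterization: pulse detection on a band-limited
# energy envelope, per-pulse spectrogram measurements (sweep endpoints,
# peak frequency, bandwidth, duration), summary statistics, and a seeded
# FM pulse-train generator for parameter-recovery testing.
#
# Measurement definitions (proprietary call-analysis software does not
# document its own, so these are explicit and configurable):
#   * detection: band-limited RMS envelope above (per-recording peak +
#     threshold_db), runs closer than a merge gap fused;
#   * per pulse: Hann-windowed STFT; the spectral ridge is the per-frame
#     power maximum (parabolic bin interpolation); frames whose ridge
#     power is within ridge_cutoff_db of the window maximum are included;
#     start/end frequency = ridge at first/last included frame; peak
#     frequency = maximum of the mean included-frame spectrum; pulse
#     edges (duration) refined on the envelope at the same cutoff.

#' Analysis configuration for call recordings
#'
#' @param sample_rate Hz.
#' @param fft_n FFT length (frames are zero-padded from `win_pts`).
#' @param win_pts Hann analysis-window length in samples.
#' @param overlap fractional window overlap (0.875 = 87.5%).
#' @param ridge_cutoff_db inclusion cutoff below the window's ridge-power
#'   maximum (positive dB).
#' @param detect_threshold_db detection threshold relative to the
#'   per-recording peak envelope (negative dB).
#' @param band detection/ridge search band in Hz, inside Nyquist.
#' @param merge_gap_ms detections closer than this are fused.
#' @param min_dur_ms detections shorter than this are dropped.
#' @return a list of class `call_config`.
#' @export
call_config <- function(sample_rate = 384000, fft_n = 1024L, win_pts = 256L,
                        overlap = 0.875, ridge_cutoff_db = 20,
                        detect_threshold_db = -24,
                        band = c(20e3, 60e3), merge_gap_ms = 5,
                        min_dur_ms = 0.5) {
  stopifnot(detect_threshold_db < 0, ridge_cutoff_db > 0,
            band[2] > band[1], band[2] < sample_rate / 2)
  structure(list(sample_rate = sample_rate, fft_n = as.integer(fft_n),
                 win_pts = as.integer(win_pts), overlap = overlap,
                 hop = max(1L, as.integer(round((1 - overlap) * win_pts))),
                 ridge_cutoff_db = ridge_cutoff_db,
                 detect_threshold_db = detect_threshold_db,
                 band = band, merge_gap_ms = merge_gap_ms,
                 min_dur_ms = min_dur_ms),
            class = "call_config")
}

#' A call recording
#'
#' @param samples numeric amplitude series in `[-1, 1]`.
#' @param sample_rate Hz.
#' @return list of class `call_recording`.
#' @export
call_recording <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "call_recording")
}

#' @export
print.call_recording <- function(x, ...) {
  cat(sprintf("<call_recording> %.3f s at %g kHz\n",
              length(x$samples) / x$sample_rate, x$sample_rate / 1000))
  invisible(x)
}

# Minimal RIFF/PCM WAV I/O ----------------------------------------------------

#' Read / write mono 16-bit PCM WAV
#'
#' Minimal RIFF reader/writer for mono PCM-16 files at arbitrary sample
#' rates (ultrasonic recorders commonly use 256-500 kHz).
#'
#' @param path WAV file path.
#' @return `read_wav`: a [call_recording] with samples scaled to
#'   `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE") stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1) stop("only PCM WAV supported")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")  # byte rate
      ba <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      bits <- ba[2]
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (tag == "data") {
      if (is.null(bits)) stop("WAV data chunk before fmt chunk")
      if (bits != 16) stop("only 16-bit PCM supported")
      samples <- readBin(con, "integer", sz / 2, 2, endian = "little")
      break
    } else readBin(con, "raw", sz)
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  if (channels != 1) stop("only mono WAV supported")
  call_recording(samples / 32767, rate)
}

#' @rdname read_wav
#' @param rec a [call_recording].
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "call_recording"))
  s <- pmax(-1, pmin(1, rec$samples))
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")        # PCM, mono
  writeBin(as.integer(rec$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 2), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")       # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

# Synthesis -------------------------------------------------------------------

#' Generate a synthetic FM pulse train
#'
#' Downward frequency sweeps (linear or hyperbolic) with a raised-cosine
#' on/off ramp (5% of the pulse duration per edge, so the -20 dB extent
#' of the envelope stays within one analysis frame of the nominal
#' duration), repeated at a fixed inter-pulse interval, plus white
#' Gaussian noise at a given SNR (peak signal power vs. noise power).
#' Ground-truth per-pulse parameters are attached.
#'
#' @param start_f,end_f sweep endpoints in kHz, `start_f > end_f > 0`.
#' @param duration pulse duration, ms.
#' @param ipi inter-pulse interval (onset to onset), ms.
#' @param n_pulses number of pulses (0 gives pure noise).
#' @param snr_db signal-to-noise ratio in dB; `Inf` disables noise.
#' @param sweep `"linear"` or `"hyperbolic"` (1/f linear in time).
#' @param seed integer seed for the noise.
#' @param sample_rate Hz; both endpoints must lie below Nyquist.
#' @param lead_ms silence before the first pulse.
#' @param amplitude pulse peak amplitude (headroom below clipping).
#' @return a [call_recording]; `attr(, "truth")` holds a data frame of
#'   planted per-pulse parameters (onset_s, start_freq, end_freq,
#'   duration, and the train-level ipi).
#' @export
gen_fm_call <- function(start_f, end_f, duration, ipi, n_pulses,
                        snr_db = 30, sweep = c("linear", "hyperbolic"),
                        seed = 1L, sample_rate = 384000, lead_ms = 20,
                        amplitude = 0.5) {
  sweep <- match.arg(sweep)
  if (n_pulses > 0 && !(start_f > end_f && end_f > 0))
    stop("need start_f > end_f > 0 for a descending FM sweep")
  if (1000 * start_f >= sample_rate / 2)
    stop("start frequency above Nyquist")
  stopifnot(duration > 0, ipi > 0)
  set.seed(seed)
  f0 <- start_f * 1000; f1 <- end_f * 1000
  dur_s <- duration / 1000; ipi_s <- ipi / 1000
  total_s <- lead_ms / 1000 + if (n_pulses > 0)
    (n_pulses - 1) * ipi_s + dur_s + lead_ms / 1000 else 0.1
  n <- ceiling(total_s * sample_rate)
  x <- numeric(n)
  npulse <- round(dur_s * sample_rate)
  tt <- (seq_len(npulse) - 1) / sample_rate
  phase <- if (sweep == "linear") {
    2 * pi * (f0 * tt + (f1 - f0) * tt^2 / (2 * dur_s))
  } else {
    a <- 1 / f0; b <- (1 / f1 - 1 / f0) / dur_s
    2 * pi * (log(a + b * tt) - log(a)) / b
  }
  ramp_n <- max(2L, round(0.05 * npulse))
  env <- rep(1, npulse)
  up <- 0.5 * (1 - cos(pi * (seq_len(ramp_n) - 1) / (ramp_n - 1)))
  env[seq_len(ramp_n)] <- up
  env[npulse + 1 - seq_len(ramp_n)] <- up
  pulse <- amplitude * env * sin(phase)
  onsets_s <- lead_ms / 1000 + (seq_len(n_pulses) - 1) * ipi_s
  for (k in seq_len(n_pulses)) {
    i0 <- round(onsets_s[k] * sample_rate) + 1L
    x[i0:(i0 + npulse - 1L)] <- x[i0:(i0 + npulse - 1L)] + pulse
  }
  if (is.finite(snr_db)) {
    sigma <- sqrt((amplitude^2 / 2) / 10^(snr_db / 10))
    x <- x + rnorm(n, 0, sigma)
  }
  rec <- call_recording(x, sample_rate)
  truth <- data.frame(onset_s = onsets_s,
                      start_freq = rep(start_f, n_pulses),
                      end_freq = rep(end_f, n_pulses),
                      duration = rep(duration, n_pulses))
  attr(rec, "truth") <- truth
  attr(rec, "ipi") <- ipi
  rec
}

# Detection --------------------------------------------------------------------

bandpass <- function(x, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

moving_rms <- function(x, w) {
  cs <- cumsum(c(0, x^2))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - ceiling(w / 2))
  hi <- pmin(n, seq_len(n) + floor(w / 2))
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Detect pulses in a recording
#'
#' Contiguous regions where the band-limited RMS envelope exceeds the
#' per-recording peak envelope by `detect_threshold_db`; regions closer
#' than the merge gap are fused and sub-millisecond blips dropped.
#' A silent recording yields an empty result.
#'
#' @param rec a [call_recording].
#' @param config a [call_config]; its `sample_rate` is ignored in favor
#'   of the recording's.
#' @return data frame with columns `onset_s`, `offset_s` (strictly
#'   increasing onsets).
#' @export
detect_pulses <- function(rec, config = call_config()) {
  stopifnot(inherits(rec, "call_recording"))
  fs <- rec$sample_rate
  if (all(rec$samples == 0))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  xf <- bandpass(rec$samples, config$band, fs)
  env <- moving_rms(xf, round(0.25e-3 * fs))
  thr <- max(env) * 10^(config$detect_threshold_db / 20)
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # drop isolated noise blips before merging, so clusters of them cannot
  # fuse into a pseudo-pulse; a real pulse is one continuous run
  long_enough <- (runs[, 2] - runs[, 1] + 1L) / fs * 1000 >= config$min_dur_ms
  runs <- runs[long_enough, , drop = FALSE]
  if (!nrow(runs))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  gap <- config$merge_gap_ms / 1000 * fs
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs) - 1L) + 1L) {
    if (runs[i, 1] - merged[nrow(merged), 2] <= gap)
      merged[nrow(merged), 2] <- runs[i, 2]
    else merged <- rbind(merged, runs[i, ])
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) / fs * 1000 >= config$min_dur_ms
  merged <- merged[keep, , drop = FALSE]
  data.frame(onset_s = (merged[, 1] - 1L) / fs,
             offset_s = (merged[, 2] - 1L) / fs)
}

# Measurement ------------------------------------------------------------------

# Hann STFT power; rows = frequency bins of the positive half, cols = frames
stft_power <- function(x, config, fs) {
  wl <- config$win_pts; hop <- config$hop; nf <- config$fft_n
  if (length(x) < wl + hop) stop("analysis window shorter than 2 spectrogram frames")
  starts <- seq(1L, length(x) - wl + 1L, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(wl) - 1) / (wl - 1)))
  frames <- vapply(starts, function(s0) {
    fr <- x[s0:(s0 + wl - 1L)] * win
    c(fr, numeric(nf - wl))
  }, numeric(nf))
  spec <- Mod(stats::mvfft(frames))^2
  half <- nf %/% 2L
  list(power = spec[seq_len(half), , drop = FALSE],
       freq = (seq_len(half) - 1L) * fs / nf,
       t_center = (starts - 1L + wl / 2) / fs)
}

# parabolic interpolation of a bin peak in the log-power domain
interp_peak <- function(p, i, freq) {
  if (i <= 1L || i >= length(p)) return(freq[i])
  y <- log(pmax(p[(i - 1):(i + 1)], 1e-300))
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom >= 0) return(freq[i])
  delta <- 0.5 * (y[1] - y[3]) / denom
  freq[i] + delta * (freq[2] - freq[1])
}

#' Measure one detected pulse
#'
#' @param rec a [call_recording].
#' @param onset_s,offset_s detection window from [detect_pulses()].
#' @param config a [call_config].
#' @return one-row data frame of class `pulse_params`: `onset_s`,
#'   `start_freq`, `end_freq`, `peak_freq`, `bandwidth` (kHz), and
#'   `duration` (ms).
#' @export
measure_pulse <- function(rec, onset_s, offset_s, config = call_config()) {
  stopifnot(inherits(rec, "call_recording"))
  fs <- rec$sample_rate
  pad <- 1e-3
  i0 <- max(1L, floor((onset_s - pad) * fs) + 1L)
  i1 <- min(length(rec$samples), ceiling((offset_s + pad) * fs) + 1L)
  x <- bandpass(rec$samples[i0:i1], config$band, fs)

  sp <- stft_power(x, config, fs)
  inband <- sp$freq >= config$band[1] & sp$freq <= config$band[2]
  pw <- sp$power[inband, , drop = FALSE]
  fr <- sp$freq[inband]
  ridge_pow <- apply(pw, 2L, max)
  ridge_bin <- apply(pw, 2L, which.max)
  cutoff <- max(ridge_pow) * 10^(-config$ridge_cutoff_db / 10)
  inc <- which(ridge_pow >= cutoff)
  first <- inc[1L]; last <- inc[length(inc)]
  ridge_freq <- vapply(seq_along(inc), function(k)
    interp_peak(pw[, inc[k]], ridge_bin[inc[k]], fr), numeric(1))

  mean_spec <- rowMeans(pw[, first:last, drop = FALSE])
  pk <- which.max(mean_spec)
  peak_freq <- interp_peak(mean_spec, pk, fr)

  # refine pulse edges on the envelope at the same relative cutoff
  env <- moving_rms(x, 32L)
  ipk <- which.max(env)
  ethr <- env[ipk] * 10^(-config$ridge_cutoff_db / 20)
  a <- ipk; while (a > 1L && env[a - 1L] >= ethr) a <- a - 1L
  b <- ipk; while (b < length(env) && env[b + 1L] >= ethr) b <- b + 1L
  duration_ms <- (b - a) / fs * 1000

  # sweep endpoints: evaluate a power-weighted polynomial fit of the
  # ridge track at the refined pulse edges; this averages the per-frame
  # spectral jitter that a single edge frame would carry
  t_on <- (a - 1L) / fs; t_off <- (b - 1L) / fs
  tc <- sp$t_center[inc]
  if (length(inc) >= 3L) {
    deg <- if (length(inc) >= 8L) 2L else 1L
    X <- stats::poly(tc, degree = deg, raw = TRUE)
    fit <- stats::lm.wfit(cbind(1, X), ridge_freq, w = ridge_pow[inc])
    predf <- function(t0) sum(fit$coefficients * t0^(0:deg))
    f_start <- predf(t_on); f_end <- predf(t_off)
  } else {
    f_start <- ridge_freq[1L]; f_end <- ridge_freq[length(ridge_freq)]
  }

  data.frame(onset_s = (i0 - 1L + a - 1L) / fs,
             start_freq = f_start / 1000,
             end_freq = f_end / 1000,
             peak_freq = peak_freq / 1000,
             bandwidth = (max(ridge_freq) - min(ridge_freq)) / 1000,
             duration = duration_ms)
}

#' Detect and measure every pulse in a recording
#'
#' @param rec a [call_recording].
#' @param config a [call_config].
#' @return data frame, one row per detected pulse (may be empty).
#' @export
measure_all_pulses <- function(rec, config = call_config()) {
  det <- detect_pulses(rec, config)
  if (!nrow(det))
    return(data.frame(onset_s = numeric(0), start_freq = numeric(0),
                      end_freq = numeric(0), peak_freq = numeric(0),
                      bandwidth = numeric(0), duration = numeric(0)))
  do.call(rbind, lapply(seq_len(nrow(det)), function(i)
    measure_pulse(rec, det$onset_s[i], det$offset_s[i], config)))
}

#' Summarize per-pulse measurements
#'
#' Per-parameter range and mean +/- sample SD (n-1 denominator), plus the
#' onset-to-onset inter-pulse interval series.
#'
#' @param pulses data frame from [measure_all_pulses()] (>= 1 row).
#' @return list of class `call_summary`: `stats` (data frame with
#'   parameter, min, max, mean, sd, n), `ipi_ms` (IPI series; length
#'   n-1), `n_pulses`.
#' @export
summarize_calls <- function(pulses) {
  if (!nrow(pulses)) stop("no pulses to summarize")
  pars <- c(start_freq = "Initial frequency (kHz)",
            end_freq = "Terminate frequency (kHz)",
            bandwidth = "Frequency bandwidth (kHz)",
            peak_freq = "Main frequency (kHz)",
            duration = "Duration time (ms)")
  rows <- lapply(names(pars), function(p) {
    v <- pulses[[p]]
    data.frame(parameter = pars[[p]], min = min(v), max = max(v),
               mean = mean(v), sd = if (length(v) > 1L) sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  ipi <- if (nrow(pulses) > 1L) diff(pulses$onset_s) * 1000 else numeric(0)
  if (length(ipi))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "Interval time (ms)", min = min(ipi), max = max(ipi),
      mean = mean(ipi), sd = if (length(ipi) > 1L) sd(ipi) else NA_real_,
      n = length(ipi), stringsAsFactors = FALSE)
  structure(list(stats = do.call(rbind, rows), ipi_ms = ipi,
                 n_pulses = nrow(pulses)),
            class = "call_summary")
}

#' @export
print.call_summary <- function(x, ...) {
  cat(sprintf("call summary over %d pulses\n", x$n_pulses))
  s <- x$stats
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-26s %6.2f-%-6.2f  %6.2f +/- %s\n", s$parameter[i],
                s$min[i], s$max[i], s$mean[i],
                if (is.na(s$sd[i])) "NA" else sprintf("%.2f", s$sd[i])))
  invisible(x)
}

#' Write a call summary as TSV
#'
#' @param x a `call_summary`.
#' @param path output path.
#' @param header_comment optional provenance lines (prefixed `# `).
#' @return `path`, invisibly.
#' @export
write_call_summary_tsv <- function(x, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  s <- x$stats
  out <- data.frame(Items = s$parameter,
                    Range = sprintf("%.2f-%.2f", s$min, s$max),
                    `Mean +/- SD` = ifelse(is.na(s$sd),
                                           sprintf("%.2f", s$mean),
                                           sprintf("%.2f +/- %.2f", s$mean, s$sd)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
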