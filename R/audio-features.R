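# Acoustic preprocessing and the two syllable representations used
# downstream: a fixed-size log-power mel spectrogram (network input) and
# per-frame acoustic feature contours with per-syllable summary statistics
# (DTW input / MRM predictors).

#' High-pass filter a syllable
#'
#' Zero-phase (forward-backward) Butterworth high-pass, order 4.
#'
#' @param s A `syllable`.
#' @param cutoff Cutoff frequency in Hz (default 100).
#' @return Filtered `syllable`.
#' @export
highpass_filter <- function(s, cutoff = 100) {
  stopifnot(inherits(s, "syllable"))
  bf <- signal::butter(4, cutoff / (s$rate / 2), type = "high")
  s$samples <- as.numeric(signal::filtfilt(bf, s$samples))
  s
}

#' Apply raised-cosine fade-in and fade-out
#'
#' @param s A `syllable`.
#' @param fade Fade duration in seconds at each end (default 0.02).
#' @return Faded `syllable`.
#' @export
apply_fades <- function(s, fade = 0.02) {
  stopifnot(inherits(s, "syllable"))
  nf <- round(fade * s$rate)
  n <- length(s$samples)
  if (2 * nf >= n) stop("syllable too short for fades")
  ramp <- 0.5 * (1 - cos(pi * seq_len(nf) / nf))
  s$samples[seq_len(nf)] <- s$samples[seq_len(nf)] * ramp
  s$samples[n - nf + seq_len(nf)] <- s$samples[n - nf + seq_len(nf)] * rev(ramp)
  s
}

#' Preprocess a syllable for analysis
#'
#' High-pass filters at 100 Hz, applies a 20 ms raised-cosine fade-in and
#' fade-out, and peak-normalises to `|max| = 1`. Length and rate are
#' unchanged.
#'
#' @param s A `syllable` with rate >= 8000 Hz and duration > 40 ms.
#' @return Preprocessed `syllable`.
#' @export
preprocess_syllable <- function(s) {
  stopifnot(inherits(s, "syllable"))
  if (s$rate < 8000) stop("sample rate must be >= 8000 Hz")
  if (length(s$samples) / s$rate <= 0.04)
    stop("syllable duration must exceed 40 ms (fades would overlap)")
  if (any(!is.finite(s$samples))) stop("non-finite samples")
  if (max(abs(s$samples)) == 0) stop("silent input")
  s <- highpass_filter(s, 100)
  s <- apply_fades(s, 0.02)
  # normalise last so the peak contract holds after filter edge transients
  # have been faded out
  s$samples <- s$samples / max(abs(s$samples))
  s
}

mel_of_hz <- function(f) 2595 * log10(1 + f / 700)
hz_of_mel <- function(m) 700 * (10^(m / 2595) - 1)

#' Short-time power spectra of a waveform
#' @noRd
stft_power <- function(x, rate, n_fft, hop, win_length) {
  if (length(x) < win_length)
    x <- c(x, numeric(win_length - length(x)))
  n_frames <- 1L + (length(x) - win_length) %/% hop
  win <- 0.5 * (1 - cos(2 * pi * seq_len(win_length) / (win_length + 1)))
  half <- n_fft %/% 2 + 1L
  P <- matrix(0, half, n_frames)
  for (k in seq_len(n_frames)) {
    seg <- x[(k - 1) * hop + seq_len(win_length)] * win
    spec <- stats::fft(c(seg, numeric(n_fft - win_length)))[seq_len(half)]
    P[, k] <- Mod(spec)^2
  }
  list(power = P, freqs = (seq_len(half) - 1) * rate / n_fft)
}

#' Log-power mel spectrogram of a syllable
#'
#' FFT window 2048, hop 128, window length 512 (Hann); 150 triangular mel
#' bands between 100 Hz and 16 kHz; power log-scaled in dB relative to
#' `ref_power` (the spectrogram's own maximum by default) with a floor at
#' -80 dB. The time axis is centre-padded with the floor value, or
#' centre-cropped, to exactly 170 frames.
#'
#' @param s A preprocessed `syllable`.
#' @param n_mels,n_frames Output size (defaults 150 x 170).
#' @param ref_power Optional reference power for the dB scale, e.g. a
#'   corpus-wide maximum; defaults to the syllable's own maximum mel power.
#' @param fmin,fmax Mel filterbank frequency range in Hz.
#' @return A `mel_spectrogram`: list with `values` (n_mels x n_frames, dB),
#'   `band_centers` (Hz) and `floor_db`.
#' @export
mel_spectrogram <- function(s, n_mels = 150, n_frames = 170,
                            ref_power = NULL, fmin = 100, fmax = 16000) {
  stopifnot(inherits(s, "syllable"))
  fmax <- min(fmax, s$rate / 2)
  st <- stft_power(s$samples, s$rate, n_fft = 2048, hop = 128,
                   win_length = 512)
  fb <- mel_filterbank(n_mels, st$freqs, fmin, fmax)
  M <- fb$weights %*% st$power
  if (is.null(ref_power)) ref_power <- max(M)
  if (ref_power <= 0) ref_power <- .Machine$double.eps
  floor_db <- -80
  vals <- 10 * log10(pmax(M / ref_power, 10^(floor_db / 10)))
  k <- ncol(vals)
  if (k >= n_frames) {
    start <- (k - n_frames) %/% 2
    vals <- vals[, start + seq_len(n_frames), drop = FALSE]
  } else {
    out <- matrix(floor_db, n_mels, n_frames)
    start <- (n_frames - k) %/% 2
    out[, start + seq_len(k)] <- vals
    vals <- out
  }
  structure(list(values = vals, band_centers = fb$centers,
                 floor_db = floor_db), class = "mel_spectrogram")
}

#' Triangular mel filterbank
#' @noRd
mel_filterbank <- function(n_mels, freqs, fmin, fmax) {
  edges <- hz_of_mel(seq(mel_of_hz(fmin), mel_of_hz(fmax),
                         length.out = n_mels + 2))
  W <- matrix(0, n_mels, length(freqs))
  for (b in seq_len(n_mels)) {
    lo <- edges[b]; ce <- edges[b + 1]; hi <- edges[b + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    W[b, ] <- pmax(0, pmin(up, down))
  }
  list(weights = W, centers = edges[2:(n_mels + 1)])
}

#' Per-frame acoustic feature contours of a syllable
#'
#' Frame step 5 ms, analysis window 10 ms (Hann). Estimates per frame:
#' fundamental frequency (autocorrelation peak in 300-4000 Hz, log Hz in the
#' output), peak frequency (spectral argmax, log Hz), mean frequency
#' (spectral centroid, log Hz), Wiener entropy (log ratio of geometric to
#' arithmetic mean of the band-limited, lightly smoothed power spectrum, so
#' white noise sits near 0), harmonicity (fraction of power within +/-5% of
#' the first 8 harmonics of the fundamental), fundamental and peak frequency
#' change (arcsin-transformed inter-frame slope, normalised by 50 kHz/s),
#' normalised fundamental (log Hz minus the syllable-wide mean) and vibrato
#' amplitude (half the peak-to-trough range of the detrended fundamental
#' over a sliding window). Unvoiced frames carry the last voiced
#' fundamental forward (leading unvoiced frames are back-filled) so that
#' contours are complete for DTW; a `voiced` flag is retained.
#'
#' @param s A preprocessed `syllable`.
#' @param frame_step,frame_win Frame step and window length in seconds.
#' @param f0_range Fundamental search range in Hz.
#' @param voicing_threshold Minimum normalised autocorrelation peak for a
#'   frame to count as voiced.
#' @return A `feature_contours` data.frame, one row per frame.
#' @export
extract_contours <- function(s, frame_step = 0.005, frame_win = 0.010,
                             f0_range = c(300, 4000),
                             voicing_threshold = 0.3) {
  stopifnot(inherits(s, "syllable"))
  rate <- s$rate
  win <- max(32L, round(frame_win * rate))
  hop <- max(1L, round(frame_step * rate))
  x <- s$samples
  if (length(x) < win) x <- c(x, numeric(win - length(x)))
  n_frames <- 1L + (length(x) - win) %/% hop
  n_fft <- 2^ceiling(log2(win * 2))
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(win) / (win + 1)))
  half <- n_fft %/% 2 + 1L
  freqs <- (seq_len(half) - 1) * rate / n_fft
  band <- freqs >= 100 & freqs <= min(16000, rate / 2)
  lag_min <- max(2L, floor(rate / f0_range[2]))
  lag_max <- min(win - 1L, ceiling(rate / f0_range[1]))

  f0_hz <- peak_hz <- mean_hz <- wiener <- harm <- numeric(n_frames)
  voiced <- logical(n_frames)
  for (k in seq_len(n_frames)) {
    seg <- x[(k - 1) * hop + seq_len(win)]
    segw <- seg * hann
    spec <- Mod(stats::fft(c(segw, numeric(n_fft - win)))[seq_len(half)])^2
    pb <- spec[band]
    fb <- freqs[band]
    tot <- sum(pb)
    if (tot <= 0) {
      peak_hz[k] <- mean_hz[k] <- NA_real_
      wiener[k] <- 0
      harm[k] <- 0
      voiced[k] <- FALSE
      f0_hz[k] <- NA_real_
      next
    }
    peak_hz[k] <- fb[which.max(pb)]
    mean_hz[k] <- sum(fb * pb) / tot
    sm <- stats::filter(pb, rep(1 / 16, 16), sides = 2)
    sm <- sm[!is.na(sm)]
    sm <- pmax(as.numeric(sm), .Machine$double.xmin)
    wiener[k] <- mean(log(sm)) - log(mean(sm))
    # autocorrelation fundamental
    seg0 <- seg - mean(seg)
    ac <- stats::fft(Mod(stats::fft(c(seg0, numeric(win))))^2, inverse = TRUE)
    ac <- Re(ac)[seq_len(win)]
    if (ac[1] > 0 && lag_max > lag_min) {
      acn <- ac / ac[1]
      lag_window <- lag_min:lag_max
      best <- lag_window[which.max(acn[lag_window + 1L])]
      if (acn[best + 1L] >= voicing_threshold) {
        voiced[k] <- TRUE
        f0_hz[k] <- rate / best
      } else f0_hz[k] <- NA_real_
    } else f0_hz[k] <- NA_real_
    if (voiced[k]) {
      hp <- 0
      # band at least as wide as the analysis window's spectral mainlobe,
      # otherwise a clean partial leaks most of its power out of the band
      for (h in seq_len(8)) {
        hf <- h * f0_hz[k]
        if (hf > max(fb)) break
        hw <- max(0.05 * hf, 1.5 * rate / win)
        hp <- hp + sum(pb[fb >= hf - hw & fb <= hf + hw])
      }
      harm[k] <- min(1, hp / tot)
    } else harm[k] <- 0
  }
  # fill unvoiced fundamentals: carry forward, back-fill leading frames
  if (!any(voiced)) {
    f0_filled <- rep(sqrt(prod(f0_range)), n_frames)
  } else {
    f0_filled <- f0_hz
    last <- NA_real_
    for (k in seq_len(n_frames)) {
      if (voiced[k]) last <- f0_filled[k] else f0_filled[k] <- last
    }
    first_voiced <- which(voiced)[1]
    if (first_voiced > 1) f0_filled[seq_len(first_voiced - 1)] <-
      f0_filled[first_voiced]
  }
  peak_fill <- fill_na(peak_hz)
  mean_fill <- fill_na(mean_hz)

  dt <- hop / rate
  slope_tf <- function(f) {
    d <- c(0, diff(f)) / dt
    asin(pmax(-1, pmin(1, d / 5e4)))
  }
  logf0 <- log(f0_filled)
  vib <- vibrato_amplitude(f0_filled, width = max(3L, round(0.05 / dt)))
  data.frame(
    time = (seq_len(n_frames) - 1) * dt,
    fundamental_frequency = logf0,
    peak_frequency = log(peak_fill),
    mean_frequency = log(mean_fill),
    fundamental_change = slope_tf(f0_filled),
    peak_change = slope_tf(peak_fill),
    normalized_fundamental = logf0 - mean(logf0),
    wiener_entropy = pmin(wiener, 0),
    harmonicity = harm,
    vibrato_amplitude = vib,
    voiced = voiced)
}

fill_na <- function(x) {
  if (!any(is.na(x))) return(x)
  if (all(is.na(x))) return(rep(1, length(x)))
  idx <- which(!is.na(x))
  filled <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  filled
}

#' Half peak-to-trough range of the detrended contour over a sliding window
#' @noRd
vibrato_amplitude <- function(f0, width) {
  n <- length(f0)
  if (width %% 2 == 0) width <- width + 1L
  trend <- stats::filter(f0, rep(1 / width, width), sides = 2)
  trend <- as.numeric(trend)
  trend[is.na(trend)] <- f0[is.na(trend)]
  resid <- f0 - trend
  half <- width %/% 2
  vapply(seq_len(n), function(k) {
    w <- resid[max(1, k - half):min(n, k + half)]
    (max(w) - min(w)) / 2
  }, numeric(1))
}

#' Per-syllable summary statistics of feature contours
#'
#' Mean, maximum, minimum, start and end of five contour features
#' (fundamental frequency, peak frequency, fundamental frequency change,
#' Wiener entropy, harmonicity) plus log syllable length: 26 values. Start
#' and end are the first and last voiced-frame values; fundamental and peak
#' frequency enter on the log scale (as stored in the contours).
#'
#' @param contours A `feature_contours` data.frame with a `voiced` column.
#' @param duration Syllable duration in seconds.
#' @return Named numeric vector of 26 statistics
#'   (`<feature>_<statistic>` plus `syllable_length`).
#' @export
summary_statistics <- function(contours, duration) {
  if (!any(contours$voiced)) stop("no voiced frames")
  feats <- c("fundamental_frequency", "peak_frequency",
             "fundamental_change", "wiener_entropy", "harmonicity")
  vidx <- which(contours$voiced)
  out <- c()
  for (f in feats) {
    v <- contours[[f]]
    out[paste0(f, "_mean")] <- mean(v)
    out[paste0(f, "_max")] <- max(v)
    out[paste0(f, "_min")] <- min(v)
    out[paste0(f, "_start")] <- v[vidx[1]]
    out[paste0(f, "_end")] <- v[vidx[length(vidx)]]
  }
  out["syllable_length"] <- log(duration)
  out
}

#' Summary statistics table for a corpus
#'
#' @param syllables Named list of `syllable` objects (preprocessed or raw;
#'   raw syllables are preprocessed first).
#' @param preprocess Apply [preprocess_syllable()] first (default `TRUE`).
#' @return Data.frame: one row per syllable, 26 statistic columns, rownames
#'   = syllable ids.
#' @export
corpus_summary_stats <- function(syllables, preprocess = TRUE) {
  rows <- lapply(syllables, function(s) {
    if (preprocess) s <- preprocess_syllable(s)
    ct <- extract_contours(s)
    summary_statistics(ct, length(s$samples) / s$rate)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- names(syllables)
  tab
}
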