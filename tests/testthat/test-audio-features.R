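test_that("preprocessing enforces its contracts", {
  s <- generate_syllable(syllable_params(duration = 0.15,
                                         noise_fraction = 0.2, seed = 2L))
  out <- preprocess_syllable(s)
  expect_equal(max(abs(out$samples)), 1)
  expect_length(out$samples, length(s$samples))
  silent <- structure(list(id = "z", samples = numeric(4800), rate = 48000),
                      class = "syllable")
  expect_error(preprocess_syllable(silent), "silent")
  short <- structure(list(id = "s", samples = stats::rnorm(1500),
                          rate = 48000), class = "syllable")
  expect_error(preprocess_syllable(short), "40 ms")
})

test_that("the high-pass filter passes 600 Hz and removes 50 Hz", {
  rms <- function(x) sqrt(mean(x^2))
  t600 <- tone_syllable(600)
  t50 <- tone_syllable(50)
  expect_gt(rms(highpass_filter(t600)$samples) / rms(t600$samples), 0.95)
  expect_lt(rms(highpass_filter(t50)$samples) / rms(t50$samples), 0.10)
})

test_that("mel spectrograms are 150 x 170 for any duration", {
  for (dur in c(0.05, 0.12, 0.3)) {
    s <- preprocess_syllable(generate_syllable(
      syllable_params(duration = dur, seed = 1L)))
    m <- mel_spectrogram(s)
    expect_identical(dim(m$values), c(150L, 170L))
    expect_true(all(is.finite(m$values)))
    expect_true(all(m$values >= m$floor_db))
  }
  # a syllable longer than 170 frames is centre-cropped, never padded
  long <- structure(list(id = "l", samples = stats::rnorm(30000),
                         rate = 48000), class = "syllable")
  expect_identical(dim(mel_spectrogram(preprocess_syllable(long))$values),
                   c(150L, 170L))
})

test_that("a pure tone concentrates mel energy at its frequency", {
  s <- preprocess_syllable(tone_syllable(600))
  m <- mel_spectrogram(s)
  peak_band <- which.max(rowSums(m$values))
  expect_lt(abs(m$band_centers[peak_band] - 600), 30)
})

test_that("padded frames equal the log floor exactly", {
  s <- preprocess_syllable(generate_syllable(
    syllable_params(duration = 0.05, seed = 4L)))
  m <- mel_spectrogram(s)
  expect_true(all(m$values[, 1] == m$floor_db))
  expect_true(all(m$values[, 170] == m$floor_db))
})

test_that("contours recover tone properties", {
  ct <- extract_contours(preprocess_syllable(tone_syllable(600)))
  mid <- ct[ct$voiced, ]
  expect_lt(abs(exp(stats::median(mid$fundamental_frequency)) - 600), 15)
  expect_lt(abs(exp(stats::median(mid$peak_frequency)) - 600), 60)
  expect_lt(stats::median(mid$wiener_entropy), -3)
  expect_gt(stats::median(mid$harmonicity), 0.8)
  # constant f0: change and normalised fundamental near zero
  expect_lt(max(abs(mid$fundamental_change)), 0.05)
  expect_lt(stats::median(abs(mid$normalized_fundamental)), 0.02)
  expect_true(all(diff(ct$time) > 0))
  expect_true(all(ct$wiener_entropy <= 0))
})

test_that("white noise yields near-zero entropy and low harmonicity", {
  s <- preprocess_syllable(generate_syllable(
    syllable_params(duration = 0.15, noise_fraction = 1, seed = 5L)))
  ct <- extract_contours(s)
  expect_gt(stats::median(ct$wiener_entropy), -0.5)
  expect_lt(stats::median(ct$harmonicity), 0.3)
})

test_that("summary statistics obey their definitions", {
  ct <- extract_contours(preprocess_syllable(tone_syllable(700)))
  st <- summary_statistics(ct, 0.1)
  expect_length(st, 26)
  expect_equal(unname(st["syllable_length"]), log(0.1))
  for (f in c("fundamental_frequency", "wiener_entropy", "harmonicity")) {
    expect_lte(st[paste0(f, "_min")], st[paste0(f, "_mean")])
    expect_lte(st[paste0(f, "_mean")], st[paste0(f, "_max")])
  }
  # constant contour: all five statistics coincide
  const <- ct
  const$fundamental_frequency <- rep(log(700), nrow(ct))
  stc <- summary_statistics(const, 0.1)
  vals <- stc[paste0("fundamental_frequency_",
                     c("mean", "max", "min", "start", "end"))]
  expect_equal(unname(diff(range(vals))), 0)
  # monotone rising contour: start = min, end = max
  rise <- ct
  rise$fundamental_frequency <- seq(log(500), log(900),
                                    length.out = nrow(ct))
  rise$voiced <- rep(TRUE, nrow(ct))
  str_ <- summary_statistics(rise, 0.1)
  expect_equal(unname(str_["fundamental_frequency_start"]),
               unname(str_["fundamental_frequency_min"]))
  expect_equal(unname(str_["fundamental_frequency_end"]),
               unname(str_["fundamental_frequency_max"]))
  unvoiced <- ct
  unvoiced$voiced <- rep(FALSE, nrow(ct))
  expect_error(summary_statistics(unvoiced, 0.1), "voiced")
})

test_that("contour summaries are robust to sub-hop time shifts", {
  s <- preprocess_syllable(generate_syllable(
    syllable_params(duration = 0.15, noise_fraction = 0.1, seed = 6L)))
  pad <- structure(list(id = "p", samples = c(numeric(100), s$samples,
                                              numeric(140)),
                        rate = s$rate), class = "syllable")
  shifted <- structure(list(id = "q",
                            samples = c(numeric(220), s$samples,
                                        numeric(20)),
                            rate = s$rate), class = "syllable")
  st1 <- summary_statistics(extract_contours(pad), 0.2)
  st2 <- summary_statistics(extract_contours(shifted), 0.2)
  keep <- c("fundamental_frequency_mean", "wiener_entropy_mean",
            "harmonicity_mean")
  expect_lt(max(abs(st1[keep] - st2[keep]) / pmax(0.05, abs(st1[keep]))),
            0.01)
})
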