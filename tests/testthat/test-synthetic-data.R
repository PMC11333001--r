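test_that("syllable generation is deterministic and validates parameters", {
  p <- syllable_params(duration = 0.1, noise_fraction = 0.3, seed = 7L)
  s1 <- generate_syllable(p)
  s2 <- generate_syllable(p)
  expect_identical(s1$samples, s2$samples)
  expect_equal(s1$rate, 48000)
  expect_error(syllable_params(duration = 0.4), "duration")
  expect_error(syllable_params(noise_fraction = 1.5), "noise_fraction")
  expect_error(syllable_params(f0_start = 50), "f0_start")
})

test_that("a pure tone has its spectral peak at the requested frequency", {
  s <- generate_syllable(syllable_params(duration = 0.2, f0_start = 600,
                                         f0_end = 600, f0_mod_depth = 0,
                                         n_harmonics = 1,
                                         noise_fraction = 0))
  spec <- Mod(stats::fft(s$samples))^2
  half <- seq_len(length(spec) %/% 2)
  peak_hz <- (which.max(spec[half]) - 1) * s$rate / length(s$samples)
  bin <- s$rate / length(s$samples)
  expect_lt(abs(peak_hz - 600), bin + 1e-9)
})

test_that("noise-dominated syllables have flatter spectra than tonal ones", {
  entropy_of <- function(nf) {
    s <- generate_syllable(syllable_params(duration = 0.15,
                                           noise_fraction = nf, seed = 3L))
    ct <- extract_contours(preprocess_syllable(s))
    stats::median(ct$wiener_entropy)
  }
  e_noise <- entropy_of(1)
  e_tone <- entropy_of(0)
  expect_gt(e_noise, e_tone)
  expect_gt(e_noise, -0.5)   # near the log-flatness maximum of 0
  expect_lt(e_tone, -3)
})

test_that("corpus generation has the right cardinality and determinism", {
  c1 <- generate_corpus(20, seed = 1)
  c2 <- generate_corpus(20, seed = 1)
  expect_length(c1$syllables, 20)
  expect_equal(nrow(c1$params), 20)
  expect_identical(c1$params, c2$params)
  expect_equal(nrow(c1$space$coords), 20)
  lat <- as.matrix(planted_distances(c1$space))
  expect_true(all(diag(lat) == 0))
  expect_error(generate_corpus(1), "n")
})

test_that("corpus WAV export round-trips", {
  dir <- withr::local_tempdir()
  corp <- generate_corpus(3, seed = 2, out_dir = dir)
  expect_length(list.files(dir, pattern = "\\.wav$"), 3)
  w <- read_wav(file.path(dir, paste0(corp$params$id[1], ".wav")))
  expect_equal(w$rate, 48000)
  expect_equal(w$samples, corp$syllables[[1]]$samples, tolerance = 1e-3)
})

test_that("choice probability is logistic, symmetric and monotone", {
  expect_equal(choice_probability(0, 0.2), 0.5)
  xs <- seq(-1, 1, by = 0.1)
  ps <- choice_probability(xs, 0.2)
  expect_true(all(diff(ps) < 0))
  # zero-noise limit is deterministic
  expect_equal(choice_probability(c(-0.3, 0, 0.4), 0), c(1, 0.5, 0))
})

test_that("training-trial accuracy matches the bird's accuracy level", {
  corp <- generate_corpus(40, seed = 6)
  ids <- corp$params$id
  set <- stimulus_set("s", ids[1:8], ids[9:16], ids[17:20])
  sim <- simulate_trials(corp$space, list(s = set), c(b = 0.7),
                         repeats = 2, n_training_trials = 1000, seed = 5)
  acc <- cycle_accuracy(sim$trials, "b", "b_c01")
  se <- sqrt(0.7 * 0.3 / 1000)
  expect_lt(abs(acc - 0.7), 3 * se)
})

test_that("zero decision noise makes every probe choice follow the planted metric", {
  corp <- generate_corpus(40, seed = 8, noise_scale = 0)
  lat <- as.matrix(planted_distances(corp$space))
  ids <- corp$params$id
  set <- stimulus_set("s", ids[1:8], ids[9:16], ids[17:24], side_of_A = "L")
  sim <- simulate_trials(corp$space, list(s = set), c(b = 1), repeats = 2,
                         seed = 3)
  probes <- sim$trials[sim$trials$role == "probe", ]
  for (i in seq_len(nrow(probes))) {
    dA <- mean(lat[probes$stimulus_id[i], set$side_A_ids])
    dB <- mean(lat[probes$stimulus_id[i], set$side_B_ids])
    expect_equal(probes$chosen_side[i], if (dA < dB) "L" else "R")
  }
})

test_that("simulated trials are reproducible under a fixed seed", {
  corp <- generate_corpus(40, seed = 9)
  ids <- corp$params$id
  set <- stimulus_set("s", ids[1:8], ids[9:16], ids[17:20])
  s1 <- simulate_trials(corp$space, list(s = set), c(b = 0.8), seed = 11)
  s2 <- simulate_trials(corp$space, list(s = set), c(b = 0.8), seed = 11)
  expect_identical(s1$trials, s2$trials)
  expect_error(simulate_trials(corp$space, list(s = set), c(b = 0.4),
                               seed = 1),
               "accuracies")
})

test_that("binned choice frequencies match the logistic within binomial error", {
  # mirrors the binned log-odds construction of the calibration figure
  ns <- 0.25
  set.seed(21)
  xp <- stats::runif(4000, -0.8, 0.8)
  chose_A <- stats::runif(4000) < choice_probability(xp, ns)
  bins <- cut(xp, breaks = stats::quantile(xp, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    p_hat <- mean(chose_A[idx])
    p_exp <- mean(choice_probability(xp[idx], ns))
    se <- sqrt(p_exp * (1 - p_exp) / sum(idx))
    expect_lt(abs(p_hat - p_exp), 4 * se + 1e-9)
  }
})
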