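# Synthetic zebra-finch-like syllables: harmonic stacks with a time-varying
# fundamental (linear ramp + sinusoidal vibrato), per-harmonic rolloff and a
# controllable broadband noise share. The generator gives every downstream
# stage a ground truth: the latent "perceptual" coordinates of each syllable
# are a deterministic function of its acoustic parameters.

#' Evaluate code under a private RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Parameters of one synthetic syllable
#'
#' @param duration Syllable length in seconds, in `[0.05, 0.3]`.
#' @param f0_start,f0_end Fundamental frequency at onset/offset, Hz, in
#'   `[400, 1500]`.
#' @param f0_mod_depth Sinusoidal vibrato depth in Hz (>= 0).
#' @param f0_mod_rate Vibrato rate in Hz (>= 0).
#' @param n_harmonics Number of harmonics in the stack (>= 1).
#' @param harmonic_rolloff Amplitude decay per harmonic in dB (>= 0).
#' @param noise_fraction Share of waveform power carried by broadband Gaussian
#'   noise, in `[0, 1]`. Controls Wiener entropy of the result.
#' @param seed Integer seed making the syllable reproducible.
#' @return An object of class `syllable_params`.
#' @export
syllable_params <- function(duration = 0.15, f0_start = 600, f0_end = 600,
                            f0_mod_depth = 0, f0_mod_rate = 0,
                            n_harmonics = 4, harmonic_rolloff = 6,
                            noise_fraction = 0.1, seed = 1L) {
  check_range <- function(x, lo, hi, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
      stop(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi))
  }
  check_range(duration, 0.05, 0.3, "duration")
  check_range(f0_start, 100, 24000 - 1e-9, "f0_start")
  check_range(f0_end, 100, 24000 - 1e-9, "f0_end")
  check_range(f0_mod_depth, 0, 500, "f0_mod_depth")
  check_range(f0_mod_rate, 0, 200, "f0_mod_rate")
  if (n_harmonics < 1 || n_harmonics != round(n_harmonics))
    stop("'n_harmonics' must be an integer >= 1")
  check_range(harmonic_rolloff, 0, 60, "harmonic_rolloff")
  check_range(noise_fraction, 0, 1, "noise_fraction")
  structure(list(duration = duration, f0_start = f0_start, f0_end = f0_end,
                 f0_mod_depth = f0_mod_depth, f0_mod_rate = f0_mod_rate,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_rolloff = harmonic_rolloff,
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "syllable_params")
}

#' Generate one synthetic syllable
#'
#' Renders a harmonic stack whose fundamental follows a linear
#' `f0_start` to `f0_end` ramp plus sinusoidal vibrato, with harmonic
#' amplitudes decaying by `harmonic_rolloff` dB per harmonic, mixed with
#' Gaussian noise so that the noise carries `noise_fraction` of the power.
#' Bit-identical output for identical parameters (including `seed`).
#'
#' @param params A [syllable_params()] object.
#' @param id Syllable identifier string.
#' @param rate Sample rate in Hz (default 48000).
#' @return A `syllable`: list with `id`, `samples`, `rate`.
#' @export
generate_syllable <- function(params, id = "syl", rate = 48000) {
  if (!inherits(params, "syllable_params"))
    params <- do.call(syllable_params, as.list(params))
  n <- max(2L, round(params$duration * rate))
  t <- (seq_len(n) - 1) / rate
  f0 <- params$f0_start +
    (params$f0_end - params$f0_start) * t / params$duration +
    params$f0_mod_depth * sin(2 * pi * params$f0_mod_rate * t)
  f0 <- pmax(f0, 1)
  phase <- 2 * pi * cumsum(f0) / rate
  tone <- numeric(n)
  nyq <- rate / 2
  for (h in seq_len(params$n_harmonics)) {
    if (max(f0) * h >= nyq) break
    amp <- 10^(-params$harmonic_rolloff * (h - 1) / 20)
    tone <- tone + amp * sin(h * phase)
  }
  nf <- params$noise_fraction
  noise <- with_seed(params$seed, rnorm(n))
  unit_rms <- function(x) {
    r <- sqrt(mean(x^2))
    if (r > 0) x / r else x
  }
  x <- if (nf >= 1) {
    unit_rms(noise)
  } else if (nf <= 0) {
    unit_rms(tone)
  } else {
    sqrt(1 - nf) * unit_rms(tone) + sqrt(nf) * unit_rms(noise)
  }
  x <- x / max(abs(x))
  structure(list(id = id, samples = x, rate = rate), class = "syllable")
}

#' @export
print.syllable <- function(x, ...) {
  cat(sprintf("<syllable> %s: %.1f ms at %d Hz\n", x$id,
              1000 * length(x$samples) / x$rate, x$rate))
  invisible(x)
}

#' Generate a synthetic syllable corpus with a planted perceptual space
#'
#' Samples `n` syllables with parameters drawn from realistic ranges and
#' derives for each a latent coordinate vector — the planted perceptual
#' space in which simulated birds judge similarity. Coordinates are a
#' deterministic function of the acoustic parameters (standardised mean
#' log-fundamental, duration and noise fraction), so the acoustic pipeline
#' and the decision pipeline share one ground truth.
#'
#' @param n Number of syllables (>= 2).
#' @param seed Integer seed.
#' @param noise_scale Logistic decision temperature stored in the planted
#'   space (see [simulate_trials()]).
#' @param out_dir Optional directory; if given, per-syllable WAV files and a
#'   `params.csv` table are written there.
#' @return A list with `syllables` (named list of `syllable`), `params`
#'   (data.frame, one row per syllable) and `space` (a `planted_space`:
#'   `coords` matrix with rownames = syllable ids, `noise_scale`).
#' @export
generate_corpus <- function(n, seed = 1L, noise_scale = 0.1, out_dir = NULL) {
  if (!is.numeric(n) || n < 2) stop("'n' must be >= 2")
  n <- as.integer(n)
  params <- with_seed(seed, data.frame(
    id = sprintf("syl%03d", seq_len(n)),
    duration = runif(n, 0.05, 0.3),
    f0_start = runif(n, 400, 1500),
    f0_end = runif(n, 400, 1500),
    f0_mod_depth = runif(n, 0, 80),
    f0_mod_rate = runif(n, 10, 40),
    n_harmonics = sample(1:8, n, replace = TRUE),
    harmonic_rolloff = runif(n, 0, 12),
    noise_fraction = runif(n, 0, 0.8),
    seed = sample.int(1e6, n),
    stringsAsFactors = FALSE))
  syllables <- lapply(seq_len(n), function(i) {
    p <- params[i, ]
    generate_syllable(syllable_params(
      duration = p$duration, f0_start = p$f0_start, f0_end = p$f0_end,
      f0_mod_depth = p$f0_mod_depth, f0_mod_rate = p$f0_mod_rate,
      n_harmonics = p$n_harmonics, harmonic_rolloff = p$harmonic_rolloff,
      noise_fraction = p$noise_fraction, seed = p$seed), id = p$id)
  })
  names(syllables) <- params$id
  space <- planted_space_from_params(params, noise_scale)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in syllables)
      write_wav(s$samples, s$rate, file.path(out_dir, paste0(s$id, ".wav")))
    utils::write.csv(params, file.path(out_dir, "params.csv"),
                     row.names = FALSE)
  }
  list(syllables = syllables, params = params, space = space)
}

#' Planted perceptual space from a syllable parameter table
#'
#' Latent coordinates: standardised mean log-fundamental, standardised
#' duration and standardised noise fraction. Deterministic in the table.
#'
#' @param params Parameter table as produced by [generate_corpus()].
#' @param noise_scale Positive logistic temperature for simulated decisions.
#' @return A `planted_space` object.
#' @export
planted_space_from_params <- function(params, noise_scale = 0.1) {
  if (noise_scale < 0) stop("'noise_scale' must be >= 0")
  zs <- function(x) {
    s <- stats::sd(x)
    if (s == 0) x - mean(x) else (x - mean(x)) / s
  }
  coords <- cbind(
    logf0 = zs(log((params$f0_start + params$f0_end) / 2)),
    duration = zs(params$duration),
    noisiness = zs(params$noise_fraction))
  rownames(coords) <- params$id
  structure(list(coords = coords, noise_scale = noise_scale),
            class = "planted_space")
}

#' Pairwise distances in a planted perceptual space
#'
#' @param space A `planted_space`.
#' @return A [dissimilarity_matrix()] of Euclidean latent distances.
#' @export
planted_distances <- function(space) {
  d <- as.matrix(stats::dist(space$coords))
  dissimilarity_matrix_from_values(d, rownames(space$coords))
}
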