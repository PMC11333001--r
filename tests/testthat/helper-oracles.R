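# Independent oracles and shared fixtures for the test suite.

# Pure-tone syllable fixture
tone_syllable <- function(freq = 600, duration = 0.2, rate = 48000,
                          id = "tone") {
  structure(list(id = id,
                 samples = sin(2 * pi * freq * (seq_len(duration * rate) - 1)
                               / rate),
                 rate = rate),
            class = "syllable")
}

# Brute-force DTW oracle: enumerate every monotone alignment (steps
# diagonal/insert/delete), take the minimum summed weighted-Euclidean point
# cost, and normalise by that path's length. Only for lengths <= 5.
dtw_oracle <- function(a, b, w) {
  n <- nrow(a); m <- nrow(b)
  best <- Inf
  best_len <- NA_integer_
  point_cost <- function(i, j) sqrt(sum(w * (a[i, ] - b[j, ])^2))
  rec <- function(i, j, total, len) {
    total <- total + point_cost(i, j)
    if (i == n && j == m) {
      if (total < best) {
        best <<- total
        best_len <<- len
      }
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, total, len + 1)
    if (i < n) rec(i + 1, j, total, len + 1)
    if (j < m) rec(i, j + 1, total, len + 1)
  }
  rec(1, 1, 0, 1)
  best / best_len
}

# Classical (Torgerson) MDS oracle via explicit double-centring and
# eigendecomposition.
cmds_oracle <- function(D, k = 2) {
  n <- nrow(D)
  B <- -0.5 * (diag(n) - 1 / n) %*% (D^2) %*% (diag(n) - 1 / n)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- pmax(e$values[seq_len(k)], 0)
  e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
}

# OLS via explicit normal equations.
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Small shared synthetic study (cached across test files). Sized down from
# the package default so the whole-suite cost stays small.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_axb_study(n_syllables = 60, n_sets = 2,
                                   n_probes = 12, n_birds = 6,
                                   repeats = 3, seed = 404)
    cache
  }
})

# The full-size benchmark study used by the end-to-end acceptance checks;
# built once and shared, as are the unambiguous-only training runs.
bench_env <- new.env(parent = emptyenv())

bench_study <- function() {
  if (is.null(bench_env$study)) {
    bench_env$study <- simulate_axb_study(seed = 101)
    bench_env$X <- study_input_array(bench_env$study)
  }
  list(study = bench_env$study, X = bench_env$X)
}

bench_u_accuracy <- function(seed) {
  key <- paste0("u", seed)
  if (is.null(bench_env[[key]])) {
    b <- bench_study()
    bench_env[[key]] <- embedding_recovery_run(
      b$study, b$X, sources = "U", d = 16, epochs = 100,
      seed = seed)$accuracy
  }
  bench_env[[key]]
}

# A tiny trial log with known composition, written by hand.
# bird good: cycle accuracy 0.8 (8/10); bird poor: accuracy 0.6 (6/10).
hand_trial_log <- function() {
  mk_train <- function(bird, cycle, n_correct, n_total) {
    data.frame(bird_id = bird, cycle_id = cycle,
               stimulus_id = sprintf("tr%02d", seq_len(n_total)),
               role = "training", correct_side = "L",
               chosen_side = c(rep("L", n_correct),
                               rep("R", n_total - n_correct)),
               rewarded = c(rep(TRUE, n_correct),
                            rep(FALSE, n_total - n_correct)),
               timestamp = seq_len(n_total), device_ok = TRUE,
               stringsAsFactors = FALSE)
  }
  mk_probe <- function(bird, cycle, probe, sides) {
    data.frame(bird_id = bird, cycle_id = cycle, stimulus_id = probe,
               role = "probe", correct_side = "none", chosen_side = sides,
               rewarded = TRUE, timestamp = 100 + seq_along(sides),
               device_ok = TRUE, stringsAsFactors = FALSE)
  }
  rbind(
    mk_train("good", "c1", 8, 10),
    # unambiguous: 3 L of 3 -> consistency 1
    mk_probe("good", "c1", "p1", c("L", "L", "L")),
    # unambiguous: 3 of 4 -> consistency 0.75 > 0.70
    mk_probe("good", "c1", "p2", c("L", "L", "L", "R")),
    # ambiguous: 2 of 3 -> consistency 2/3
    mk_probe("good", "c1", "p3", c("L", "L", "R")),
    # ambiguous: tie 1-1 -> consistency 0.5
    mk_probe("good", "c1", "p4", c("L", "R")),
    # single decision: excluded from both datasets
    mk_probe("good", "c1", "p5", "L"),
    # poor bird (accuracy 0.6 < 0.65): everything excluded
    mk_train("poor", "c1", 6, 10),
    mk_probe("poor", "c1", "p1", c("L", "L", "L")),
    mk_probe("poor", "c1", "p3", c("R", "R", "R")))
}

hand_stimulus_sets <- function() {
  list(setX = stimulus_set("setX",
                           side_A_ids = sprintf("a%d", 1:8),
                           side_B_ids = sprintf("b%d", 1:8),
                           probe_ids = sprintf("p%d", 1:5),
                           side_of_A = "L"))
}

hand_cycle_sets <- function() {
  data.frame(cycle_id = "c1", stimulus_set_id = "setX",
             stringsAsFactors = FALSE)
}
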