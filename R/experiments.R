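# Packaged end-to-end simulation experiments: a synthetic corpus with a
# planted perceptual space, simulated operant decisions, the behavioural
# filters, and embedding training — the package's own recovery benchmarks.

#' Build a synthetic AXB study: corpus, stimulus sets and decision log
#'
#' Generates a syllable corpus with a planted perceptual space, selects
#' stimulus sets by similarity rank in that space (rank windows scaled to
#' the corpus size), simulates operant trials for a group of birds, applies
#' the behavioural filters and splits triplets into training and held-out
#' evaluation sets.
#'
#' @param n_syllables Corpus size (default 120).
#' @param n_sets Number of stimulus sets (default 2).
#' @param n_probes Probes per set (default 40).
#' @param n_birds Number of birds (default 18).
#' @param accuracy_range Bird training-accuracy range (default 0.75-0.9).
#' @param noise_scale Logistic decision temperature of the planted space
#'   (default 0.1, giving a consistency ceiling near 0.85 with 4 repeats).
#' @param repeats Probe presentations per (bird, cycle) (default 4).
#' @param eval_fraction Anchor fraction held out per set (default 0.25).
#' @param seed Integer seed.
#' @return List with `corpus`, `sets`, `trials`, `cycles`, `accuracies`,
#'   `decisions`, `datasets` (unambiguous/ambiguous), `split` (train/eval of
#'   the unambiguous set), `bounds` (attainable-accuracy bounds on the
#'   evaluation decisions).
#' @export
simulate_axb_study <- function(n_syllables = 120, n_sets = 2, n_probes = 40,
                               n_birds = 18, accuracy_range = c(0.75, 0.9),
                               noise_scale = 0.1, repeats = 4,
                               eval_fraction = 0.25, seed = 1L) {
  corpus <- generate_corpus(n_syllables, seed = seed,
                            noise_scale = noise_scale)
  lat <- planted_distances(corpus$space)
  rb <- round(c(0.25, 0.75) * n_syllables)
  pr <- round(c(0.08, 0.92) * n_syllables)
  sets <- list()
  for (k in seq_len(n_sets)) {
    sets[[sprintf("set%d", k)]] <- select_stimulus_set(
      lat, seed = seed + 1000L + k, n_side = 8, rank_B = rb,
      probe_ranks = pr, n_probes = n_probes, id = sprintf("set%d", k),
      side_of_A = if (k %% 2 == 1) "L" else "R")
  }
  acc <- with_seed(seed + 5L,
                   stats::runif(n_birds, accuracy_range[1],
                                accuracy_range[2]))
  names(acc) <- sprintf("bird%02d", seq_len(n_birds))
  sim <- simulate_trials(corpus$space, sets, acc, repeats = repeats,
                         n_training_trials = 60, seed = seed + 9L)
  acc_tab <- cycle_accuracy_table(sim$trials)
  decisions <- consolidate_probe_decisions(sim$trials, sim$cycles)
  datasets <- build_triplet_datasets(decisions, acc_tab, sets)
  split <- split_triplets(datasets$unambiguous, eval_fraction,
                          seed = seed + 17L)
  eval_keys <- paste(split$eval$bird_id, split$eval$cycle_id)
  eval_cycles <- acc_tab[paste(acc_tab$bird_id, acc_tab$cycle_id) %in%
                           eval_keys, , drop = FALSE]
  eval_dec <- decisions[paste(decisions$bird_id, decisions$cycle_id) %in%
                          eval_keys, , drop = FALSE]
  bounds <- attainable_bounds(eval_cycles, eval_dec)
  list(corpus = corpus, sets = sets, trials = sim$trials,
       cycles = sim$cycles, accuracies = acc_tab, decisions = decisions,
       datasets = datasets, split = split, bounds = bounds)
}

#' Mel-spectrogram input array for the syllables referenced by a study
#'
#' @param study Result of [simulate_axb_study()].
#' @param ids Syllable ids to include (default: all training stimuli and
#'   probes of the study's sets).
#' @return Input array for [train_embedder()].
#' @export
study_input_array <- function(study, ids = NULL) {
  if (is.null(ids)) {
    ids <- unique(unlist(lapply(study$sets, function(s)
      c(s$side_A_ids, s$side_B_ids, s$probe_ids))))
  }
  mels <- lapply(study$corpus$syllables[ids], function(s)
    mel_spectrogram(preprocess_syllable(s)))
  mel_input_array(mels)
}

#' Train an embedder on a simulated study and score held-out agreement
#'
#' Trains on the study's training triplets (sources as requested) and
#' reports agreement of embedding-space AXB decisions with the held-out
#' unambiguous bird decisions.
#'
#' @param study Result of [simulate_axb_study()].
#' @param X Input array from [study_input_array()] (rebuilt if `NULL`).
#' @param sources Training sources, subset of `c("U", "A")` plus `"L"` if
#'   `machine_triplets` supplied.
#' @param machine_triplets Optional machine (L) triplet data.frame.
#' @param d Embedding dimensionality (default 16).
#' @param epochs Training epochs (default 100).
#' @param seed Integer seed (network init, exemplar sampling).
#' @param ... Further arguments passed to [train_config()].
#' @return List with `model`, `accuracy` (held-out agreement), `report`
#'   (the [axb_accuracy()] report), `bounds` and triplet counts.
#' @export
embedding_recovery_run <- function(study, X = NULL, sources = "U",
                                   machine_triplets = NULL, d = 16,
                                   epochs = 100, seed = 1L, ...) {
  if (is.null(X)) X <- study_input_array(study)
  datasets <- list(U = study$split$train,
                   A = study$datasets$ambiguous,
                   L = machine_triplets)
  cfg <- train_config(sources = sources, epochs = epochs, seed = seed, ...)
  model <- init_embedder(network_config(d = d), seed = seed)
  model <- train_embedder(model, X, datasets, cfg)
  md <- method_decisions(model$embeddings, study$split$eval)
  report <- axb_accuracy(md$agree, method = paste(sources, collapse = "+"),
                         seed = seed)
  list(model = model, accuracy = report$accuracy, report = report,
       bounds = study$bounds,
       n_train = nrow(study$split$train), n_eval = nrow(study$split$eval),
       n_ambiguous = nrow(study$datasets$ambiguous))
}
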