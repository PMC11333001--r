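# Simulated operant AXB decision logs. Training-trial responses follow each
# bird's accuracy level; probe choices follow a logistic decision rule on
# the planted-space relative dissimilarity, the inverse of the monotone
# choice-distance relation observed behaviourally, with an optional side
# bias. noise_scale is the logistic temperature: as it approaches zero every
# probe choice matches the planted-space nearer side.

#' Choice probability of the side-A perch given a relative dissimilarity
#'
#' `P(choose A) = 1 / (1 + exp(Xp / noise_scale + bias_against_A))`; at
#' `Xp = 0` with no bias this is 0.5, and it decreases strictly in `Xp`.
#'
#' @param xp Relative dissimilarity oriented so side A is the reference.
#' @param noise_scale Positive logistic temperature; 0 gives the
#'   deterministic limit.
#' @param bias Additive log-odds bias against side A (default 0).
#' @return Probability of choosing side A.
#' @export
choice_probability <- function(xp, noise_scale, bias = 0) {
  if (noise_scale < 0) stop("'noise_scale' must be >= 0")
  if (noise_scale == 0) return(ifelse(xp < 0, 1, ifelse(xp > 0, 0, 0.5)))
  stats::plogis(-(xp / noise_scale + bias))
}

#' Simulate operant AXB trials against a planted perceptual space
#'
#' For every (bird, stimulus set) pair one testing cycle is simulated.
#' Training trials present a random training stimulus; the bird answers
#' correctly with probability equal to its accuracy level. Probe trials
#' present each of the set's probes `repeats` times; the probability of
#' choosing the perch of side A follows [choice_probability()] applied to
#' the planted-space relative dissimilarity
#' `Xp = (D_probeA - D_probeB) / (D_probeA + D_probeB)` (mean latent
#' distance to each side's stimuli). Deterministic given `seed`.
#'
#' @param space A `planted_space` from [generate_corpus()].
#' @param stimulus_sets Named list of `stimulus_set` objects.
#' @param bird_accuracies Named numeric vector, one accuracy in `(0.5, 1]`
#'   per bird; names become bird ids.
#' @param repeats Presentations of each probe per (bird, cycle).
#' @param n_training_trials Training trials per (bird, cycle).
#' @param side_bias Log-odds bias toward the left perch (default 0).
#' @param seed Integer seed.
#' @return List with `trials` (trial data.frame in the standard log schema),
#'   `cycles` (data.frame mapping `bird_id`, `cycle_id` to
#'   `stimulus_set_id`).
#' @export
simulate_trials <- function(space, stimulus_sets, bird_accuracies,
                            repeats = 3, n_training_trials = 60,
                            side_bias = 0, seed = 1L) {
  stopifnot(inherits(space, "planted_space"))
  if (length(stimulus_sets) == 0) stop("need at least one stimulus set")
  if (any(bird_accuracies <= 0.5 | bird_accuracies > 1))
    stop("bird accuracies must lie in (0.5, 1]")
  for (set in stimulus_sets) {
    if (length(set$side_A_ids) < 1 || length(set$side_B_ids) < 1)
      stop("empty stimulus set side")
  }
  if (is.null(names(bird_accuracies)))
    names(bird_accuracies) <- sprintf("bird%02d", seq_along(bird_accuracies))
  if (is.null(names(stimulus_sets)))
    names(stimulus_sets) <- vapply(stimulus_sets, `[[`, "", "id")
  lat <- as.matrix(planted_distances(space))
  ns <- space$noise_scale

  with_seed(seed, {
    trial_rows <- list()
    cycle_rows <- list()
    ts <- 0
    for (bird in names(bird_accuracies)) {
      acc <- bird_accuracies[[bird]]
      for (si in seq_along(stimulus_sets)) {
        set <- stimulus_sets[[si]]
        cycle <- sprintf("%s_c%02d", bird, si)
        cycle_rows[[length(cycle_rows) + 1L]] <-
          data.frame(bird_id = bird, cycle_id = cycle,
                     stimulus_set_id = names(stimulus_sets)[si],
                     stringsAsFactors = FALSE)
        # training block
        stim <- sample(c(set$side_A_ids, set$side_B_ids),
                       n_training_trials, replace = TRUE)
        side_of <- ifelse(stim %in% set$side_A_ids, set$side_of_A,
                          setdiff(c("L", "R"), set$side_of_A))
        correct <- stats::runif(n_training_trials) < acc
        chosen <- ifelse(correct, side_of,
                         ifelse(side_of == "L", "R", "L"))
        t_train <- data.frame(
          bird_id = bird, cycle_id = cycle, stimulus_id = stim,
          role = "training", correct_side = side_of, chosen_side = chosen,
          rewarded = correct,
          timestamp = ts + seq_len(n_training_trials),
          device_ok = TRUE, stringsAsFactors = FALSE)
        ts <- ts + n_training_trials
        # probe block
        probes <- rep(set$probe_ids, each = repeats)
        d_A <- vapply(probes, function(p) mean(lat[p, set$side_A_ids]),
                      numeric(1))
        d_B <- vapply(probes, function(p) mean(lat[p, set$side_B_ids]),
                      numeric(1))
        xp <- ifelse(d_A + d_B > 0, (d_A - d_B) / (d_A + d_B), 0)
        bias_against_A <- if (set$side_of_A == "L") -side_bias else side_bias
        p_A <- choice_probability(xp, ns, bias_against_A)
        choose_A <- stats::runif(length(probes)) < p_A
        side_B_perch <- setdiff(c("L", "R"), set$side_of_A)
        chosen_p <- ifelse(choose_A, set$side_of_A, side_B_perch)
        t_probe <- data.frame(
          bird_id = bird, cycle_id = cycle, stimulus_id = probes,
          role = "probe", correct_side = "none", chosen_side = chosen_p,
          rewarded = TRUE,
          timestamp = ts + seq_along(probes),
          device_ok = TRUE, stringsAsFactors = FALSE)
        ts <- ts + length(probes)
        trial_rows[[length(trial_rows) + 1L]] <- rbind(t_train, t_probe)
      }
    }
    trials <- do.call(rbind, trial_rows)
    rownames(trials) <- NULL
    cycles <- do.call(rbind, cycle_rows)
    rownames(cycles) <- NULL
    list(trials = trials, cycles = cycles)
  })
}
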