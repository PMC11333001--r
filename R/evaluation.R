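# Scoring similarity methods against behavioural AXB decisions: agreement
# accuracy with bootstrap intervals, attainable-accuracy bounds, a
# disagreement MDS across methods, the binned choice-calibration curve, and
# ingestion of dissimilarity matrices produced by external tools.

#' Method decisions for a triplet dataset from a dissimilarity matrix
#'
#' Convenience wrapper running [axb_decide()] for every triplet: side A is
#' the triplet's positive (bird-chosen) side, so `"A"` means agreement.
#'
#' @param D A `dissimilarity_matrix` or embedding matrix (rownames = ids;
#'   a non-square matrix is treated as embeddings).
#' @param triplets Triplet data.frame.
#' @param aggregate Probe-to-side aggregation.
#' @return Data.frame with `agree` (logical, NA = abstention), `Xp`, `tie`.
#' @export
method_decisions <- function(D, triplets, aggregate = "mean") {
  if (is.matrix(D) && nrow(D) != ncol(D)) D <- embedding_distance_matrix(D)
  out <- data.frame(agree = rep(NA, nrow(triplets)),
                    Xp = rep(NA_real_, nrow(triplets)),
                    tie = rep(FALSE, nrow(triplets)))
  for (i in seq_len(nrow(triplets))) {
    dec <- axb_decide(D, triplets$anchor_id[i],
                      triplets$positive_ids[[i]],
                      triplets$negative_ids[[i]], aggregate = aggregate)
    out$Xp[i] <- dec$Xp
    out$tie[i] <- dec$tie
    if (!dec$degenerate && !dec$tie) out$agree[i] <- dec$side == "A"
  }
  out
}

#' AXB agreement accuracy of a method, with bootstrap confidence interval
#'
#' Accuracy is the fraction of scored triplets on which the method chose
#' the same side as the bird's majority decision; abstentions and ties are
#' excluded from the denominator and counted separately. The 95% interval
#' is a percentile bootstrap over triplets.
#'
#' @param agree Logical vector, one element per evaluation triplet: did the
#'   method agree with the bird? `NA` marks an abstention. (Use
#'   [method_decisions()] to produce it from a matrix.)
#' @param method Method name carried into the report.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An `evaluation_report`: list with `method`, `n_triplets`,
#'   `n_scored`, `n_abstained`, `accuracy`, `ci_low`, `ci_high`.
#' @export
axb_accuracy <- function(agree, method = "method", n_boot = 1000,
                         seed = 1L) {
  scored <- agree[!is.na(agree)]
  if (length(scored) == 0) stop("zero scorable triplets")
  acc <- mean(scored)
  ci <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b)
      mean(sample(scored, replace = TRUE)), numeric(1))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  })
  structure(list(method = method, n_triplets = length(agree),
                 n_scored = length(scored),
                 n_abstained = sum(is.na(agree)),
                 accuracy = acc, ci_low = min(ci[1], acc),
                 ci_high = max(ci[2], acc)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %s: accuracy %.3f [%.3f, %.3f] on %d triplets (%d abstained)\n",
    x$method, x$accuracy, x$ci_low, x$ci_high, x$n_scored, x$n_abstained))
  invisible(x)
}

#' Attainable-accuracy bounds from the birds' own behaviour
#'
#' `bound_cycle` is the unweighted mean cycle accuracy over the (bird,
#' cycle) pairs contributing evaluation decisions — how well the birds did
#' on stimuli with a known correct answer. `bound_consistency` is the mean,
#' over consolidated decisions with more than one presentation, of the
#' fraction of choices agreeing with the majority side — an optimistic
#' ceiling resting on the assumption that each majority decision is
#' correct.
#'
#' @param cycle_accuracies Data.frame from [cycle_accuracy_table()]
#'   restricted to contributing cycles.
#' @param decisions Consolidated decisions from
#'   [consolidate_probe_decisions()] for the evaluation set.
#' @param weighted Weight `bound_cycle` by each cycle's decision count
#'   instead of the unweighted mean (default `FALSE`).
#' @return List with `bound_cycle` and `bound_consistency` (the latter `NA`
#'   if no multi-decision triplets exist).
#' @export
attainable_bounds <- function(cycle_accuracies, decisions,
                              weighted = FALSE) {
  if (nrow(cycle_accuracies) == 0) stop("no contributing cycles")
  bound_cycle <- if (weighted) {
    key <- paste(decisions$bird_id, decisions$cycle_id)
    akey <- paste(cycle_accuracies$bird_id, cycle_accuracies$cycle_id)
    counts <- table(key)
    w <- as.numeric(counts[match(akey, names(counts))])
    w[is.na(w)] <- 0
    if (sum(w) == 0) stop("no decisions match the accuracy table")
    sum(cycle_accuracies$accuracy * w) / sum(w)
  } else mean(cycle_accuracies$accuracy)
  multi <- decisions[decisions$n_decisions > 1, , drop = FALSE]
  bound_consistency <- if (nrow(multi) == 0) NA_real_ else
    mean(multi$consistency)
  list(bound_cycle = bound_cycle, bound_consistency = bound_consistency)
}

#' Disagreement MDS across methods
#'
#' The distance between two methods is the fraction of common triplets on
#' which they choose different sides; the birds' own majority labels enter
#' as the method `"BIRDS"` when supplied. Methods are embedded in two
#' dimensions by classical (Torgerson) MDS.
#'
#' @param decisions Named list of per-method side vectors (`"A"`/`"B"`,
#'   aligned to one common triplet set; `NA` allowed and skipped pairwise).
#' @param include_birds Add a `"BIRDS"` method of all-`"A"` sides (the
#'   majority labels' own orientation) when not already present.
#' @return List with `coords` (methods x 2), `distances` (disagreement
#'   matrix) and `eigenvalues`.
#' @export
disagreement_mds <- function(decisions, include_birds = TRUE) {
  if (include_birds && !"BIRDS" %in% names(decisions))
    decisions$BIRDS <- rep("A", length(decisions[[1]]))
  k <- length(decisions)
  if (k < 3) stop("need at least three methods")
  n <- unique(vapply(decisions, length, integer(1)))
  if (length(n) != 1) stop("methods must share one triplet set")
  methods <- names(decisions)
  Dm <- matrix(0, k, k, dimnames = list(methods, methods))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- decisions[[i]]; b <- decisions[[j]]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) stop("methods with no common triplets: ",
                         methods[i], ", ", methods[j])
      Dm[i, j] <- Dm[j, i] <- mean(a[ok] != b[ok])
    }
  }
  fit <- stats::cmdscale(Dm, k = 2, eig = TRUE)
  coords <- fit$points
  rownames(coords) <- methods
  list(coords = coords, distances = Dm, eigenvalues = fit$eig)
}

#' Binned choice-calibration curve
#'
#' For each probe trial the relative rank distance
#' `x = (RD_left - RD_right) / (RD_left + RD_right)` is computed, where
#' `RD_side` is the rank of that side's training stimulus in the probe's
#' dissimilarity ranking (rank 1 = most similar, ties broken by id order).
#' Trials are sorted by `x` and split into `n_bins` equal-count bins; each
#' bin reports the empirical log-odds of choosing the right perch
#' (Haldane-Anscombe corrected), minus the dataset-wide side-bias log-odds.
#'
#' @param probe_trials Data.frame with columns `probe_id`, `left_id`,
#'   `right_id`, `chosen_side` (`"L"`/`"R"`), e.g. built with
#'   [probe_trial_table()].
#' @param D A `dissimilarity_matrix` covering all referenced ids.
#' @param n_bins Number of equal-count bins (default 20); the number of
#'   trials must be at least `n_bins` and is divided as evenly as possible.
#' @return Data.frame with `bin`, `n`, `x_center` (mean relative rank
#'   distance) and `adjusted_log_odds`; the overall side-bias log-odds is
#'   attached as attribute `"side_bias"`.
#' @export
choice_calibration <- function(probe_trials, D, n_bins = 20) {
  n <- nrow(probe_trials)
  if (n < n_bins) stop("fewer trials than bins")
  M <- if (inherits(D, "dissimilarity_matrix")) D$values else as.matrix(D)
  ids <- rownames(M)
  rank_dist <- function(probe, stim) {
    others <- setdiff(ids, probe)
    ord <- order(M[probe, others], others)  # ties broken by id order
    match(stim, others[ord])
  }
  x <- numeric(n)
  for (i in seq_len(n)) {
    rl <- rank_dist(probe_trials$probe_id[i], probe_trials$left_id[i])
    rr <- rank_dist(probe_trials$probe_id[i], probe_trials$right_id[i])
    x[i] <- (rl - rr) / (rl + rr)
  }
  right <- probe_trials$chosen_side == "R"
  side_bias <- log((sum(right) + 0.5) / (sum(!right) + 0.5))
  ord <- order(x)
  bin_sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) bin_sizes[seq_len(extra)] <- bin_sizes[seq_len(extra)] + 1L
  bin_of <- rep(seq_len(n_bins), bin_sizes)
  out <- data.frame(bin = seq_len(n_bins), n = bin_sizes,
                    x_center = NA_real_, adjusted_log_odds = NA_real_)
  for (b in seq_len(n_bins)) {
    idx <- ord[bin_of == b]
    k <- sum(right[idx])
    lo <- log((k + 0.5) / (length(idx) - k + 0.5))
    out$x_center[b] <- mean(x[idx])
    out$adjusted_log_odds[b] <- lo - side_bias
  }
  attr(out, "side_bias") <- side_bias
  out
}

#' Probe-trial table for calibration from a trial log and stimulus sets
#'
#' Maps each answered probe trial to its left and right training exemplars.
#'
#' @param trials Trial data.frame.
#' @param cycles Cycle-to-set mapping (`cycle_id`, `stimulus_set_id`).
#' @param stimulus_sets Named list of `stimulus_set` objects.
#' @return Data.frame with `probe_id`, `left_id`, `right_id`, `chosen_side`.
#' @export
probe_trial_table <- function(trials, cycles, stimulus_sets) {
  t <- trials[trials$role == "probe" & trials$chosen_side != "none" &
                trials$device_ok, , drop = FALSE]
  set_id <- cycles$stimulus_set_id[match(t$cycle_id, cycles$cycle_id)]
  left <- character(nrow(t))
  right <- character(nrow(t))
  for (i in seq_len(nrow(t))) {
    set <- stimulus_sets[[set_id[i]]]
    if (set$side_of_A == "L") {
      left[i] <- set$exemplar_A; right[i] <- set$exemplar_B
    } else {
      left[i] <- set$exemplar_B; right[i] <- set$exemplar_A
    }
  }
  data.frame(probe_id = t$stimulus_id, left_id = left, right_id = right,
             chosen_side = t$chosen_side, stringsAsFactors = FALSE)
}

#' Ingest a (dis)similarity matrix produced by an external tool
#'
#' Reads a square delimited matrix with id headers. Similarities are
#' converted to dissimilarities as `max(s) - s`. Probe-stimulus pairs whose
#' source similarity was exactly zero are recorded in the attribute
#' `"zero_pairs"`, so triplets in which the probe had zero similarity to
#' both training sides can be flagged and excluded (see
#' [flag_zero_similarity_triplets()]).
#'
#' @param path Path to a comma-delimited matrix with an id header row and
#'   first column.
#' @param kind `"similarity"` or `"dissimilarity"`.
#' @param tol Symmetry tolerance relative to the largest value.
#' @return A `dissimilarity_matrix`.
#' @export
ingest_external_matrix <- function(path, kind = c("dissimilarity",
                                                  "similarity"),
                                   tol = 1e-6) {
  kind <- match.arg(kind)
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(raw)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  if (!identical(rownames(M), colnames(M)))
    stop("row and column ids must match")
  if (max(abs(M - t(M))) > tol * (1 + max(abs(M))))
    stop("matrix asymmetric beyond tolerance")
  zero <- NULL
  if (kind == "similarity") {
    zero <- M == 0
    M <- max(M) - M
  }
  out <- dissimilarity_matrix_from_values(M)
  attr(out, "zero_pairs") <- zero
  out
}

#' Flag triplets with zero source similarity to both training sides
#'
#' Reproduces the sensitivity handling for tools that report exact-zero
#' similarity for highly dissimilar pairs: a triplet is flagged when the
#' probe's similarity to every stimulus of both sides was zero.
#'
#' @param D Matrix from [ingest_external_matrix()] (with `"zero_pairs"`).
#' @param triplets Triplet data.frame.
#' @return Logical vector, `TRUE` = flagged for exclusion.
#' @export
flag_zero_similarity_triplets <- function(D, triplets) {
  zero <- attr(D, "zero_pairs")
  if (is.null(zero)) return(rep(FALSE, nrow(triplets)))
  vapply(seq_len(nrow(triplets)), function(i) {
    a <- triplets$anchor_id[i]
    all(zero[a, triplets$positive_ids[[i]]]) &&
      all(zero[a, triplets$negative_ids[[i]]])
  }, logical(1))
}

#' Write a dissimilarity matrix as delimited text
#' @param D A `dissimilarity_matrix`.
#' @param path Output path.
#' @export
write_dissimilarity_matrix <- function(D, path) {
  utils::write.csv(as.data.frame(D$values), path, row.names = TRUE)
  invisible(path)
}
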