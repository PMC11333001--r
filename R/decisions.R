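# Operant AXB decision handling: trial-log parsing, cycle accuracy, probe
# decision consolidation, construction of the unambiguous and ambiguous
# triplet datasets, and rank-based stimulus-set construction.

TRIAL_COLUMNS <- c("bird_id", "cycle_id", "stimulus_id", "role",
                   "correct_side", "chosen_side", "rewarded", "timestamp",
                   "device_ok")

#' Parse an operant trial log
#'
#' Reads a comma-delimited trial log with header
#' `bird_id,cycle_id,stimulus_id,role,correct_side,chosen_side,rewarded,timestamp,device_ok`
#' and validates every row: roles are `training`/`probe`, sides are
#' `L`/`R`/`none`, training trials carry a correct side while probe trials
#' must not, and `chosen_side = none` marks unanswered trials. Malformed
#' rows are reported with their line numbers.
#'
#' @param path Path to the delimited log.
#' @return Data.frame of validated trial records.
#' @export
parse_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0) return(empty_trials())
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad <- character(0)
  note <- function(cond, msg) {
    if (any(cond))
      bad <<- c(bad, sprintf("line %d: %s", line[cond], msg))
  }
  note(!raw$role %in% c("training", "probe"), "unknown role token")
  note(!raw$correct_side %in% c("L", "R", "none"), "unknown side token")
  note(!raw$chosen_side %in% c("L", "R", "none"), "unknown side token")
  note(raw$role == "probe" & raw$correct_side != "none",
       "probe trial must have correct_side = none")
  note(raw$role == "training" & !raw$correct_side %in% c("L", "R"),
       "training trial must have correct_side L or R")
  note(!toupper(raw$rewarded) %in% c("TRUE", "FALSE", "0", "1"),
       "rewarded must be logical")
  note(!toupper(raw$device_ok) %in% c("TRUE", "FALSE", "0", "1"),
       "device_ok must be logical")
  if (length(bad))
    stop("malformed trial log:\n", paste(bad, collapse = "\n"))
  data.frame(
    bird_id = raw$bird_id, cycle_id = raw$cycle_id,
    stimulus_id = raw$stimulus_id, role = raw$role,
    correct_side = raw$correct_side, chosen_side = raw$chosen_side,
    rewarded = toupper(raw$rewarded) %in% c("TRUE", "1"),
    timestamp = as.numeric(raw$timestamp),
    device_ok = toupper(raw$device_ok) %in% c("TRUE", "1"),
    stringsAsFactors = FALSE)
}

empty_trials <- function() {
  data.frame(bird_id = character(0), cycle_id = character(0),
             stimulus_id = character(0), role = character(0),
             correct_side = character(0), chosen_side = character(0),
             rewarded = logical(0), timestamp = numeric(0),
             device_ok = logical(0), stringsAsFactors = FALSE)
}

#' Write a trial log
#' @param trials Trial data.frame with the standard columns.
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Cycle accuracy of one bird in one testing cycle
#'
#' Proportion of correct responses among all answered training-stimulus
#' trials of that (bird, cycle); probe trials and unanswered or
#' device-fault trials never enter the count.
#'
#' @param trials Trial data.frame.
#' @param bird_id,cycle_id Identifiers of the cycle.
#' @return Fraction in `[0, 1]`.
#' @export
cycle_accuracy <- function(trials, bird_id, cycle_id) {
  t <- trials[trials$bird_id == bird_id & trials$cycle_id == cycle_id &
                trials$role == "training" & trials$chosen_side != "none" &
                trials$device_ok, , drop = FALSE]
  if (nrow(t) == 0) stop("no answered training trials for that bird/cycle")
  mean(t$chosen_side == t$correct_side)
}

#' Cycle accuracy for every (bird, cycle) in a log
#' @param trials Trial data.frame.
#' @return Data.frame with `bird_id`, `cycle_id`, `accuracy`, `n_trials`.
#' @export
cycle_accuracy_table <- function(trials) {
  t <- trials[trials$role == "training" & trials$chosen_side != "none" &
                trials$device_ok, , drop = FALSE]
  if (nrow(t) == 0)
    return(data.frame(bird_id = character(0), cycle_id = character(0),
                      accuracy = numeric(0), n_trials = integer(0)))
  key <- interaction(t$bird_id, t$cycle_id, drop = TRUE)
  agg <- lapply(split(t, key), function(g)
    data.frame(bird_id = g$bird_id[1], cycle_id = g$cycle_id[1],
               accuracy = mean(g$chosen_side == g$correct_side),
               n_trials = nrow(g), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Consolidate probe trials into per-(bird, cycle, probe) decisions
#'
#' One record per (bird, cycle, probe) with the number of answered
#' decisions, side counts, the majority side and the side consistency
#' (`max(side counts) / n_decisions`). A tie is resolved to side `L`
#' (lexicographically first); tied decisions have consistency 0.5 and can
#' only ever enter the ambiguous dataset. Unanswered and device-fault
#' trials are excluded.
#'
#' @param trials Trial data.frame.
#' @param cycle_sets Optional data.frame mapping `cycle_id` to
#'   `stimulus_set_id`.
#' @return Data.frame of probe decisions.
#' @export
consolidate_probe_decisions <- function(trials, cycle_sets = NULL) {
  t <- trials[trials$role == "probe" & trials$chosen_side != "none" &
                trials$device_ok, , drop = FALSE]
  if (nrow(t) == 0)
    return(data.frame(bird_id = character(0), cycle_id = character(0),
                      probe_id = character(0), n_decisions = integer(0),
                      n_L = integer(0), n_R = integer(0),
                      majority_side = character(0), consistency = numeric(0),
                      stimulus_set_id = character(0),
                      stringsAsFactors = FALSE))
  key <- interaction(t$bird_id, t$cycle_id, t$stimulus_id, drop = TRUE)
  rows <- lapply(split(t, key), function(g) {
    n_L <- sum(g$chosen_side == "L")
    n_R <- sum(g$chosen_side == "R")
    data.frame(bird_id = g$bird_id[1], cycle_id = g$cycle_id[1],
               probe_id = g$stimulus_id[1], n_decisions = n_L + n_R,
               n_L = n_L, n_R = n_R,
               majority_side = if (n_L >= n_R) "L" else "R",
               consistency = max(n_L, n_R) / (n_L + n_R),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(cycle_sets)) {
    out$stimulus_set_id <-
      cycle_sets$stimulus_set_id[match(out$cycle_id, cycle_sets$cycle_id)]
  } else out$stimulus_set_id <- NA_character_
  out
}

#' Build the unambiguous and ambiguous triplet datasets
#'
#' Applies the behavioural filters: decisions from any (bird, cycle) with
#' cycle accuracy below `accuracy_threshold` (0.65) are discarded entirely
#' (device-fault trials were already dropped during consolidation);
#' unambiguous triplets are consolidated decisions with at least two
#' answered presentations and side consistency strictly above
#' `consistency_threshold` (0.70); ambiguous triplets have consistency in
#' `ambiguous_range` (0.50 to 0.70, both ends included, so the 70% boundary
#' is ambiguous). Each triplet stores the probe as anchor, the training
#' stimuli of the majority side as positives and the other side as
#' negatives, the ambiguity flag `u` and the decision count as `weight`.
#'
#' @param decisions Consolidated decisions from
#'   [consolidate_probe_decisions()] with `stimulus_set_id` filled.
#' @param cycle_accuracies Data.frame from [cycle_accuracy_table()].
#' @param stimulus_sets Named list of `stimulus_set` objects.
#' @param accuracy_threshold,consistency_threshold,ambiguous_range Filter
#'   thresholds; all must lie in `[0.5, 1]`.
#' @return List with data.frames `unambiguous` (`u = 1`) and `ambiguous`
#'   (`u = 0`); both carry list columns `positive_ids`/`negative_ids`.
#' @export
build_triplet_datasets <- function(decisions, cycle_accuracies,
                                   stimulus_sets,
                                   accuracy_threshold = 0.65,
                                   consistency_threshold = 0.70,
                                   ambiguous_range = c(0.50, 0.70)) {
  th <- c(accuracy_threshold, consistency_threshold, ambiguous_range)
  if (any(th < 0.5 | th > 1))
    stop("thresholds must lie in [0.5, 1]")
  key <- paste(decisions$bird_id, decisions$cycle_id)
  akey <- paste(cycle_accuracies$bird_id, cycle_accuracies$cycle_id)
  acc <- cycle_accuracies$accuracy[match(key, akey)]
  d <- decisions
  d$cycle_accuracy <- acc
  d <- d[!is.na(d$cycle_accuracy) & d$cycle_accuracy >= accuracy_threshold, ,
         drop = FALSE]
  orient <- function(rows, u) {
    if (nrow(rows) == 0) return(empty_triplets(u))
    pos <- vector("list", nrow(rows))
    neg <- vector("list", nrow(rows))
    keep <- logical(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      set <- stimulus_sets[[rows$stimulus_set_id[i]]]
      if (is.null(set)) next
      chose_A <- rows$majority_side[i] == set$side_of_A
      pos[[i]] <- if (chose_A) set$side_A_ids else set$side_B_ids
      neg[[i]] <- if (chose_A) set$side_B_ids else set$side_A_ids
      keep[i] <- !rows$probe_id[i] %in% c(pos[[i]], neg[[i]])
    }
    out <- rows[keep, c("bird_id", "cycle_id", "probe_id",
                        "stimulus_set_id", "majority_side", "n_decisions",
                        "consistency", "cycle_accuracy"), drop = FALSE]
    names(out)[names(out) == "probe_id"] <- "anchor_id"
    names(out)[names(out) == "n_decisions"] <- "weight"
    out$u <- u
    out$positive_ids <- I(pos[keep])
    out$negative_ids <- I(neg[keep])
    rownames(out) <- NULL
    out
  }
  unamb <- d[d$n_decisions >= 2 & d$consistency > consistency_threshold, ,
             drop = FALSE]
  amb <- d[d$n_decisions >= 2 & d$consistency >= ambiguous_range[1] &
             d$consistency <= ambiguous_range[2], , drop = FALSE]
  list(unambiguous = orient(unamb, 1L), ambiguous = orient(amb, 0L))
}

empty_triplets <- function(u) {
  out <- data.frame(bird_id = character(0), cycle_id = character(0),
                    anchor_id = character(0), stimulus_set_id = character(0),
                    majority_side = character(0), weight = integer(0),
                    consistency = numeric(0), cycle_accuracy = numeric(0),
                    u = integer(0), stringsAsFactors = FALSE)
  out$positive_ids <- I(list())
  out$negative_ids <- I(list())
  out
}

#' Train/evaluation split of a triplet dataset
#'
#' Splits triplets stratified by stimulus set; all triplets sharing an
#' anchor within a set go to the same side of the split, so anchors are
#' never shared across splits. Optionally restricts the evaluation side to
#' decisions from cycles at or above a stricter accuracy (the 77%
#' evaluation filter).
#'
#' @param triplets Triplet data.frame (as from [build_triplet_datasets()]).
#' @param eval_fraction Fraction of anchors per set assigned to evaluation.
#' @param seed Integer seed.
#' @param eval_accuracy Optional minimum cycle accuracy for evaluation
#'   triplets (e.g. 0.77); training triplets are unaffected.
#' @return List with `train` and `eval` triplet data.frames.
#' @export
split_triplets <- function(triplets, eval_fraction = 0.3, seed = 1L,
                           eval_accuracy = NULL) {
  if (nrow(triplets) == 0) return(list(train = triplets, eval = triplets))
  assign_eval <- with_seed(seed, {
    keys <- unique(triplets[, c("stimulus_set_id", "anchor_id")])
    chosen <- logical(nrow(keys))
    for (s in unique(keys$stimulus_set_id)) {
      idx <- which(keys$stimulus_set_id == s)
      n_eval <- max(1L, round(eval_fraction * length(idx)))
      chosen[sample(idx, min(n_eval, length(idx)))] <- TRUE
    }
    keys$eval <- chosen
    keys
  })
  key_t <- paste(triplets$stimulus_set_id, triplets$anchor_id)
  key_k <- paste(assign_eval$stimulus_set_id, assign_eval$anchor_id)
  is_eval <- assign_eval$eval[match(key_t, key_k)]
  ev <- triplets[is_eval, , drop = FALSE]
  if (!is.null(eval_accuracy))
    ev <- ev[ev$cycle_accuracy >= eval_accuracy, , drop = FALSE]
  list(train = triplets[!is_eval, , drop = FALSE], eval = ev)
}

#' Construct a stimulus set object
#'
#' @param id Set identifier.
#' @param side_A_ids,side_B_ids Stimulus ids of the two sides (first element
#'   of each is the exemplar); sides must be disjoint.
#' @param probe_ids Probe ids, in neither side.
#' @param side_of_A Physical side (`"L"` or `"R"`) rewarded for side A.
#' @return A `stimulus_set` object.
#' @export
stimulus_set <- function(id, side_A_ids, side_B_ids, probe_ids,
                         side_of_A = "L") {
  if (length(intersect(side_A_ids, side_B_ids)))
    stop("sides must be disjoint")
  if (length(intersect(probe_ids, c(side_A_ids, side_B_ids))))
    stop("probes must not be training stimuli")
  if (!side_of_A %in% c("L", "R")) stop("side_of_A must be L or R")
  structure(list(id = id, exemplar_A = side_A_ids[1],
                 exemplar_B = side_B_ids[1],
                 side_A_ids = side_A_ids, side_B_ids = side_B_ids,
                 probe_ids = probe_ids, side_of_A = side_of_A),
            class = "stimulus_set")
}

#' Select a stimulus set by similarity rank
#'
#' Exemplar A is drawn uniformly at random; exemplar B uniformly among the
#' syllables ranked `rank_B` (50-150 by default) in A's similarity ranking
#' (rank 1 = most similar, self excluded). Each side consists of its
#' exemplar plus the exemplar's `n_side - 1` most similar syllables. Probes
#' are drawn from syllables whose rank with respect to both exemplars lies
#' in `probe_ranks` (20-200) and that belong to neither side. If the two
#' sides overlap, exemplar B is resampled.
#'
#' @param D A `dissimilarity_matrix` over the candidate corpus.
#' @param seed Integer seed.
#' @param n_side Stimuli per side (default 8).
#' @param rank_B Rank window for exemplar B relative to A.
#' @param probe_ranks Rank window for probes relative to both exemplars.
#' @param n_probes Number of probes to draw (default: all eligible).
#' @param id Set identifier.
#' @param side_of_A Rewarded side for side A.
#' @return A `stimulus_set`.
#' @export
select_stimulus_set <- function(D, seed = 1L, n_side = 8,
                                rank_B = c(50, 150),
                                probe_ranks = c(20, 200), n_probes = NULL,
                                id = "set1", side_of_A = "L") {
  M <- if (inherits(D, "dissimilarity_matrix")) D$values else as.matrix(D)
  ids <- rownames(M)
  n <- length(ids)
  if (n - 1 < max(rank_B[2], probe_ranks[2]))
    stop("corpus too small for the requested rank windows")
  rank_of <- function(ex) {
    ord <- order(M[ex, setdiff(ids, ex)])
    ranked <- setdiff(ids, ex)[ord]
    stats::setNames(seq_along(ranked), ranked)
  }
  with_seed(seed, {
    for (attempt in 1:100) {
      ex_A <- sample(ids, 1)
      ranks_A <- rank_of(ex_A)
      cand_B <- names(ranks_A)[ranks_A >= rank_B[1] & ranks_A <= rank_B[2]]
      ex_B <- sample(cand_B, 1)
      side_A <- c(ex_A, names(ranks_A)[order(ranks_A)][seq_len(n_side - 1)])
      ranks_B <- rank_of(ex_B)
      side_B <- c(ex_B, names(ranks_B)[order(ranks_B)][seq_len(n_side - 1)])
      if (length(intersect(side_A, side_B)) == 0) break
      if (attempt == 100) stop("could not find disjoint sides")
    }
    ok_probe <- function(s) {
      ra <- ranks_A[s]; rb <- ranks_B[s]
      !is.na(ra) && !is.na(rb) &&
        ra >= probe_ranks[1] && ra <= probe_ranks[2] &&
        rb >= probe_ranks[1] && rb <= probe_ranks[2]
    }
    cand_probe <- setdiff(ids, c(side_A, side_B, ex_A, ex_B))
    cand_probe <- cand_probe[vapply(cand_probe, ok_probe, logical(1))]
    if (length(cand_probe) == 0) stop("no eligible probes in rank window")
    probes <- if (is.null(n_probes)) cand_probe else
      sample(cand_probe, min(n_probes, length(cand_probe)))
    stimulus_set(id, side_A, side_B, probes, side_of_A)
  })
}

#' Write a triplet dataset as JSON lines
#'
#' One JSON object per line with the anchor, positive and negative ids,
#' ambiguity flag, weight and provenance fields — the interchange format
#' for triplet datasets.
#'
#' @param triplets Triplet data.frame.
#' @param path Output path.
#' @export
write_triplets <- function(triplets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(triplets))) {
    rec <- list(bird_id = triplets$bird_id[i],
                cycle_id = triplets$cycle_id[i],
                anchor_id = triplets$anchor_id[i],
                stimulus_set_id = triplets$stimulus_set_id[i],
                majority_side = triplets$majority_side[i],
                weight = triplets$weight[i],
                consistency = triplets$consistency[i],
                cycle_accuracy = triplets$cycle_accuracy[i],
                u = triplets$u[i],
                positive_ids = triplets$positive_ids[[i]],
                negative_ids = triplets$negative_ids[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a triplet dataset from JSON lines
#'
#' @param path Path written by [write_triplets()].
#' @return Triplet data.frame.
#' @export
read_triplets <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_triplets(1L))
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- do.call(rbind, lapply(recs, function(r)
    data.frame(bird_id = r$bird_id, cycle_id = r$cycle_id,
               anchor_id = r$anchor_id,
               stimulus_set_id = r$stimulus_set_id,
               majority_side = r$majority_side,
               weight = as.integer(r$weight),
               consistency = r$consistency,
               cycle_accuracy = r$cycle_accuracy, u = as.integer(r$u),
               stringsAsFactors = FALSE)))
  out$positive_ids <- I(lapply(recs, function(r) r$positive_ids))
  out$negative_ids <- I(lapply(recs, function(r) r$negative_ids))
  out
}
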