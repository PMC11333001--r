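# Abstract synthetic feature contours with planted DTW feature weights:
# ground truth for the weight-calibration chain without audio in the loop.

#' Generate abstract feature contours for weight-recovery experiments
#'
#' Each syllable gets a contour matrix (frames x features) built from a
#' syllable-specific offset, slope and sinusoidal component per feature, so
#' different features disagree about which syllables are similar.
#'
#' @param n Number of syllables.
#' @param n_features Number of contour features.
#' @param len_range Frame-count range, inclusive.
#' @param seed Integer seed.
#' @return Named list of contour matrices.
#' @export
synthetic_contour_corpus <- function(n, n_features = 3,
                                     len_range = c(8, 14), seed = 1L) {
  with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      len <- sample(len_range[1]:len_range[2], 1)
      t <- seq(0, 1, length.out = len)
      sapply(seq_len(n_features), function(f) {
        stats::rnorm(1, 0, 1) + stats::rnorm(1, 0, 1) * t +
          stats::rnorm(1, 0, 0.5) * sin(2 * pi * (1 + stats::runif(1)) * t +
                                          stats::runif(1, 0, 2 * pi))
      })
    })
    names(out) <- sprintf("c%04d", seq_len(n))
    out
  })
}

#' Triplets labelled by a planted weight vector
#'
#' Draws random (probe, A, B) triples from the corpus and labels each side
#' as positive according to the DTW metric with the planted weights. With
#' `choice = "logistic"` (the default) the chosen side is sampled from the
#' decision model itself, `P(side A) = 1/(1 + exp(4 Xp))`, so the
#' calibration chain is fitting a correctly specified model and its
#' posterior concentrates on the planted weights. With
#' `choice = "deterministic"` the nearer side is always chosen; that
#' labelling contains no decision noise at all, but the maximum-likelihood
#' weights are then the margin-maximising ones, which are systematically
#' tilted toward the dominant feature — useful as a contrast, not for
#' recovery checks.
#'
#' @param contours Named list of contour matrices (standardised internally).
#' @param w_true Planted weight vector (normalised).
#' @param n_triplets Number of triplets.
#' @param seed Integer seed.
#' @param min_margin Minimum `|Xp|` (default 0.01); smaller-margin triples
#'   are redrawn.
#' @param choice Label-generation rule, see above.
#' @return Triplet data.frame (`u = 1`) with single-exemplar sides.
#' @export
planted_weight_triplets <- function(contours, w_true, n_triplets,
                                    seed = 1L, min_margin = 0.01,
                                    choice = c("logistic",
                                               "deterministic")) {
  choice <- match.arg(choice)
  w <- weight_vector(unclass(w_true))
  mats <- standardize_contours(lapply(contours, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  }))
  ids <- names(mats)
  with_seed(seed, {
    anchor <- character(n_triplets)
    pos <- vector("list", n_triplets)
    neg <- vector("list", n_triplets)
    got <- 0L
    while (got < n_triplets) {
      tri <- sample(ids, 3)
      da <- dtw_dissimilarity(mats[[tri[1]]], mats[[tri[2]]], w)
      db <- dtw_dissimilarity(mats[[tri[1]]], mats[[tri[3]]], w)
      if (da + db == 0) next
      xp <- (da - db) / (da + db)
      if (abs(xp) < min_margin) next
      got <- got + 1L
      anchor[got] <- tri[1]
      first_chosen <- if (choice == "logistic")
        stats::runif(1) < 1 / (1 + exp(4 * xp)) else xp < 0
      if (first_chosen) {
        pos[[got]] <- tri[2]; neg[[got]] <- tri[3]
      } else {
        pos[[got]] <- tri[3]; neg[[got]] <- tri[2]
      }
    }
    data.frame(bird_id = "planted", cycle_id = "planted", anchor_id = anchor,
               stimulus_set_id = "planted", majority_side = "L",
               weight = 1L, consistency = 1, cycle_accuracy = 1, u = 1L,
               positive_ids = I(pos), negative_ids = I(neg),
               stringsAsFactors = FALSE)
  })
}
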