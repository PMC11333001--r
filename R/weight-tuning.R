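# Calibration of DTW feature weights against behavioural triplet decisions
# by Metropolis-Hastings MCMC, and generation of machine-labelled triplets
# from the tuned metric.

#' Decision log-likelihood of a relative dissimilarity
#'
#' The likelihood that the metric makes the same choice as the bird, with
#' `Xp` oriented so that the bird-chosen side is side A (`Xp < 0` means the
#' metric agrees): `log(1 / (1 + exp(4 * Xp)))`.
#'
#' @param xp Relative dissimilarity in `[-1, 1]` (vectorised).
#' @return Log-likelihood value(s), always negative.
#' @export
decision_log_likelihood <- function(xp) {
  z <- 4 * xp
  -ifelse(z > 35, z, log1p(exp(z)))
}

#' Calibrate DTW feature weights by Metropolis-Hastings MCMC
#'
#' Starting from equal weights, each iteration proposes new weights by
#' multiplying every weight by `exp(N(0, proposal_sd))` and renormalising to
#' sum one, recomputes every triplet's relative dissimilarity `Xp` under the
#' proposal, and accepts or rejects by the Metropolis-Hastings rule on the
#' summed [decision_log_likelihood()] (flat prior on the weight simplex).
#' Because the multiplicative-then-renormalise proposal is asymmetric, the
#' acceptance ratio includes the log proposal-ratio correction
#' `sum(log w') - sum(log w)` by default. The posterior mean is taken over
#' the post-burn-in samples.
#'
#' @param triplets Triplet data.frame (unambiguous decisions; `u = 0` rows
#'   are dropped with a message) with `anchor_id` and list columns
#'   `positive_ids` (the chosen side) and `negative_ids`.
#' @param contours Named list of feature contour data.frames or matrices
#'   covering every referenced syllable.
#' @param n_iter,burn_in,proposal_sd Chain settings (defaults 10000, 1000,
#'   0.1).
#' @param seed Integer seed; the chain is deterministic given it.
#' @param jacobian Include the proposal-asymmetry correction (default
#'   `TRUE`); `FALSE` gives the uncorrected rule.
#' @param features Contour columns used as DTW features.
#' @param standardize Standardise contours corpus-wide first.
#' @return A `dtw_weight_fit`: list with `posterior_mean` (a
#'   [weight_vector()]), `samples` (n_iter x features), `log_likelihood`,
#'   `accepted`, `acceptance_rate`, `burn_in`, `features`.
#' @export
tune_dtw_weights <- function(triplets, contours, n_iter = 10000,
                             burn_in = 1000, proposal_sd = 0.1, seed = 1L,
                             jacobian = TRUE,
                             features = dtw_default_features(),
                             standardize = TRUE) {
  if (!is.null(triplets$u) && any(triplets$u == 0)) {
    message("dropping ", sum(triplets$u == 0),
            " ambiguous triplets from weight tuning")
    triplets <- triplets[triplets$u == 1, , drop = FALSE]
  }
  if (nrow(triplets) < 1) stop("need at least one unambiguous triplet")
  if (burn_in >= n_iter) stop("'burn_in' must be smaller than 'n_iter'")
  mats <- lapply(contours, function(x) {
    if (is.data.frame(x)) contour_matrix(x, features) else {
      m <- as.matrix(x); storage.mode(m) <- "double"; m
    }
  })
  if (standardize) mats <- standardize_contours(mats)
  ids <- names(mats)
  need <- unique(c(triplets$anchor_id, unlist(triplets$positive_ids),
                   unlist(triplets$negative_ids)))
  missing <- setdiff(need, ids)
  if (length(missing))
    stop("contours missing for syllables: ",
         paste(utils::head(missing, 5), collapse = ", "))
  # unique (anchor, stimulus) pairs; triplets point into the pair list
  pair_key <- character(0)
  pair_i <- integer(0)
  pair_j <- integer(0)
  pair_env <- new.env(parent = emptyenv())
  pair_index <- function(a, s) {
    key <- paste0(a, "\r", s)
    idx <- pair_env[[key]]
    if (is.null(idx)) {
      idx <- length(pair_i) + 1L
      pair_i[[idx]] <<- match(a, ids) - 1L
      pair_j[[idx]] <<- match(s, ids) - 1L
      pair_env[[key]] <- idx
    }
    idx
  }
  pos_pairs <- vector("list", nrow(triplets))
  neg_pairs <- vector("list", nrow(triplets))
  for (t in seq_len(nrow(triplets))) {
    a <- triplets$anchor_id[t]
    pos_pairs[[t]] <- vapply(triplets$positive_ids[[t]],
                             function(s) pair_index(a, s), integer(1)) - 1L
    neg_pairs[[t]] <- vapply(triplets$negative_ids[[t]],
                             function(s) pair_index(a, s), integer(1)) - 1L
  }
  nf <- ncol(mats[[1]])
  res <- with_seed(seed, mcmc_tune_cpp(
    mats, as.integer(pair_i), as.integer(pair_j), pos_pairs, neg_pairs,
    rep(1 / nf, nf), as.integer(n_iter), proposal_sd, jacobian))
  samples <- res$samples
  colnames(samples) <- if (ncol(mats[[1]]) == length(features)) features else
    sprintf("f%d", seq_len(nf))
  post <- colMeans(samples[(burn_in + 1):n_iter, , drop = FALSE])
  structure(list(
    posterior_mean = weight_vector(post),
    samples = samples,
    log_likelihood = as.numeric(res$log_likelihood),
    accepted = as.logical(res$accepted),
    acceptance_rate = mean(res$accepted),
    burn_in = burn_in, n_iter = n_iter, proposal_sd = proposal_sd,
    features = colnames(samples)),
    class = "dtw_weight_fit")
}

#' @export
print.dtw_weight_fit <- function(x, ...) {
  cat(sprintf(
    "<dtw_weight_fit> %d iterations (%d burn-in), acceptance rate %.2f\n",
    x$n_iter, x$burn_in, x$acceptance_rate))
  cat("posterior-mean weights:\n")
  print(round(unclass(x$posterior_mean), 4))
  invisible(x)
}

#' @export
coef.dtw_weight_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$posterior_mean), object$features)
}

#' @export
summary.dtw_weight_fit <- function(object, ...) {
  keep <- (object$burn_in + 1):object$n_iter
  s <- object$samples[keep, , drop = FALSE]
  out <- data.frame(feature = colnames(s), mean = colMeans(s),
                    sd = apply(s, 2, stats::sd),
                    q025 = apply(s, 2, stats::quantile, 0.025),
                    q975 = apply(s, 2, stats::quantile, 0.975))
  rownames(out) <- NULL
  out
}

#' @export
plot.dtw_weight_fit <- function(x, ...) {
  graphics::matplot(x$samples, type = "l", lty = 1,
                    xlab = "iteration", ylab = "weight", ...)
  graphics::abline(v = x$burn_in, lty = 2)
  graphics::legend("topright", legend = x$features, col = seq_along(x$features),
                   lty = 1, cex = 0.6, bty = "n")
  invisible(x)
}

#' Generate machine-labelled triplets from a tuned dissimilarity matrix
#'
#' For every probe x stimulus-set pair, labels the triplet with the side
#' chosen by [axb_decide()] on `D` and keeps only decisions whose margin
#' `|Xp|` reaches `min_margin` — the coarse, unambiguous distinctions. Ties
#' and degenerate probes are skipped.
#'
#' @param D A `dissimilarity_matrix` (typically built with tuned weights).
#' @param stimulus_sets Named list of `stimulus_set` objects.
#' @param min_margin Minimum `|Xp|` in `[0, 1]` (default 0).
#' @param aggregate Probe-to-side aggregation passed to [axb_decide()].
#' @return Triplet data.frame (`u = 1`, `bird_id = "machine"`).
#' @export
generate_machine_triplets <- function(D, stimulus_sets, min_margin = 0,
                                      aggregate = "mean") {
  if (min_margin < 0 || min_margin > 1)
    stop("'min_margin' must lie in [0, 1]")
  if (is.null(names(stimulus_sets)))
    names(stimulus_sets) <- vapply(stimulus_sets, `[[`, "", "id")
  rows <- list()
  pos <- list()
  neg <- list()
  for (set_id in names(stimulus_sets)) {
    set <- stimulus_sets[[set_id]]
    for (probe in set$probe_ids) {
      dec <- axb_decide(D, probe, set$side_A_ids, set$side_B_ids,
                        aggregate = aggregate)
      if (dec$degenerate || dec$tie || abs(dec$Xp) < min_margin) next
      chose_A <- dec$side == "A"
      rows[[length(rows) + 1L]] <- data.frame(
        bird_id = "machine", cycle_id = set_id, anchor_id = probe,
        stimulus_set_id = set_id,
        majority_side = if (chose_A) set$side_of_A else
          setdiff(c("L", "R"), set$side_of_A),
        weight = 1L, consistency = 1, cycle_accuracy = 1,
        u = 1L, Xp = dec$Xp, stringsAsFactors = FALSE)
      pos[[length(pos) + 1L]] <- if (chose_A) set$side_A_ids else
        set$side_B_ids
      neg[[length(neg) + 1L]] <- if (chose_A) set$side_B_ids else
        set$side_A_ids
    }
  }
  if (length(rows) == 0) {
    out <- empty_triplets(1L)
    out$Xp <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$positive_ids <- I(pos)
  out$negative_ids <- I(neg)
  rownames(out) <- NULL
  out
}
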