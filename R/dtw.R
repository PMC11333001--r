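# Weighted dynamic-time-warping dissimilarity over acoustic feature
# contours, in the style of DTW-based birdsong comparison tools: per-frame
# feature vectors (time included as a feature so warping is penalised),
# weighted Euclidean point costs, and an optimal monotone alignment whose
# summed cost is averaged over the alignment path.

#' Construct a feature weight vector
#'
#' Weights are non-negative and normalised to sum to one so that they are
#' comparable across features.
#'
#' @param w Named (or unnamed) numeric vector of non-negative weights.
#' @return Normalised weight vector of class `weight_vector`.
#' @export
weight_vector <- function(w) {
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  if (sum(w) <= 0) stop("at least one weight must be positive")
  structure(w / sum(w), class = "weight_vector")
}

#' Square symmetric dissimilarity matrix container
#'
#' @param values Square numeric matrix, symmetric with zero diagonal.
#' @param ids Character vector of syllable ids (defaults to dimnames).
#' @return An object of class `dissimilarity_matrix`.
#' @export
dissimilarity_matrix_from_values <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate syllable ids")
  if (any(!is.finite(values))) stop("dissimilarities must be finite")
  if (max(abs(values - t(values))) > 1e-8 * (1 + max(abs(values))))
    stop("matrix not symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values), class = "dissimilarity_matrix")
}

#' @export
as.matrix.dissimilarity_matrix <- function(x, ...) x$values

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d syllables, mean off-diagonal %.4g\n",
              length(x$ids),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Convert feature contours to the numeric matrix used by DTW
#'
#' Selects the per-frame features (including time) as a frames x features
#' matrix. Missing fundamental-derived values must already be filled.
#'
#' @param contours A `feature_contours` data.frame from [extract_contours()],
#'   or any data.frame with the requested columns.
#' @param features Character vector of column names; defaults to the nine
#'   acoustic contour features plus time.
#' @return Numeric matrix, frames x features.
#' @export
contour_matrix <- function(contours, features = dtw_default_features()) {
  missing <- setdiff(features, names(contours))
  if (length(missing))
    stop("contours lack features: ", paste(missing, collapse = ", "))
  m <- as.matrix(contours[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Default DTW feature set (nine acoustic contours plus time)
#' @export
dtw_default_features <- function() {
  c("time", "fundamental_frequency", "peak_frequency", "mean_frequency",
    "fundamental_change", "peak_change", "normalized_fundamental",
    "wiener_entropy", "harmonicity", "vibrato_amplitude")
}

#' Weighted DTW dissimilarity between two feature contour matrices
#'
#' Point cost between frame `i` of one syllable and frame `j` of the other is
#' the weighted Euclidean distance `sqrt(sum_f w_f (a_if - b_jf)^2)`. A
#' dynamic program finds the monotone alignment (diagonal, insert and delete
#' steps, no slope constraint or band) minimising the summed point cost; the
#' returned dissimilarity is that total divided by the alignment path length.
#' Time is normally included as one of the features, so warping itself is
#' penalised.
#'
#' @param c1,c2 Frames x features numeric matrices (see [contour_matrix()]),
#'   assumed already standardised per feature when comparability matters
#'   (done corpus-wide by [dissimilarity_matrix()]).
#' @param w Feature weights, recycled through [weight_vector()].
#' @return Non-negative scalar dissimilarity.
#' @export
dtw_dissimilarity <- function(c1, c2, w) {
  c1 <- as.matrix(c1); c2 <- as.matrix(c2)
  if (nrow(c1) == 0 || nrow(c2) == 0) stop("empty contour")
  if (ncol(c1) != ncol(c2)) stop("contours have different feature counts")
  w <- weight_vector(unclass(w))
  if (length(w) != ncol(c1)) stop("weight length must match feature count")
  dtw_cost_cpp(c1, c2, as.numeric(w))
}

#' Pairwise DTW dissimilarity matrix over a corpus of contours
#'
#' Standardises every feature to corpus-wide z-scores (pooling frames over
#' all syllables) so that the weights act on comparable scales, then computes
#' all unordered pairs once.
#'
#' @param contour_list Named list of frames x features matrices (or
#'   `feature_contours` data.frames, converted via [contour_matrix()]).
#' @param w Feature weights.
#' @param features Feature columns used when elements are data.frames.
#' @param standardize Standardise features corpus-wide before weighting
#'   (default `TRUE`).
#' @return A `dissimilarity_matrix`.
#' @export
dissimilarity_matrix <- function(contour_list, w,
                                 features = dtw_default_features(),
                                 standardize = TRUE) {
  if (length(contour_list) < 2) stop("need at least two syllables")
  ids <- names(contour_list)
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(contour_list))
  if (anyDuplicated(ids)) stop("duplicate syllable ids")
  mats <- lapply(contour_list, function(x) {
    if (is.data.frame(x)) contour_matrix(x, features) else {
      m <- as.matrix(x); storage.mode(m) <- "double"; m
    }
  })
  if (standardize) mats <- standardize_contours(mats)
  w <- weight_vector(unclass(w))
  if (length(w) != ncol(mats[[1]]))
    stop("weight length must match feature count")
  values <- dtw_matrix_cpp(mats, as.numeric(w))
  dissimilarity_matrix_from_values(values, ids)
}

#' Standardise a list of contour matrices to pooled per-feature z-scores
#' @param mats List of frames x features matrices with identical columns.
#' @return List of matrices on the pooled z-score scale.
#' @export
standardize_contours <- function(mats) {
  all_rows <- do.call(rbind, mats)
  mu <- colMeans(all_rows)
  sd <- apply(all_rows, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  lapply(mats, function(m) sweep(sweep(m, 2, mu), 2, sd, "/"))
}

#' AXB decision from a dissimilarity matrix
#'
#' Computes the relative probe dissimilarity
#' `Xp = (D_probeA - D_probeB) / (D_probeA + D_probeB)` where `D_probeA` and
#' `D_probeB` aggregate the probe's dissimilarity to each side's stimulus set
#' (mean by default), and chooses side A when `Xp < 0`, side B when `Xp > 0`.
#' An exact tie (`Xp == 0`) is resolved deterministically to side A and
#' flagged; if both sides are at zero distance the decision abstains.
#'
#' @param D A `dissimilarity_matrix` (or plain matrix with dimnames).
#' @param probe Probe syllable id.
#' @param side_A_ids,side_B_ids Character vectors of stimulus ids.
#' @param aggregate One of `"mean"`, `"min"`, `"exemplar"` (first id only).
#' @return List with `side` (`"A"`, `"B"` or `NA` on abstention), `Xp`,
#'   `tie` and `degenerate` flags.
#' @export
axb_decide <- function(D, probe, side_A_ids, side_B_ids,
                       aggregate = c("mean", "min", "exemplar")) {
  aggregate <- match.arg(aggregate)
  M <- if (inherits(D, "dissimilarity_matrix")) D$values else as.matrix(D)
  ids <- c(probe, side_A_ids, side_B_ids)
  missing <- setdiff(ids, rownames(M))
  if (length(missing))
    stop("ids not in matrix: ", paste(missing, collapse = ", "))
  agg <- switch(aggregate,
    mean = function(v) mean(v),
    min = function(v) min(v),
    exemplar = function(v) v[1])
  dA <- agg(M[probe, side_A_ids])
  dB <- agg(M[probe, side_B_ids])
  if (dA + dB == 0)
    return(list(side = NA_character_, Xp = NA_real_, tie = FALSE,
                degenerate = TRUE))
  xp <- (dA - dB) / (dA + dB)
  list(side = if (xp <= 0) "A" else "B", Xp = xp, tie = xp == 0,
       degenerate = FALSE)
}
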