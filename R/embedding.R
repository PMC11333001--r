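# The convolutional triplet-embedding model: configuration, initialisation,
# the standard and ambiguity-aware losses, Adam training on set-valued
# triplets, inference, and AXB decisions in embedding space.

#' Network configuration
#'
#' @param d Embedding dimensionality (>= 2, default 64).
#' @param channels Output channels of the conv blocks (default
#'   `c(8, 16, 32, 64)`; 3x3 kernels, stride 2, "same" padding).
#' @param kernel,stride Conv kernel size and stride, shared by all blocks.
#' @param slope Leaky-ReLU negative slope.
#' @param batch_norm Use batch normalisation in every block.
#' @param unit_normalise Project embeddings to the unit sphere.
#' @param input_shape Mel-spectrogram input shape (bands x frames), fixed at
#'   150 x 170.
#' @return A `network_config` list.
#' @export
network_config <- function(d = 64, channels = c(8, 16, 32, 64), kernel = 3,
                           stride = 2, slope = 0.01, batch_norm = TRUE,
                           unit_normalise = TRUE,
                           input_shape = c(150, 170)) {
  if (d < 2) stop("'d' must be >= 2")
  if (length(channels) < 1 || any(channels < 1))
    stop("'channels' must be positive")
  structure(list(d = as.integer(d), channels = as.integer(channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 slope = slope, batch_norm = batch_norm,
                 unit_normalise = unit_normalise,
                 input_shape = as.integer(input_shape)),
            class = "network_config")
}

#' Training configuration
#'
#' @param sources Subset of `c("U", "A", "L")`: unambiguous bird decisions,
#'   ambiguous bird decisions, machine (tuned-metric) triplets.
#' @param pretrain_on_L Run a pre-training phase on the L triplets before
#'   the main phase (which then uses the remaining sources).
#' @param margin Margin `delta` (>= 0, default 0.2 on unit-norm embeddings).
#' @param learning_rate,epochs Adam step size and training epochs. The
#'   default step size (`NULL`) is loss-aware: 1e-2 for the mixed loss,
#'   whose exponential weighting yields gradients roughly an order of
#'   magnitude smaller, and 1e-3 for the hinge losses.
#' @param loss `"auto"` (mixed loss when source A is active, otherwise the
#'   hinge loss on squared distances), `"mixed"`, `"hinge_sq"` or `"hinge"`
#'   (unsquared distances).
#' @param holdout_fraction Fraction of training anchors whose triplets are
#'   held out to select the best epoch (0 disables).
#' @param input_jitter Standard deviation of Gaussian noise added to the
#'   (scaled) training inputs each epoch — cheap augmentation against
#'   memorising a small syllable set (0 disables).
#' @param time_shift Maximum random circular-free shift, in frames, applied
#'   to each training spectrogram per epoch (floor-filled); exploits the
#'   time-translation invariance of syllable identity (0 disables).
#' @param seed Integer seed for exemplar sampling and the holdout split.
#' @return A `train_config` list.
#' @export
train_config <- function(sources = "U", pretrain_on_L = FALSE, margin = 0.2,
                         learning_rate = NULL, epochs = 100, loss = "auto",
                         holdout_fraction = 0.1, input_jitter = 0.1,
                         time_shift = 8L, seed = 1L) {
  sources <- match.arg(sources, c("U", "A", "L"), several.ok = TRUE)
  if (margin < 0) stop("'margin' must be >= 0")
  if (input_jitter < 0) stop("'input_jitter' must be >= 0")
  if (time_shift < 0) stop("'time_shift' must be >= 0")
  loss <- match.arg(loss, c("auto", "mixed", "hinge_sq", "hinge"))
  structure(list(sources = sources, pretrain_on_L = pretrain_on_L,
                 margin = margin, learning_rate = learning_rate,
                 epochs = as.integer(epochs), loss = loss,
                 holdout_fraction = holdout_fraction,
                 input_jitter = input_jitter,
                 time_shift = as.integer(time_shift),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialise an untrained embedding model
#'
#' He-style initialisation of the conv and dense weights; batch-norm scales
#' start at one, offsets at zero.
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return A `song_embedder` model object.
#' @export
init_embedder <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  k <- config$kernel
  c_in <- 1L
  with_seed(seed, {
    conv_W <- list(); conv_b <- list()
    bn_gamma <- list(); bn_beta <- list()
    for (l in seq_along(config$channels)) {
      c_out <- config$channels[l]
      fan_in <- c_in * k * k
      conv_W[[l]] <- matrix(stats::rnorm(c_out * fan_in, 0,
                                         sqrt(2 / fan_in)), c_out, fan_in)
      conv_b[[l]] <- numeric(c_out)
      bn_gamma[[l]] <- rep(1, c_out)
      bn_beta[[l]] <- numeric(c_out)
      c_in <- c_out
    }
    cL <- config$channels[length(config$channels)]
    params <- list(
      conv_W = conv_W, conv_b = conv_b,
      bn_gamma = bn_gamma, bn_beta = bn_beta,
      att_v = stats::rnorm(cL, 0, sqrt(1 / cL)), att_b = 0,
      dense_W = matrix(stats::rnorm(config$d * 2 * cL, 0,
                                    sqrt(2 / (2 * cL))), config$d, 2 * cL),
      dense_b = numeric(config$d))
    bn_state <- list(
      mean = lapply(config$channels, function(c) numeric(c)),
      var = lapply(config$channels, function(c) rep(1, c)))
    structure(list(params = params, bn_state = bn_state, config = config,
                   log = NULL),
              class = "song_embedder")
  })
}

#' @export
print.song_embedder <- function(x, ...) {
  cat(sprintf(
    "<song_embedder> d = %d, conv channels %s%s\n", x$config$d,
    paste(x$config$channels, collapse = "/"),
    if (is.null(x$log)) " (untrained)" else
      sprintf(", trained %d epochs (final loss %.4g)",
              nrow(x$log), x$log$train_loss[nrow(x$log)])))
  invisible(x)
}

#' Stack mel spectrograms into the network input array
#'
#' Spectrogram values (dB) are mapped to roughly unit scale as
#' `(dB + 40) / 40` before entering the network.
#'
#' @param mels Named list of `mel_spectrogram` objects.
#' @return Numeric array bands x frames x n, dimnames carrying ids.
#' @export
mel_input_array <- function(mels) {
  stopifnot(length(mels) > 0)
  dims <- dim(mels[[1]]$values)
  X <- array(0, c(dims, length(mels)),
             dimnames = list(NULL, NULL, names(mels)))
  for (i in seq_along(mels)) X[, , i] <- (mels[[i]]$values + 40) / 40
  X
}

#' Embed syllables with a model
#'
#' @param model A `song_embedder`.
#' @param X Input array from [mel_input_array()] (or one `mel_spectrogram`).
#' @return Embedding matrix n x d with syllable ids as rownames; rows have
#'   unit norm when the model is configured to normalise.
#' @export
embed_syllables <- function(model, X) {
  stopifnot(inherits(model, "song_embedder"))
  if (inherits(X, "mel_spectrogram")) X <- mel_input_array(list(syl = X))
  if (!identical(dim(X)[1:2], as.integer(model$config$input_shape)))
    stop("input shape must be ",
         paste(model$config$input_shape, collapse = " x "))
  res <- net_run_cpp(model$params, unclass(model$config), X,
                     matrix(integer(0), 0, 3), numeric(0), 0, "hinge_sq",
                     FALSE, model$bn_state, 0)
  emb <- res$emb
  rownames(emb) <- dimnames(X)[[3]]
  emb
}

#' Standard triplet loss (hinge on embedding distances)
#'
#' `max(0, D_ap - D_an + delta)` per triplet.
#'
#' @param d_ap,d_an Non-negative anchor-positive / anchor-negative distances
#'   (vectorised).
#' @param delta Non-negative margin.
#' @return Loss value(s).
#' @export
triplet_loss <- function(d_ap, d_an, delta) {
  if (any(delta < 0)) stop("'delta' must be >= 0")
  if (any(d_ap < 0 | d_an < 0)) stop("distances must be >= 0")
  pmax(0, d_ap - d_an + delta)
}

#' Ambiguity-aware mixed triplet loss
#'
#' With `p_u = D_an^2 - D_ap^2 - delta` and `p_a = D_an^2 - D_ap^2`, the per
#' triplet loss is `[u (1 - exp(p_u)) + (1 - u)(1 - exp(-|p_a|))]_+`: an
#' unambiguous triplet (`u = 1`) is pushed to satisfy the squared-distance
#' margin, while an ambiguous one (`u = 0`) is pulled toward equidistance.
#'
#' @param d_ap,d_an Non-negative embedding distances (vectorised).
#' @param delta Non-negative margin.
#' @param u Ambiguity flag, 0 (ambiguous) or 1 (unambiguous).
#' @return Loss value(s) in `[0, 1]`.
#' @export
mixed_loss <- function(d_ap, d_an, delta, u) {
  if (any(delta < 0)) stop("'delta' must be >= 0")
  if (any(d_ap < 0 | d_an < 0)) stop("distances must be >= 0")
  if (any(!u %in% c(0, 1))) stop("'u' must be 0 or 1")
  p_u <- d_an^2 - d_ap^2 - delta
  p_a <- d_an^2 - d_ap^2
  pmax(0, u * (1 - exp(p_u)) + (1 - u) * (1 - exp(-abs(p_a))))
}

#' Train the triplet-embedding model
#'
#' Pools the selected triplet sources into one training stream (or runs a
#' pre-training phase on the L triplets first when `pretrain_on_L`). Each
#' epoch every set-valued triplet is expanded by sampling one positive and
#' one negative exemplar uniformly from its sides, all referenced syllables
#' are embedded, and one Adam step is taken on the mean triplet loss. With
#' `holdout_fraction > 0` a fixed fraction of triplets is excluded from the
#' gradient and the returned model carries the parameters of the epoch with
#' the lowest holdout loss.
#'
#' @param model A `song_embedder` from [init_embedder()].
#' @param X Input array from [mel_input_array()] covering every referenced
#'   syllable id.
#' @param datasets Named list of triplet data.frames, e.g.
#'   `list(U = ..., A = ..., L = ...)`.
#' @param cfg A [train_config()].
#' @return The trained `song_embedder`; `$log` holds per-epoch losses and
#'   the per-source triplet counts, `$embeddings` the final embeddings of
#'   all syllables in `X`.
#' @export
train_embedder <- function(model, X, datasets, cfg) {
  stopifnot(inherits(model, "song_embedder"), inherits(cfg, "train_config"))
  ids <- dimnames(X)[[3]]
  if (is.null(ids)) stop("input array must carry syllable ids")
  missing_src <- setdiff(cfg$sources, names(datasets))
  if (length(missing_src))
    stop("datasets missing source(s): ", paste(missing_src, collapse = ", "))
  if (cfg$pretrain_on_L) {
    if (!"L" %in% names(datasets)) stop("pre-training requires L triplets")
    pre_cfg <- cfg
    pre_cfg$sources <- "L"
    pre_cfg$pretrain_on_L <- FALSE
    pre_cfg$loss <- if (cfg$loss == "auto") "hinge_sq" else cfg$loss
    model <- train_embedder(model, X, datasets["L"], pre_cfg)
    main_sources <- setdiff(cfg$sources, "L")
    if (length(main_sources) == 0) return(model)
    cfg$sources <- main_sources
    cfg$pretrain_on_L <- FALSE
  }
  pooled <- do.call(rbind, lapply(cfg$sources, function(s) {
    d <- datasets[[s]]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    data.frame(anchor_id = d$anchor_id, u = d$u, source = s,
               positive_ids = I(d$positive_ids),
               negative_ids = I(d$negative_ids), stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) stop("empty pooled dataset")
  need <- unique(c(pooled$anchor_id, unlist(pooled$positive_ids),
                   unlist(pooled$negative_ids)))
  missing <- setdiff(need, ids)
  if (length(missing))
    stop("mel spectrograms missing for: ",
         paste(utils::head(missing, 5), collapse = ", "))
  loss_type <- if (cfg$loss == "auto") {
    if ("A" %in% cfg$sources && any(pooled$u == 0)) "mixed" else "hinge_sq"
  } else cfg$loss
  lr <- if (is.null(cfg$learning_rate)) {
    if (loss_type == "mixed") 1e-2 else 1e-3
  } else cfg$learning_rate
  n_t <- nrow(pooled)
  a_idx <- match(pooled$anchor_id, ids) - 1L
  u <- as.numeric(pooled$u)

  flat <- unlist(model$params, use.names = FALSE)
  m_adam <- numeric(length(flat))
  v_adam <- numeric(length(flat))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  skel <- model$params
  best_holdout <- Inf
  best_params <- model$params
  best_bn <- model$bn_state
  log_rows <- vector("list", cfg$epochs)

  with_seed(cfg$seed, {
    # hold out whole anchors, so the holdout loss measures generalisation
    # to unseen probes (the regime the model is evaluated in)
    holdout <- rep(FALSE, n_t)
    if (cfg$holdout_fraction > 0 && n_t >= 10) {
      anchors <- unique(pooled$anchor_id)
      held <- sample(anchors, max(1, round(cfg$holdout_fraction *
                                             length(anchors))))
      holdout <- pooled$anchor_id %in% held
      if (all(holdout)) holdout <- rep(FALSE, n_t)
    }
    for (epoch in seq_len(cfg$epochs)) {
      p_idx <- vapply(pooled$positive_ids, function(s)
        match(s[[sample.int(length(s), 1)]], ids), integer(1)) - 1L
      n_idx <- vapply(pooled$negative_ids, function(s)
        match(s[[sample.int(length(s), 1)]], ids), integer(1)) - 1L
      trip <- cbind(a_idx, p_idx, n_idx)
      X_ep <- if (cfg$time_shift > 0) shift_frames(X, cfg$time_shift) else X
      if (cfg$input_jitter > 0)
        X_ep <- X_ep + stats::rnorm(length(X_ep), 0, cfg$input_jitter)
      res <- net_run_cpp(model$params, unclass(model$config), X_ep,
                         trip[!holdout, , drop = FALSE], u[!holdout],
                         cfg$margin, loss_type, TRUE, model$bn_state, 0.1)
      model$bn_state <- res$bn_state
      g <- unlist(res$grads, use.names = FALSE)
      m_adam <- beta1 * m_adam + (1 - beta1) * g
      v_adam <- beta2 * v_adam + (1 - beta2) * g^2
      mhat <- m_adam / (1 - beta1^epoch)
      vhat <- v_adam / (1 - beta2^epoch)
      flat <- unlist(model$params, use.names = FALSE) -
        lr * mhat / (sqrt(vhat) + eps)
      model$params <- utils::relist(flat, skel)
      hold_loss <- NA_real_
      if (any(holdout)) {
        emb <- res$emb
        # epoch selection tracks the discriminative target: score only the
        # unambiguous holdout triplets (the u = 0 term's non-vanishing
        # gradient at its optimum makes the pooled loss a noisy selector);
        # fall back to all holdout triplets if none are unambiguous
        sel <- holdout & (u == 1)
        if (!any(sel)) sel <- holdout
        hl <- embedding_triplet_losses(emb, trip[sel, , drop = FALSE],
                                       u[sel], cfg$margin, loss_type)
        hold_loss <- mean(hl)
        if (hold_loss < best_holdout) {
          best_holdout <- hold_loss
          best_params <- model$params
          best_bn <- model$bn_state
        }
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = res$loss,
                                      holdout_loss = hold_loss)
    }
  })
  if (is.finite(best_holdout)) {
    model$params <- best_params
    model$bn_state <- best_bn
  }
  log <- do.call(rbind, log_rows)
  log$loss_type <- loss_type
  src_counts <- table(pooled$source)
  combined <- if (is.null(model$log)) log else rbind(model$log, log)
  # the audit reflects the final training phase's sources
  attr(combined, "sources") <- stats::setNames(as.integer(src_counts),
                                               names(src_counts))
  model$log <- combined
  model$embeddings <- embed_syllables(model, X)
  model
}

#' Per-triplet losses from an embedding matrix (used for holdout scoring)
#' @noRd
embedding_triplet_losses <- function(emb, trip, u, delta, loss_type) {
  d_ap <- sqrt(rowSums((emb[trip[, 1] + 1, , drop = FALSE] -
                          emb[trip[, 2] + 1, , drop = FALSE])^2))
  d_an <- sqrt(rowSums((emb[trip[, 1] + 1, , drop = FALSE] -
                          emb[trip[, 3] + 1, , drop = FALSE])^2))
  switch(loss_type,
         mixed = mixed_loss(d_ap, d_an, delta, u),
         hinge_sq = pmax(0, d_ap^2 - d_an^2 + delta),
         hinge = triplet_loss(d_ap, d_an, delta))
}

#' Euclidean distance matrix between embedded syllables
#'
#' @param emb Embedding matrix with syllable ids as rownames.
#' @return A `dissimilarity_matrix` of pairwise Euclidean distances.
#' @export
embedding_distance_matrix <- function(emb) {
  dissimilarity_matrix_from_values(as.matrix(stats::dist(emb)),
                                   rownames(emb))
}

#' AXB decision in embedding space
#'
#' Delegates to [axb_decide()] on the Euclidean embedding-distance matrix.
#'
#' @param emb Embedding matrix (rownames = ids) or a `song_embedder` with
#'   stored `$embeddings`.
#' @param probe,side_A_ids,side_B_ids As in [axb_decide()].
#' @param aggregate Probe-to-side aggregation.
#' @return As [axb_decide()].
#' @export
embedding_axb <- function(emb, probe, side_A_ids, side_B_ids,
                          aggregate = "mean") {
  if (inherits(emb, "song_embedder")) emb <- emb$embeddings
  axb_decide(embedding_distance_matrix(emb), probe, side_A_ids, side_B_ids,
             aggregate = aggregate)
}

#' Randomly shift each spectrogram along time, filling with the input floor
#' @noRd
shift_frames <- function(X, kmax) {
  n <- dim(X)[3]
  ks <- sample(seq(-kmax, kmax), n, replace = TRUE)
  for (i in seq_len(n)) {
    k <- ks[i]
    if (k == 0) next
    M <- X[, , i]
    fill <- matrix(min(M), nrow(M), abs(k))
    X[, , i] <- if (k > 0)
      cbind(fill, M[, seq_len(ncol(M) - k), drop = FALSE])
    else
      cbind(M[, (-k + 1):ncol(M), drop = FALSE], fill)
  }
  X
}
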