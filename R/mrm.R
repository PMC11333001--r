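# Multiple regression on distance matrices (MRM): explain an embedding's
# pairwise distances from acoustic-feature distance matrices, with inference
# by simultaneous row/column permutation of the response matrix.

#' Build predictor distance matrices from summary statistics
#'
#' Each of the 26 measures (5 statistics x 5 features plus syllable length)
#' is z-scored across syllables first. Groupings: `per_measure` gives one
#' absolute-difference matrix per measure (26); `per_feature` gives one
#' Euclidean distance matrix over each feature's 5 statistics plus one for
#' syllable length (6); `per_statistic` gives one Euclidean matrix for each
#' of the mean, start and end statistics pooled across the 5 features (3).
#' Zero-variance measures are excluded with a warning.
#'
#' @param stats_table Data.frame from [corpus_summary_stats()] (rownames =
#'   syllable ids).
#' @param grouping One of `"per_measure"`, `"per_feature"`,
#'   `"per_statistic"`.
#' @return Named list of symmetric distance matrices.
#' @export
build_predictor_matrices <- function(stats_table,
                                     grouping = c("per_measure",
                                                  "per_feature",
                                                  "per_statistic")) {
  grouping <- match.arg(grouping)
  if (nrow(stats_table) < 3) stop("need at least three syllables")
  X <- as.matrix(stats_table)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance measure(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Z <- scale(X)
  features <- c("fundamental_frequency", "peak_frequency",
                "fundamental_change", "wiener_entropy", "harmonicity")
  statistics <- c("mean", "max", "min", "start", "end")
  euclid <- function(cols) {
    as.matrix(stats::dist(Z[, cols, drop = FALSE]))
  }
  out <- switch(grouping,
    per_measure = {
      ms <- lapply(colnames(Z), function(m) abs(outer(Z[, m], Z[, m], "-")))
      names(ms) <- colnames(Z)
      ms
    },
    per_feature = {
      ms <- lapply(features, function(f) {
        cols <- intersect(paste0(f, "_", statistics), colnames(Z))
        euclid(cols)
      })
      names(ms) <- features
      if ("syllable_length" %in% colnames(Z))
        ms$syllable_length <- euclid("syllable_length")
      ms
    },
    per_statistic = {
      ms <- lapply(c("mean", "start", "end"), function(s) {
        cols <- intersect(paste0(features, "_", s), colnames(Z))
        euclid(cols)
      })
      names(ms) <- c("mean", "start", "end")
      ms
    })
  lapply(out, function(m) {
    dimnames(m) <- list(rownames(stats_table), rownames(stats_table))
    m
  })
}

#' Multiple regression on distance matrices with permutation inference
#'
#' Regresses the vectorised lower triangle (diagonal excluded) of the
#' response matrix on the predictors' lower triangles by ordinary least
#' squares. All vectors are z-scored, so coefficients are standardised.
#' Inference permutes the response matrix's rows and columns jointly
#' `n_perm` times; two-sided per-coefficient p-values are the proportion of
#' permuted `|coefficient|` at or above the observed one, and the model
#' p-value the proportion of permuted R-squared at or above observed, both
#' with the plus-one correction (so the smallest attainable p is
#' `1 / (n_perm + 1)`).
#'
#' @param response A `dissimilarity_matrix` or square symmetric matrix.
#' @param predictors Named list of square matrices over the same ids.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param condition_threshold Condition-number threshold above which
#'   collinearity is reported and a pseudo-inverse used.
#' @return An `mrm_result`: list with `coefficients`, `p_values`,
#'   `r_squared`, `model_p`, `n_permutations`, `n_objects`.
#' @export
mrm <- function(response, predictors, n_perm = 10000, seed = 1L,
                condition_threshold = 1e8) {
  R <- if (inherits(response, "dissimilarity_matrix")) response$values else
    as.matrix(response)
  n <- nrow(R)
  if (ncol(R) != n) stop("response must be square")
  for (nm in names(predictors)) {
    P <- predictors[[nm]]
    if (!all(dim(P) == n)) stop("predictor '", nm, "' has wrong dimensions")
    if (!is.null(rownames(P)) && !is.null(rownames(R)) &&
        !identical(rownames(P), rownames(R)))
      stop("predictor '", nm, "' ids do not match the response")
  }
  lower <- lower.tri(R)
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("constant distance vector")
    (v - mean(v)) / s
  }
  y <- zs(R[lower])
  Xp <- vapply(predictors, function(P) zs(P[lower]), numeric(sum(lower)))
  Xd <- cbind(`(Intercept)` = 1, Xp)
  XtX <- crossprod(Xd)
  cond <- kappa(XtX, exact = TRUE)
  solver <- if (is.finite(cond) && cond < condition_threshold) {
    solve(XtX)
  } else {
    warning(sprintf(
      "collinear predictors (condition number %.3g); using pseudo-inverse",
      cond))
    pseudo_inverse(XtX)
  }
  hat <- solver %*% t(Xd)            # (p+1) x m projector
  fit_once <- function(yv) {
    beta <- drop(hat %*% yv)
    fitted <- drop(Xd %*% beta)
    r2 <- 1 - sum((yv - fitted)^2) / sum((yv - mean(yv))^2)
    list(beta = beta[-1], r2 = r2)
  }
  obs <- fit_once(y)
  perm_stats <- with_seed(seed, {
    count_beta <- rep(1L, length(obs$beta))
    count_r2 <- 1L
    for (b in seq_len(n_perm)) {
      ord <- sample.int(n)
      Rp <- R[ord, ord]
      fp <- fit_once(zs(Rp[lower]))
      count_beta <- count_beta + (abs(fp$beta) >= abs(obs$beta))
      count_r2 <- count_r2 + (fp$r2 >= obs$r2)
    }
    list(p_beta = count_beta / (n_perm + 1), p_r2 = count_r2 / (n_perm + 1))
  })
  structure(list(coefficients = stats::setNames(obs$beta, names(predictors)),
                 p_values = stats::setNames(perm_stats$p_beta,
                                            names(predictors)),
                 r_squared = obs$r2, model_p = perm_stats$p_r2,
                 n_permutations = n_perm, n_objects = n),
            class = "mrm_result")
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf(
    "<mrm_result> %d objects, R^2 = %.3f (model p = %.4g, %d permutations)\n",
    x$n_objects, x$r_squared, x$model_p, x$n_permutations))
  tab <- data.frame(coefficient = round(x$coefficients, 4),
                    p_value = signif(x$p_values, 3))
  print(tab)
  invisible(x)
}

#' @export
coef.mrm_result <- function(object, ...) object$coefficients

#' Write an MRM coefficient table as delimited text
#' @param x An `mrm_result`.
#' @param path Output path.
#' @export
write_mrm_table <- function(x, path) {
  tab <- data.frame(predictor = names(x$coefficients),
                    coefficient = x$coefficients, p_value = x$p_values,
                    r_squared = x$r_squared, model_p = x$model_p,
                    n_permutations = x$n_permutations)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
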