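#' Sampling-based Shapley attributions for one prediction
#'
#' Permutation-sampling estimate of Shapley values under marginal feature
#' replacement: for each Monte-Carlo sample a feature permutation and a
#' background row are drawn, features are switched from the background value
#' to the explained value in permutation order, and each feature is credited
#' with the resulting change in model output. Background rows are cycled in a
#' balanced (equal-count) order so the telescoping sum makes the local
#' accuracy identity \code{base + sum(phi) == f(x)} hold to machine
#' precision, with \code{base} the mean model output over the sampled
#' background rows.
#'
#' @param model an \code{mlp_model}, or a function mapping a numeric matrix
#'   of rows to a numeric vector of outputs.
#' @param x the feature vector to explain.
#' @param background matrix of background rows (same width as \code{x}).
#' @param n_samples number of permutation samples (must be >= 2 * D).
#' @param seed integer seed.
#' @return A \code{shap_result}: named \code{phi}, \code{base},
#'   \code{fx} and the per-feature sampling standard errors.
#' @export
shap_attributions <- function(model, x, background, n_samples = 2000,
                              seed = 1L) {
  f <- if (is.function(model)) model else function(X) mlp_predict(model, X)$prob
  x <- as.numeric(x)
  D <- length(x)
  if (is.null(dim(background))) background <- matrix(background, ncol = D)
  if (ncol(background) != D || nrow(background) == 0L) {
    stop("background must be a non-empty matrix with ", D, " columns",
         call. = FALSE)
  }
  if (n_samples < 2L * D) {
    stop("n_samples must be at least 2 * D = ", 2L * D, call. = FALSE)
  }
  nb <- nrow(background)
  draws <- with_seed(seed, list(
    bg_order = sample(nb),
    perms = replicate(n_samples, sample(D), simplify = FALSE)
  ))
  bg_idx <- draws$bg_order[((seq_len(n_samples) - 1L) %% nb) + 1L]

  # Build all masked rows for all samples, one forward pass.
  big <- matrix(0, n_samples * (D + 1L), D)
  for (s in seq_len(n_samples)) {
    row <- background[bg_idx[s], ]
    block <- matrix(row, D + 1L, D, byrow = TRUE)
    perm <- draws$perms[[s]]
    for (k in seq_len(D)) {
      block[(k + 1L):(D + 1L), perm[k]] <- x[perm[k]]
    }
    big[((s - 1L) * (D + 1L) + 1L):(s * (D + 1L)), ] <- block
  }
  out <- f(big)
  contrib <- matrix(0, n_samples, D)
  for (s in seq_len(n_samples)) {
    o <- out[((s - 1L) * (D + 1L) + 1L):(s * (D + 1L))]
    contrib[s, draws$perms[[s]]] <- diff(o)
  }
  base_vals <- out[seq(1L, by = D + 1L, length.out = n_samples)]
  phi <- colMeans(contrib)
  names(phi) <- if (!is.null(colnames(background))) colnames(background)
                else paste0("x", seq_len(D))
  structure(
    list(phi = phi, base = mean(base_vals), fx = f(matrix(x, nrow = 1))[1],
         se = apply(contrib, 2, sd) / sqrt(n_samples),
         n_samples = n_samples),
    class = "shap_result"
  )
}

#' Shapley attributions over a dataset
#'
#' @param model as in \code{\link{shap_attributions}}.
#' @param X matrix of rows to explain.
#' @param background background matrix (defaults to \code{X}).
#' @param n_samples permutation samples per row.
#' @param seed integer seed.
#' @return Matrix of phi values (rows match \code{X}).
#' @export
shap_global <- function(model, X, background = X, n_samples = 200,
                        seed = 1L) {
  res <- lapply(seq_len(nrow(X)), function(i) {
    shap_attributions(model, X[i, ], background, n_samples, seed + i)$phi
  })
  do.call(rbind, res)
}

#' Top-k features by mean absolute Shapley value
#'
#' Descending global importance ranking by mean |phi|, with deterministic
#' tie-breaking by feature index; used for the top-7 feature reduction.
#'
#' @param phi matrix of Shapley values (rows = explained instances) or a
#'   single \code{shap_result}.
#' @param k number of features to return (default 7).
#' @return Character vector of the k top feature names, plus the full mean
#'   |phi| ranking as attribute \code{"importance"}.
#' @export
top_k_features <- function(phi, k = 7) {
  if (inherits(phi, "shap_result")) phi <- matrix(phi$phi, nrow = 1,
                                                  dimnames = list(NULL, names(phi$phi)))
  D <- ncol(phi)
  if (k > D) stop("k exceeds the number of features", call. = FALSE)
  imp <- colMeans(abs(phi))
  ord <- order(-imp, seq_len(D))
  ranked <- imp[ord]
  structure(names(ranked)[seq_len(k)], importance = ranked)
}
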