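#' Training configuration for the broadband predictor
#'
#' @param epochs maximum Levenberg-Marquardt iterations (default 1000).
#' @param learning_rate initial damping factor (default 0.01).
#' @param train_frac training fraction of an unsplit dataset (default 0.8).
#' @param balance class-balancing mode for the training split.
#' @param hidden hidden-layer width (default 10).
#' @param grad_tol stop when the max absolute gradient falls below this.
#' @param seed integer seed for weight initialization and splits.
#' @return A \code{train_config} object.
#' @export
train_config <- function(epochs = 1000, learning_rate = 0.01,
                         train_frac = 0.8,
                         balance = c("undersample", "oversample", "none"),
                         hidden = 10, grad_tol = 1e-7, seed = 1L) {
  balance <- match.arg(balance)
  stopifnot(epochs >= 1, learning_rate > 0, train_frac > 0, train_frac < 1)
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         train_frac = train_frac, balance = balance, hidden = as.integer(hidden),
         grad_tol = grad_tol, seed = as.integer(seed)),
    class = "train_config"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

unpack_theta <- function(theta, d_in, d_hid) {
  n1 <- d_in * d_hid
  list(
    W1 = matrix(theta[seq_len(n1)], d_in, d_hid),
    b1 = theta[n1 + seq_len(d_hid)],
    w2 = theta[n1 + d_hid + seq_len(d_hid)],
    b2 = theta[n1 + 2L * d_hid + 1L]
  )
}

mlp_forward <- function(theta, X, d_hid) {
  p <- unpack_theta(theta, ncol(X), d_hid)
  A1 <- sigmoid(sweep(X %*% p$W1, 2, p$b1, "+"))
  out <- sigmoid(drop(A1 %*% p$w2) + p$b2)
  list(out = out, A1 = A1, p = p)
}

# Jacobian of the network output w.r.t. all parameters (N x n_par); the
# network is small (141 parameters at 12-10-1) so the exact Gauss-Newton
# normal equations are cheap.
mlp_jacobian <- function(fw, X, d_hid) {
  s2 <- fw$out * (1 - fw$out)                  # N
  dA1 <- fw$A1 * (1 - fw$A1)                   # N x H
  G <- (s2 * dA1) * matrix(fw$p$w2, nrow(X), d_hid, byrow = TRUE) # N x H
  JW1 <- do.call(cbind, lapply(seq_len(d_hid), function(j) G[, j] * X))
  cbind(JW1, G, s2 * fw$A1, s2)
}

#' Train the sigmoid MLP broadband predictor by Levenberg-Marquardt
#'
#' A 12-10-1 fully connected network with sigmoid hidden and output
#' activations (141 trainable parameters at the default widths), trained to
#' minimize mean squared error by a damped Gauss-Newton loop on the exact
#' Jacobian: a step is accepted and the damping divided by 10 when it lowers
#' the SSE, otherwise the damping is multiplied by 10 and the step retried.
#' Features are z-scored with statistics from the training data, stored with
#' the model. Training stops at the epoch cap, at the gradient tolerance, or
#' on damping overflow.
#'
#' @param train an \code{ae_dataset}, typically balanced (see
#'   \code{\link{undersample}}).
#' @param config a \code{\link{train_config}}.
#' @return An \code{mlp_model}: weights, scaler, decision threshold (0.5) and
#'   a training history (SSE per epoch, stop reason).
#' @export
train_mlp <- function(train, config = train_config()) {
  stopifnot(inherits(train, "ae_dataset"))
  X <- train$X
  y <- as.numeric(train$y)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")

  d_in <- ncol(Xs)
  H <- config$hidden
  n_par <- d_in * H + 2L * H + 1L
  theta <- with_seed(config$seed, runif(n_par, -0.5, 0.5))

  lambda <- config$learning_rate
  fw <- mlp_forward(theta, Xs, H)
  sse <- sum((fw$out - y)^2)
  history <- numeric(0)
  reason <- "epoch_cap"

  for (epoch in seq_len(config$epochs)) {
    J <- mlp_jacobian(fw, Xs, H)
    r <- fw$out - y
    g <- drop(crossprod(J, r))
    if (max(abs(g)) < config$grad_tol) { reason <- "gradient_tol"; break }
    JtJ <- crossprod(J)
    dmp <- pmax(diag(JtJ), 1e-8)
    accepted <- FALSE
    for (try in 1:25) {
      step <- tryCatch(
        solve(JtJ + lambda * diag(dmp), -g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        cand <- theta + step
        fw_new <- mlp_forward(cand, Xs, H)
        sse_new <- sum((fw_new$out - y)^2)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- cand; fw <- fw_new; sse <- sse_new
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e10) break
    }
    history <- c(history, sse)
    if (!is.finite(sse)) {
      stop("training diverged at epoch ", epoch, call. = FALSE)
    }
    if (!accepted) { reason <- "damping_overflow"; break }
  }

  p <- unpack_theta(theta, d_in, H)
  structure(
    list(W1 = p$W1, b1 = p$b1, w2 = p$w2, b2 = p$b2,
         center = mu, scale = sdv, threshold = 0.5,
         feature_names = colnames(X), hidden = H,
         history = history, stop_reason = reason,
         config = config),
    class = "mlp_model"
  )
}

#' Predict broadband-event probability for feature vectors
#'
#' Applies the stored z-scoring and the forward pass; a model output of 0.5
#' or greater is a positive prediction (the tie at exactly 0.5 is positive).
#'
#' @param model an \code{mlp_model}.
#' @param X numeric matrix (rows are 12-feature vectors) or a single vector.
#' @return List with numeric \code{prob} in (0, 1) and logical
#'   \code{positive}.
#' @export
mlp_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(model$W1)) {
    stop("feature dimension mismatch: expected ", nrow(model$W1),
         ", got ", ncol(X), call. = FALSE)
  }
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  Xs <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
  A1 <- sigmoid(sweep(Xs %*% model$W1, 2, model$b1, "+"))
  prob <- sigmoid(drop(A1 %*% model$w2) + model$b2)
  # keep outputs in the open interval despite float saturation
  prob <- pmin(pmax(prob, 1e-15), 1 - 1e-15)
  list(prob = prob, positive = prob >= model$threshold)
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  mlp_predict(object, newdata)
}

#' Confusion counts and derived classification metrics
#'
#' @param predicted logical/0-1 predictions.
#' @param actual logical/0-1 labels of equal length.
#' @return A \code{confusion_metrics} object: counts TP, FP, TN, FN and
#'   accuracy, sensitivity (recall), precision and specificity. Ratios with a
#'   zero denominator are NaN with a warning.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_metrics <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual)) {
    stop("predicted and actual must be equal-length, non-empty", call. = FALSE)
  }
  p <- as.logical(predicted)
  a <- as.logical(actual)
  tp <- sum(p & a); fp <- sum(p & !a); tn <- sum(!p & !a); fn <- sum(!p & a)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  structure(
    list(TP = tp, FP = fp, TN = tn, FN = fn,
         accuracy = (tp + tn) / length(p),
         sensitivity = ratio(tp, tp + fn, "sensitivity"),
         precision = ratio(tp, tp + fp, "precision"),
         specificity = ratio(tn, tn + fp, "specificity")),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("accuracy %.4f  sensitivity %.4f  precision %.4f  specificity %.4f\n",
              x$accuracy, x$sensitivity, x$precision, x$specificity))
  invisible(x)
}
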