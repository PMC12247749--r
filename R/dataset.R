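#' Feature column sets
#'
#' The 12-feature set pairs the ultra-harmonics (orders 1--7) with pressure,
#' target coordinates, the microbubble-kinetics proxy (tracker H4 level
#' normalized by its run maximum) and the tumor flag. The 20-feature set adds
#' the harmonics (orders 2--8) and the pulse number, and is used for the
#' attention model and Shapley analysis.
#'
#' @param feature_set 12 or 20.
#' @return Character vector of feature names.
#' @export
feature_names <- function(feature_set = 12) {
  base12 <- c(paste0("uh", 1:7), "pressure", "target_x", "target_y",
              "mb_kinetics", "tumor")
  if (feature_set == 12) return(base12)
  if (feature_set == 20) return(c(paste0("h", 2:8), base12, "pulse_number"))
  stop("feature_set must be 12 or 20", call. = FALSE)
}

#' Assemble a next-pulse-labelled dataset from sonication records
#'
#' Row t pairs the features measured at pulse t with a binary label equal to
#' the broadband event flag of pulse t + 1; the final pulse of every run is
#' dropped. The microbubble-kinetics feature is the tracker 4th-harmonic
#' level normalized by its within-run maximum, clipped to [0, 1].
#'
#' @param records list of \code{sonication_record} (each with >= 2 pulses).
#' @param feature_set 12 or 20 (see \code{\link{feature_names}}).
#' @return An \code{ae_dataset}: list with matrix \code{X} (N x D), binary
#'   vector \code{y}, \code{feature_set}, \code{run_id} per row, and class
#'   counts.
#' @export
build_dataset <- function(records, feature_set = 12) {
  if (length(records) == 0L) stop("no records supplied", call. = FALSE)
  if (inherits(records, "sonication_record")) records <- list(records)
  fnames <- feature_names(feature_set)
  xs <- vector("list", length(records))
  ys <- vector("list", length(records))
  ids <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    p <- r$pulses
    n <- nrow(p)
    if (n < 2L) stop("records need at least 2 pulses", call. = FALSE)
    mx <- max(p$h4_db)
    mbk <- if (mx > 0) pmin(pmax(p$h4_db / mx, 0), 1) else rep(0, n)
    feat <- data.frame(
      p[paste0("h", 2:8)], p[paste0("uh", 1:7)],
      pressure = p$pressure_mpa,
      target_x = r$subject$target_x, target_y = r$subject$target_y,
      mb_kinetics = mbk, tumor = as.numeric(r$subject$tumor),
      pulse_number = p$pulse_index
    )
    keep <- seq_len(n - 1L)
    xs[[i]] <- as.matrix(feat[keep, fnames, drop = FALSE])
    ys[[i]] <- as.integer(p$is_event[keep + 1L])
    ids[[i]] <- rep(i, n - 1L)
  }
  X <- do.call(rbind, xs)
  y <- unlist(ys)
  new_dataset(X, y, feature_set, unlist(ids))
}

new_dataset <- function(X, y, feature_set, run_id = rep(NA_integer_, nrow(X))) {
  stopifnot(nrow(X) == length(y))
  structure(
    list(X = X, y = as.integer(y), feature_set = feature_set,
         run_id = run_id,
         n = nrow(X), n_pos = sum(y == 1L), n_neg = sum(y == 0L)),
    class = "ae_dataset"
  )
}

subset_dataset <- function(dataset, idx) {
  new_dataset(dataset$X[idx, , drop = FALSE], dataset$y[idx],
              dataset$feature_set, dataset$run_id[idx])
}

#' Balance a dataset by under-sampling the majority class
#'
#' Keeps every positive (broadband event) row and samples an equal number of
#' negatives without replacement; seeded and deterministic.
#'
#' @param dataset an \code{ae_dataset} with both classes present.
#' @param seed integer seed.
#' @return Balanced \code{ae_dataset}.
#' @export
undersample <- function(dataset, seed = 1L) {
  pos <- which(dataset$y == 1L)
  neg <- which(dataset$y == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (length(neg) < length(pos)) {
    stop("more positives than negatives; under-sampling undefined",
         call. = FALSE)
  }
  keep_neg <- with_seed(seed, sample(neg, length(pos)))
  subset_dataset(dataset, sort(c(pos, keep_neg)))
}

#' Balance a dataset by duplicating the minority class
#'
#' Alternative to \code{\link{undersample}} behind the same interface:
#' positives are duplicated (sampling with replacement) up to the negative
#' count.
#'
#' @inheritParams undersample
#' @return Balanced \code{ae_dataset}.
#' @export
oversample <- function(dataset, seed = 1L) {
  pos <- which(dataset$y == 1L)
  neg <- which(dataset$y == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  extra <- with_seed(seed,
                     sample(pos, max(0L, length(neg) - length(pos)),
                            replace = TRUE))
  subset_dataset(dataset, c(seq_len(dataset$n), extra))
}

#' Train/test split with optional class balancing of the training part
#'
#' Stratified random split: \code{train_frac} of each class goes to training.
#' The training split may then be balanced 1:1 by under-sampling (default) or
#' oversampling; the test split always keeps the natural class ratio.
#'
#' @param dataset an \code{ae_dataset}.
#' @param seed integer seed.
#' @param train_frac training fraction (default 0.8).
#' @param balance "undersample", "oversample" or "none".
#' @return List with \code{train} and \code{test} \code{ae_dataset}s.
#' @export
train_test_split <- function(dataset, seed = 1L, train_frac = 0.8,
                             balance = c("undersample", "oversample", "none")) {
  balance <- match.arg(balance)
  pos <- which(dataset$y == 1L)
  neg <- which(dataset$y == 0L)
  sel <- with_seed(seed, {
    tp <- sample(pos, round(train_frac * length(pos)))
    tn <- sample(neg, round(train_frac * length(neg)))
    list(train = sort(c(tp, tn)))
  })
  train <- subset_dataset(dataset, sel$train)
  test <- subset_dataset(dataset, setdiff(seq_len(dataset$n), sel$train))
  if (balance == "undersample") train <- undersample(train, seed + 1L)
  if (balance == "oversample") train <- oversample(train, seed + 1L)
  list(train = train, test = test)
}
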