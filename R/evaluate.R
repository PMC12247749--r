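#' Broadband event rate of a record set
#'
#' @param records a \code{sonication_record}, a list of them, or a logical /
#'   0-1 vector of per-pulse event flags.
#' @return List with integer \code{count}, \code{total} and \code{percent}
#'   (rounded to 2 decimals).
#' @examples
#' event_rate(c(rep(1, 46), rep(0, 1002)))  # 4.39% (46/1048)
#' @export
event_rate <- function(records) {
  flags <- collect_flags(records, "is_event")
  if (length(flags) == 0L) stop("no pulses supplied", call. = FALSE)
  count <- sum(flags == 1L)
  list(count = count, total = length(flags),
       percent = round(100 * count / length(flags), 2))
}

#' Positive-prediction rate of a record set
#'
#' @inheritParams event_rate
#' @return List with \code{count}, \code{total} and \code{percent}.
#' @export
prediction_rate <- function(records) {
  flags <- collect_flags(records, "prediction")
  if (length(flags) == 0L) stop("no pulses supplied", call. = FALSE)
  count <- sum(flags == 1L)
  list(count = count, total = length(flags),
       percent = round(100 * count / length(flags), 2))
}

collect_flags <- function(records, col) {
  if (inherits(records, "sonication_record")) records <- list(records)
  if (is.list(records)) {
    unlist(lapply(records, function(r) as.integer(r$pulses[[col]])))
  } else {
    as.integer(records)
  }
}

#' Percent reduction between two rates
#'
#' \code{100 * (rate_ref - rate_new) / rate_ref}; the integer-rounded value
#' is attached as attribute \code{"rounded"} for reporting.
#'
#' @param rate_ref reference rate (> 0).
#' @param rate_new new rate.
#' @return Percent reduction.
#' @examples
#' percent_reduction(14 / 1048, 1 / 1048)  # ~92.86, reported as 93
#' @export
percent_reduction <- function(rate_ref, rate_new) {
  if (rate_ref <= 0) stop("reference rate must be positive", call. = FALSE)
  x <- 100 * (rate_ref - rate_new) / rate_ref
  structure(x, rounded = round(x))
}

#' Hyper-tangent (saturating) curve fit
#'
#' Least-squares fit of \code{y = a + b * tanh((x - c) / d)} with multi-start
#' initialization (\code{nls} with a Nelder-Mead fallback). The inflection
#' point \code{c} marks the exposure at which broadband emission likelihood
#' escalates and is used as the upper bound of the treatment window.
#'
#' @param x,y numeric vectors (>= 5 points, x spread > 0).
#' @param n_starts number of multi-start initializations.
#' @param seed integer seed for start jitter.
#' @return A \code{tanh_fit}: parameters a, b, c (inflection), d (width > 0),
#'   residual sum of squares, and a \code{degenerate} flag set when y has no
#'   usable spread (b ~ 0, c unidentifiable).
#' @export
fit_tanh <- function(x, y, n_starts = 20, seed = 1L) {
  if (length(x) < 5L || length(x) != length(y)) {
    stop("need >= 5 (x, y) points", call. = FALSE)
  }
  if (diff(range(x)) <= 0) stop("x must have positive spread", call. = FALSE)
  if (sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    return(structure(list(a = mean(y), b = 0, c = NA_real_, d = NA_real_,
                          rss = 0, degenerate = TRUE), class = "tanh_fit"))
  }
  sse <- function(p) {
    if (p[4] <= 0) return(Inf)
    sum((y - (p[1] + p[2] * tanh((x - p[3]) / p[4])))^2)
  }
  starts <- with_seed(seed, {
    cs <- quantile(x, probs = seq(0.1, 0.9, length.out = n_starts))
    lapply(seq_len(n_starts), function(i) {
      c(a = mean(y), b = diff(range(y)) / 2 * sample(c(-1, 1), 1),
        c = as.numeric(cs[i]),
        d = diff(range(x)) / runif(1, 2, 10))
    })
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(
        nls(y ~ a + b * tanh((x - c) / d),
            start = as.list(st),
            control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
      ),
      error = function(e) NULL
    )
    cand <- if (!is.null(fit)) {
      p <- coef(fit)[c("a", "b", "c", "d")]
      list(par = p, rss = sse(p))
    } else {
      o <- optim(st, sse, method = "Nelder-Mead",
                 control = list(maxit = 2000))
      list(par = o$par, rss = o$value)
    }
    if (is.finite(cand$rss) && (is.null(best) || cand$rss < best$rss)) {
      best <- cand
    }
  }
  if (is.null(best)) stop("tanh fit failed for all starts", call. = FALSE)
  p <- best$par
  if (p[["d"]] < 0) { # tanh(-z) = -tanh(z): canonicalize width > 0
    p[["d"]] <- -p[["d"]]; p[["b"]] <- -p[["b"]]
  }
  structure(list(a = p[["a"]], b = p[["b"]], c = p[["c"]], d = p[["d"]],
                 rss = best$rss, degenerate = FALSE), class = "tanh_fit")
}

#' Treatment window from a lower bound and a fitted inflection
#'
#' The lower bound is an input (the lowest exposure with measurable
#' blood-brain-barrier opening); the upper bound is the inflection point of
#' the hyper-tangent fit of broadband level versus exposure.
#'
#' @param lower_bound lower bound, MPa.
#' @param fit a \code{\link{fit_tanh}} result (or a number taken directly as
#'   the upper bound).
#' @return List with \code{lower}, \code{upper} and \code{width} (MPa).
#' @examples
#' treatment_window(0.17, 0.26)  # width 0.09 MPa
#' @export
treatment_window <- function(lower_bound, fit) {
  upper <- if (inherits(fit, "tanh_fit")) {
    if (fit$degenerate) stop("degenerate fit: no inflection", call. = FALSE)
    fit$c
  } else {
    as.numeric(fit)
  }
  if (lower_bound >= upper) {
    stop("empty treatment window: lower bound >= upper bound", call. = FALSE)
  }
  list(lower = lower_bound, upper = upper, width = upper - lower_bound)
}

#' Mean, SD and adjusted Fisher-Pearson skewness
#'
#' @param x numeric sample (n >= 3 for skewness; constant samples have no
#'   defined skewness).
#' @return List with \code{mean}, \code{sd} (n - 1 denominator) and
#'   \code{skewness}.
#' @export
distribution_stats <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need n >= 3 for skewness", call. = FALSE)
  s <- sd(x)
  if (s == 0) stop("skewness undefined for a constant sample", call. = FALSE)
  m <- mean(x)
  g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  list(mean = m, sd = s, skewness = skew)
}

#' F and Levene (Brown-Forsythe) variance tests for two groups
#'
#' The F test compares \code{var(a) / var(b)} against the F distribution
#' (two-sided). The Levene statistic uses the robust Brown-Forsythe variant
#' (absolute deviations from the group medians, one-way ANOVA F), suited to
#' the skewed harmonic-level distributions.
#'
#' @param group_a,group_b numeric samples (each n >= 2).
#' @return List with \code{f_statistic}, \code{f_p}, \code{levene_statistic},
#'   \code{levene_p} and the degrees of freedom.
#' @export
variance_tests <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2", call. = FALSE)
  va <- var(group_a); vb <- var(group_b)
  if (va == 0 && vb == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  f_stat <- va / vb
  f_p <- 2 * min(pf(f_stat, na - 1, nb - 1),
                 pf(f_stat, na - 1, nb - 1, lower.tail = FALSE))
  f_p <- min(f_p, 1)

  za <- abs(group_a - median(group_a))
  zb <- abs(group_b - median(group_b))
  z <- c(za, zb)
  g <- c(rep(1L, na), rep(2L, nb))
  zbar <- mean(z)
  means <- c(mean(za), mean(zb))
  ssb <- na * (means[1] - zbar)^2 + nb * (means[2] - zbar)^2
  ssw <- sum((za - means[1])^2) + sum((zb - means[2])^2)
  df1 <- 1L
  df2 <- na + nb - 2L
  lev <- (ssb / df1) / (ssw / df2)
  lev_p <- pf(lev, df1, df2, lower.tail = FALSE)
  list(f_statistic = f_stat, f_p = f_p, f_df = c(na - 1L, nb - 1L),
       levene_statistic = lev, levene_p = lev_p, levene_df = c(df1, df2))
}

#' Summarize a multi-arm controller experiment
#'
#' Aggregates per-arm event and prediction rates, 7th-harmonic distribution
#' statistics, surrogate permeability, and (when exposure spread allows) the
#' hyper-tangent treatment-window analysis: the lower bound is the smallest
#' arm-mean pressure whose permeability surrogate exceeds background + 2 SD,
#' the upper bound the fitted inflection of broadband level versus pressure.
#'
#' @param arms named list; each element is a list of \code{sonication_record}
#'   for one controller arm.
#' @param window_lower optional fixed lower bound, MPa (otherwise derived
#'   from the surrogate as above, or omitted).
#' @return An \code{experiment_summary}: per-arm data frame plus optional
#'   window fields.
#' @export
summarize_experiment <- function(arms, window_lower = NULL) {
  if (length(arms) == 0L) stop("need at least one arm", call. = FALSE)
  rows <- lapply(names(arms), function(nm) {
    recs <- arms[[nm]]
    er <- event_rate(recs)
    pr <- prediction_rate(recs)
    h7 <- unlist(lapply(recs, function(r) {
      r$pulses$h7[r$pulses$phase %in% c("recording", "active", "ceased")]
    }))
    ds <- if (length(h7) >= 3 && sd(h7) > 0) distribution_stats(h7) else
      list(mean = mean(h7), sd = NA_real_, skewness = NA_real_)
    kt <- vapply(recs, ktrans_surrogate, numeric(1))
    data.frame(arm = nm, n_runs = length(recs),
               events = er$count, pulses = er$total,
               event_percent = er$percent,
               predictions = pr$count, prediction_percent = pr$percent,
               h7_mean = ds$mean, h7_sd = ds$sd, h7_skewness = ds$skewness,
               ktrans_mean = mean(kt),
               mean_pressure = mean(unlist(lapply(recs, function(r) {
                 p <- r$pulses
                 p$pressure_mpa[p$phase %in% c("recording", "active", "ceased")]
               }))),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- list(arms = tab)

  all_recs <- unlist(arms, recursive = FALSE)
  pres <- unlist(lapply(all_recs, function(r) {
    p <- r$pulses
    p$pressure_mpa[p$phase %in% c("recording", "active", "ceased")]
  }))
  bb <- unlist(lapply(all_recs, function(r) {
    p <- r$pulses
    p$broadband_db[p$phase %in% c("recording", "active", "ceased")]
  }))
  if (length(unique(round(pres, 4))) >= 5 && sd(bb) > 0) {
    fit <- tryCatch(fit_tanh(pres, bb), error = function(e) NULL)
    if (!is.null(fit) && !fit$degenerate) {
      lower <- window_lower
      if (is.null(lower)) {
        kt <- vapply(all_recs, ktrans_surrogate, numeric(1))
        mp <- vapply(all_recs, function(r) {
          p <- r$pulses
          mean(p$pressure_mpa[p$phase %in% c("recording", "active", "ceased")])
        }, numeric(1))
        bg <- 0.010
        ok <- kt > bg + 2 * 0.002
        lower <- if (any(ok)) min(mp[ok]) else NA_real_
      }
      if (is.finite(lower) && lower < fit$c) {
        w <- treatment_window(lower, fit)
        out$window <- w
        out$tanh_fit <- fit
      }
    }
  }
  class(out) <- "experiment_summary"
  out
}
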