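#' Controller configuration
#'
#' The three controller kinds share the microbubble-kinetics gating state
#' machine (waiting -> recording -> active -> ceased) driven by the
#' tracker-pulse 4th harmonic: therapeutic control turns on at a +10 dB rise
#' over background, the clearance slope is recorded for at least
#' \code{min_record_s} (20 s in mice, 40 s in rats, to accommodate faster
#' rat kinetics), and control ceases -- holding the last pressure -- once the
#' fitted normalized 4th harmonic has decayed 20% from its maximum.
#'
#' \itemize{
#'   \item \code{OL}: constant commanded pressure with the 5% reactive drop
#'     on each detected broadband event.
#'   \item \code{CL}: multiplicative ramp toward a 7th-harmonic target level
#'     (median-of-\code{smooth_window} smoothing, +/-\code{deadband_db}
#'     deadband, factor \code{1 +/- ramp_delta} per pulse), plus the 5%
#'     reactive drop.
#'   \item \code{MLCL}: the CL law plus a predictive safety layer -- when the
#'     broadband predictor fires, the ramp is skipped and the same 5% drop is
#'     applied as if the event had already occurred; at most one safety
#'     action per pulse.
#' }
#'
#' @param kind "OL", "CL" or "MLCL".
#' @param target_db 7th-harmonic target level, dB (CL/MLCL).
#' @param fixed_pressure_mpa constant commanded pressure, MPa (OL only).
#' @param p_init,p_min,p_max initial and clamping pressures, MPa.
#' @param ramp_delta fractional pressure step per pulse (default 0.05).
#' @param safety_drop fractional drop on a safety action (default 0.05).
#' @param on_threshold_db tracker-on H4 rise over background, dB (default 10).
#' @param cease_decay fractional normalized-H4 decay that ceases control
#'   (default 0.20).
#' @param min_record_s minimum clearance-slope recording time, s.
#' @param deadband_db ramp deadband around the target, dB.
#' @param smooth_window moving-median window for the controlled level, pulses.
#' @param tracker_pressure_mpa commanded pressure while not operating, MPa.
#' @return A \code{controller_config} object.
#' @export
controller_config <- function(kind = c("CL", "OL", "MLCL"), target_db = 36,
                              fixed_pressure_mpa = NULL, p_init = 0.05,
                              p_min = 0.05, p_max = 0.40, ramp_delta = 0.05,
                              safety_drop = 0.05, on_threshold_db = 10,
                              cease_decay = 0.20, min_record_s = 20,
                              deadband_db = 1, smooth_window = 3,
                              tracker_pressure_mpa = 0.06) {
  kind <- match.arg(kind)
  if (!(p_min > 0 && p_min <= p_init && p_init <= p_max)) {
    stop("need 0 < p_min <= p_init <= p_max", call. = FALSE)
  }
  if (safety_drop <= 0 || safety_drop >= 1) {
    stop("safety_drop must be in (0, 1)", call. = FALSE)
  }
  if (kind == "OL" && is.null(fixed_pressure_mpa)) {
    stop("OL controllers need `fixed_pressure_mpa`", call. = FALSE)
  }
  structure(
    list(kind = kind, target_db = target_db,
         fixed_pressure_mpa = fixed_pressure_mpa, p_init = p_init,
         p_min = p_min, p_max = p_max, ramp_delta = ramp_delta,
         safety_drop = safety_drop, on_threshold_db = on_threshold_db,
         cease_decay = cease_decay, min_record_s = min_record_s,
         deadband_db = deadband_db, smooth_window = smooth_window,
         tracker_pressure_mpa = tracker_pressure_mpa),
    class = "controller_config"
  )
}

#' Build a controller
#'
#' @param config a \code{\link{controller_config}}.
#' @param model a trained \code{mlp_model} (required for kind "MLCL").
#' @param label optional label for logs (defaults to the kind, with the fixed
#'   pressure appended for OL).
#' @return A \code{mbfus_controller} object usable by
#'   \code{\link{simulate_run}}.
#' @export
make_controller <- function(config, model = NULL, label = NULL) {
  stopifnot(inherits(config, "controller_config"))
  if (config$kind == "MLCL" && !inherits(model, "mlp_model")) {
    stop("MLCL controllers need a trained `mlp_model`", call. = FALSE)
  }
  if (is.null(label)) {
    label <- config$kind
    if (config$kind == "OL") {
      label <- sprintf("OL(%.3g MPa)", config$fixed_pressure_mpa)
    }
  }
  structure(list(config = config, model = model, label = label),
            class = "mbfus_controller")
}

#' Initialize controller state for one sonication
#'
#' @param controller a \code{mbfus_controller}.
#' @param protocol the \code{\link{sonication_protocol}} being run.
#' @param subject the \code{\link{subject_model}}; the controller sees only
#'   the operator-known fields (target coordinates, tumor flag, species).
#' @return A \code{controller_state} object (phase "waiting").
#' @export
ctrl_init <- function(controller, protocol, subject) {
  cfg <- controller$config
  p0 <- if (cfg$kind == "OL") cfg$fixed_pressure_mpa else cfg$p_init
  structure(
    list(phase = "waiting", pressure = min(max(p0, cfg$p_min), cfg$p_max),
         background = NA_real_, bg_vals = numeric(0),
         on_time = NA_real_, max_h4 = -Inf,
         t_hist = numeric(0), h4_hist = numeric(0), h7_hist = numeric(0),
         slope = NA_real_, last_prediction = FALSE, cooldown = FALSE,
         target_x = subject$target_x, target_y = subject$target_y,
         tumor = subject$tumor),
    class = "controller_state"
  )
}

#' Microbubble-kinetics tracker update
#'
#' Advances the gating state machine from one tracker-pulse 4th-harmonic
#' measurement: waiting -> recording at a +10 dB rise over background;
#' recording -> active once \code{min_record_s} have elapsed (the clearance
#' slope is fit by least squares over a trailing window and updated in real
#' time); active -> ceased when the fitted normalized H4 has decayed by
#' \code{cease_decay} (20%) from its maximum, after which the pressure is
#' held. Phases never skip or revisit.
#'
#' @param state a \code{controller_state}.
#' @param h4_db tracker-pulse 4th-harmonic level, dB re baseline.
#' @param time_s time of the measurement, s (must be non-decreasing).
#' @param config a \code{\link{controller_config}}.
#' @return Updated \code{controller_state}.
#' @export
tracker_update <- function(state, h4_db, time_s, config) {
  if (!is.finite(h4_db)) stop("h4_db must be finite", call. = FALSE)
  if (length(state$t_hist) > 0 && time_s < max(state$t_hist)) {
    stop("time must be non-decreasing", call. = FALSE)
  }
  if (state$phase == "waiting") {
    bg <- if (is.na(state$background)) 0 else state$background
    if (h4_db >= bg + config$on_threshold_db) {
      state$phase <- "recording"
      state$on_time <- time_s
      state$max_h4 <- h4_db
      state$t_hist <- time_s
      state$h4_hist <- h4_db
    } else {
      state$bg_vals <- c(state$bg_vals, h4_db)
      state$background <- median(state$bg_vals)
    }
    return(state)
  }
  if (state$phase == "ceased") return(state)

  state$t_hist <- c(state$t_hist, time_s)
  state$h4_hist <- c(state$h4_hist, h4_db)
  # Running max over a 3-pulse median, not raw values: a max over noisy
  # levels overestimates the peak and biases the decay rule early.
  k3 <- length(state$h4_hist)
  h4_sm <- median(state$h4_hist[seq.int(max(1L, k3 - 2L), k3)])
  state$max_h4 <- max(state$max_h4, h4_sm)

  # Trailing least-squares fit of normalized H4 (clearance slope), updated
  # in real time; the trailing window avoids contamination by the wash-in.
  k <- min(length(state$t_hist), 15L)
  idx <- seq.int(length(state$t_hist) - k + 1L, length(state$t_hist))
  tt <- state$t_hist[idx]
  norm_h4 <- state$h4_hist[idx] / state$max_h4
  if (k >= 3L && var(tt) > 0) {
    b <- stats::cov(tt, norm_h4) / var(tt)
    a <- mean(norm_h4) - b * mean(tt)
    state$slope <- b
    fitted_now <- a + b * time_s
  } else {
    fitted_now <- norm_h4[length(norm_h4)]
  }

  if (state$phase == "recording" &&
      time_s - state$on_time >= config$min_record_s) {
    state$phase <- "active"
  }
  if (state$phase == "active" && fitted_now <= 1 - config$cease_decay) {
    state$phase <- "ceased"
  }
  state
}

clamp_p <- function(p, config) min(max(p, config$p_min), config$p_max)

#' Closed-loop pressure ramp step
#'
#' Multiplicative ramp toward the 7th-harmonic target: scale the pressure by
#' \code{1 + ramp_delta} when the smoothed level is below
#' \code{target - deadband}, by \code{1 - ramp_delta} when above
#' \code{target + deadband}, hold otherwise; clamped to
#' \code{[p_min, p_max]}.
#'
#' @param state a \code{controller_state} in an operating phase ("recording"
#'   or "active" -- the controller ramps throughout its minimum operation
#'   time).
#' @param level_db smoothed 7th-harmonic level, dB.
#' @param config a \code{\link{controller_config}}.
#' @return New commanded pressure, MPa.
#' @export
cl_step <- function(state, level_db, config) {
  if (!state$phase %in% c("recording", "active")) {
    stop("cl_step called outside an operating phase", call. = FALSE)
  }
  p <- state$pressure
  if (level_db < config$target_db - config$deadband_db) {
    p <- p * (1 + config$ramp_delta)
  } else if (level_db > config$target_db + config$deadband_db) {
    p <- p * (1 - config$ramp_delta)
  }
  clamp_p(p, config)
}

#' Reactive safety rule
#'
#' Reduce the commanded pressure by 5% upon a detected broadband emission
#' event (applied after any ramp decision on that pulse); identity otherwise.
#'
#' @param pressure commanded pressure, MPa.
#' @param event logical: broadband event detected.
#' @param config a \code{\link{controller_config}} (supplies
#'   \code{safety_drop} and \code{p_min}).
#' @return Adjusted pressure, MPa.
#' @export
reactive_safety <- function(pressure, event, config) {
  stopifnot(pressure > 0)
  if (isTRUE(event)) max(pressure * (1 - config$safety_drop), config$p_min)
  else pressure
}

mlcl_features <- function(state, frame) {
  mbk <- if (is.finite(state$max_h4) && state$max_h4 > 0) {
    min(max(frame$h4_db / state$max_h4, 0), 1)
  } else 0
  c(frame$ultraharmonic_db,
    pressure = frame$pressure_mpa,
    target_x = state$target_x, target_y = state$target_y,
    mb_kinetics = mbk, tumor = as.numeric(state$tumor))
}

#' ML-assisted closed-loop step
#'
#' Builds the 12-feature vector from the latest frame and the controller
#' state, queries the broadband predictor, and on a positive prediction skips
#' the ramp and applies the 5% safety drop exactly as if the event had
#' already occurred; otherwise defers to \code{\link{cl_step}}. A detected
#' event on the same pulse does not stack a second drop.
#'
#' @param state a \code{controller_state} in an operating phase.
#' @param frame the previous pulse's \code{\link{ae_frame}}.
#' @param model a trained \code{mlp_model}.
#' @param config a \code{\link{controller_config}}.
#' @return List with \code{pressure}, logical \code{prediction} and
#'   \code{safety_action} ("none", "reactive" or "predictive").
#' @export
mlcl_step <- function(state, frame, model, config) {
  if (!state$phase %in% c("recording", "active")) {
    stop("mlcl_step called outside an operating phase", call. = FALSE)
  }
  x <- mlcl_features(state, frame)
  pred <- mlp_predict(model, matrix(x, nrow = 1))$positive[1]
  event <- isTRUE(frame$is_event)
  if (pred || event) {
    p <- max(state$pressure * (1 - config$safety_drop), config$p_min)
    action <- if (pred) "predictive" else "reactive"
  } else {
    level <- smoothed_level(state)
    p <- cl_step(state, level, config)
    action <- "none"
  }
  list(pressure = clamp_p(p, config), prediction = pred,
       safety_action = action)
}

smoothed_level <- function(state) {
  k <- length(state$h7_hist)
  if (k == 0L) return(-Inf)
  median(state$h7_hist[seq.int(max(1L, k - 2L), k)])
}

#' One controller decision
#'
#' Single entry point used by \code{\link{simulate_run}}: feeds the previous
#' pulse's frame through the tracker state machine and produces the commanded
#' pressure for the current pulse under the configured control law.
#'
#' @param controller a \code{mbfus_controller}.
#' @param state a \code{controller_state}.
#' @param frame the previous pulse's \code{\link{ae_frame}}, or NULL at the
#'   first pulse.
#' @param pulse_index current pulse number.
#' @param time_s current time, s.
#' @return List with updated \code{state}, commanded \code{pressure} (MPa),
#'   the \code{phase} used for this pulse, logical \code{prediction} and
#'   \code{safety_action}.
#' @export
ctrl_step <- function(controller, state, frame, pulse_index, time_s) {
  cfg <- controller$config
  prediction <- FALSE
  action <- "none"

  if (!is.null(frame)) {
    state <- tracker_update(state, frame$h4_db, frame$time_s, cfg)
    if (state$phase %in% c("recording", "active")) {
      state$h7_hist <- c(state$h7_hist, frame$harmonic_db[["h7"]])
    }
  }

  if (state$phase == "waiting") {
    pressure <- cfg$tracker_pressure_mpa
  } else if (state$phase == "ceased") {
    pressure <- state$pressure
  } else if (is.null(frame)) {
    pressure <- state$pressure
  } else if (cfg$kind == "OL") {
    pressure <- reactive_safety(state$pressure, frame$is_event, cfg)
    if (frame$is_event) action <- "reactive"
    state$pressure <- pressure
  } else if (cfg$kind == "CL") {
    pressure <- cl_step(state, smoothed_level(state), cfg)
    pressure <- reactive_safety(pressure, frame$is_event, cfg)
    if (frame$is_event) action <- "reactive"
    # one-pulse cooldown: never ramp above the pressure of a safety pulse
    if (isTRUE(state$cooldown)) pressure <- min(pressure, state$pressure)
    state$pressure <- pressure
  } else { # MLCL
    res <- mlcl_step(state, frame, controller$model, cfg)
    pressure <- res$pressure
    prediction <- res$prediction
    action <- res$safety_action
    if (isTRUE(state$cooldown)) pressure <- min(pressure, state$pressure)
    state$pressure <- pressure
    state$last_prediction <- prediction
  }
  state$cooldown <- action != "none"

  list(state = state, pressure = pressure, phase = state$phase,
       prediction = prediction, safety_action = action)
}
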