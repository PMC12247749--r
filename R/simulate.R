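#' Sonication protocol
#'
#' Pulse-train description of one sonication: 0.5 MHz excitation, 10 ms
#' pulses at 1 Hz for 130 s, with an interleaved 60 kPa microbubble-tracking
#' pulse and an 11 ms passive record per pulse.
#'
#' @param f0 excitation frequency, MHz.
#' @param pulse_length_ms therapeutic pulse length, ms.
#' @param prf pulse repetition frequency, Hz.
#' @param duration_s sonication duration, s.
#' @param tracker_pressure_mpa constant tracking-pulse peak-negative
#'   pressure, MPa.
#' @param record_length_ms passive record length, ms.
#' @return A \code{sonication_protocol} object.
#' @export
sonication_protocol <- function(f0 = 0.5, pulse_length_ms = 10, prf = 1,
                                duration_s = 130, tracker_pressure_mpa = 0.06,
                                record_length_ms = 11) {
  n <- duration_s * prf
  if (abs(n - round(n)) > 1e-9) {
    stop("duration_s * prf must be an integer pulse count", call. = FALSE)
  }
  structure(
    list(f0 = f0, pulse_length_ms = pulse_length_ms, prf = prf,
         duration_s = duration_s, tracker_pressure_mpa = tracker_pressure_mpa,
         record_length_ms = record_length_ms, n_pulses = as.integer(round(n))),
    class = "sonication_protocol"
  )
}

#' Subject model
#'
#' Per-animal description used by the generator: species-dependent bolus
#' kinetics (rats clear microbubbles roughly twice as fast as mice under the
#' defaults), skull transmission, target coordinates and tumor status.
#'
#' @param species "mouse" or "rat".
#' @param tumor logical tumor flag for the sonicated target.
#' @param target_x,target_y target coordinates, mm (referenced to the eyes).
#' @param skull_transmission fraction of commanded pressure reaching the
#'   focus (0, 1]; default 1 for mouse, 0.8 for rat.
#' @param arrival_time_s bolus arrival time at the brain, s.
#' @param rise_tau_s rise time constant of the bolus wash-in, s.
#' @param clearance_tau_s exponential clearance time constant, s.
#' @param seed subject-level seed (per-target realization noise).
#' @return A \code{subject_model} object.
#' @export
subject_model <- function(species = c("mouse", "rat"), tumor = FALSE,
                          target_x = 1.5, target_y = 0,
                          skull_transmission = NULL, arrival_time_s = 8,
                          rise_tau_s = 6, clearance_tau_s = NULL,
                          seed = 1L) {
  species <- match.arg(species)
  if (is.null(skull_transmission)) {
    skull_transmission <- if (species == "mouse") 1.0 else 0.8
  }
  if (is.null(clearance_tau_s)) {
    clearance_tau_s <- if (species == "mouse") 180 else 90
  }
  if (skull_transmission <= 0 || skull_transmission > 1) {
    stop("skull_transmission must be in (0, 1]", call. = FALSE)
  }
  if (rise_tau_s >= clearance_tau_s) {
    stop("rise_tau_s must be smaller than clearance_tau_s", call. = FALSE)
  }
  structure(
    list(species = species, tumor = isTRUE(tumor), target_x = target_x,
         target_y = target_y, skull_transmission = skull_transmission,
         arrival_time_s = arrival_time_s, rise_tau_s = rise_tau_s,
         clearance_tau_s = clearance_tau_s, seed = as.integer(seed)),
    class = "subject_model"
  )
}

#' Generator parameters
#'
#' Shapes of the surrogate acoustic-emission model. The pressure to
#' 7th-harmonic dose-response is linear then plateaus:
#' \code{L7 = L_max * tanh(max(0, trans * p * conc - dose_threshold) /
#' slope_width)}. Defaults are calibrated so that 0.14 MPa at peak
#' concentration yields ~32 dB (the highest level in the linear regime) with
#' a ~37 dB plateau, and so that the marginal broadband-event rate of the
#' standard constant-pressure mouse corpus is 5-10% (see the methods
#' vignette for the calibration procedure).
#'
#' @param L_max harmonic plateau, dB.
#' @param p50 half-saturation pressure for the instability drive, MPa.
#' @param slope_width dose-response width, MPa.
#' @param dose_threshold minimum effective dose before harmonic response, MPa.
#' @param harmonic_scale length-7 multipliers (orders 2..8) of the
#'   7th-harmonic mean; reflects receiver sensitivity peaking near 3.5 MHz.
#' @param uh_scale length-7 multipliers (orders 1..7) for ultra-harmonic
#'   means relative to the 7th-harmonic mean.
#' @param uh_gain ultra-harmonic dB gain per unit latent instability.
#' @param h4_gain tracker-pulse 4th-harmonic rise at peak concentration, dB.
#' @param inst_leak,inst_gain,inst_noise_sd,inst_reset latent-instability
#'   accumulator: leak per pulse, gain on the pressure-concentration excess
#'   above \code{p50}, Gaussian step noise SD, and multiplicative partial
#'   reset after a broadband event.
#' @param event_beta0,event_beta_instability,event_beta_tumor,event_beta_bolus
#'   logistic coefficients for the per-pulse broadband event probability
#'   \code{plogis(b0 + b_i * instability + b_t * tumor + b_b * [conc > 0.7])}.
#' @param bb_event_mean_db mean excess above 6 dB of broadband levels on
#'   event pulses (exponential).
#' @param level_noise_sd per-band Gaussian level noise, dB.
#' @return A \code{generator_params} object.
#' @export
generator_params <- function(L_max = 37, p50 = 0.17, slope_width = 0.06,
                             dose_threshold = 0.06,
                             harmonic_scale = c(0.55, 0.65, 0.72, 0.80, 0.88,
                                                1.00, 0.95),
                             uh_scale = c(0.50, 0.42, 0.38, 0.35, 0.33,
                                          0.40, 0.38),
                             uh_gain = 5, h4_gain = 25,
                             inst_leak = 0.90, inst_gain = 7,
                             inst_noise_sd = 0.05, inst_reset = 0.8,
                             event_beta0 = -14.5, event_beta_instability = 16,
                             event_beta_tumor = 1.0, event_beta_bolus = 0.8,
                             bb_event_mean_db = 3, level_noise_sd = 1.5) {
  if (L_max <= 0 || slope_width <= 0) {
    stop("L_max and slope_width must be positive", call. = FALSE)
  }
  if (length(harmonic_scale) != 7L || length(uh_scale) != 7L) {
    stop("harmonic_scale and uh_scale must have length 7", call. = FALSE)
  }
  structure(
    list(L_max = L_max, p50 = p50, slope_width = slope_width,
         dose_threshold = dose_threshold, harmonic_scale = harmonic_scale,
         uh_scale = uh_scale, uh_gain = uh_gain, h4_gain = h4_gain,
         inst_leak = inst_leak, inst_gain = inst_gain,
         inst_noise_sd = inst_noise_sd, inst_reset = inst_reset,
         event_beta0 = event_beta0,
         event_beta_instability = event_beta_instability,
         event_beta_tumor = event_beta_tumor,
         event_beta_bolus = event_beta_bolus,
         bb_event_mean_db = bb_event_mean_db,
         level_noise_sd = level_noise_sd),
    class = "generator_params"
  )
}

#' Normalized bolus microbubble concentration
#'
#' Difference-of-exponentials wash-in/wash-out: zero before arrival, rise
#' with \code{rise_tau_s}, exponential clearance with \code{clearance_tau_s},
#' normalized so the global maximum is exactly 1.
#'
#' @param t time(s) since sonication start, s.
#' @param subject a \code{\link{subject_model}}.
#' @return Concentration fraction(s) in [0, 1].
#' @export
mb_concentration <- function(t, subject) {
  ta <- subject$arrival_time_s
  R <- subject$rise_tau_s
  C <- subject$clearance_tau_s
  tt <- pmax(0, t - ta)
  raw <- exp(-tt / C) - exp(-tt / R)
  t_peak <- (C * R / (C - R)) * log(C / R)
  peak <- exp(-t_peak / C) - exp(-t_peak / R)
  out <- ifelse(t < ta, 0, raw / peak)
  pmin(pmax(out, 0), 1)
}

#' Latent microbubble state
#'
#' @param concentration normalized concentration in [0, 1].
#' @param instability non-negative latent instability accumulator.
#' @return A \code{latent_state} object.
#' @export
latent_state <- function(concentration = 0, instability = 0) {
  if (concentration < 0 || concentration > 1 || instability < 0) {
    stop("invalid latent state", call. = FALSE)
  }
  structure(list(concentration = concentration, instability = instability),
            class = "latent_state")
}

#' Advance the latent instability accumulator by one pulse
#'
#' Leaky accumulation of the pressure-concentration excess above the
#' half-saturation pressure \code{p50}, plus small Gaussian noise; monotone
#' non-decreasing in pressure holding everything else fixed. This latent
#' state is what makes broadband events have learnable one-pulse-ahead
#' precursors (elevated ultra-harmonics).
#'
#' @param state a \code{\link{latent_state}} whose \code{concentration} is
#'   already set for the current pulse.
#' @param pressure effective at-focus peak-negative pressure, MPa (commanded
#'   pressure times skull transmission).
#' @param params a \code{\link{generator_params}}.
#' @param noise optional fixed Gaussian draw (standard normal) for
#'   reproducible substreams; if NULL one is drawn from the current RNG.
#' @return Updated \code{latent_state}.
#' @export
step_instability <- function(state, pressure, params, noise = NULL) {
  stopifnot(inherits(state, "latent_state"), pressure >= 0)
  if (is.null(noise)) noise <- rnorm(1)
  drive <- max(0, pressure * state$concentration - params$p50)
  inst <- params$inst_leak * state$instability + params$inst_gain * drive +
    params$inst_noise_sd * noise
  state$instability <- max(0, inst)
  state
}

#' Synthesize one per-pulse acoustic-emission frame
#'
#' Realizes the surrogate emission model at one pulse: a saturating
#' (linear-then-plateau) pressure to 7th-harmonic dose-response, scaled
#' replicas for the other harmonics, ultra-harmonics that additionally rise
#' with the latent instability, a concentration-driven tracker 4th harmonic,
#' and a Bernoulli broadband event whose log-odds are linear in instability,
#' tumor status and a high-transient-concentration (bolus first-pass) flag.
#' On an event the broadband level is at least 6 dB and the instability
#' partially resets.
#'
#' @param pressure commanded peak-negative pressure, MPa.
#' @param state a \code{\link{latent_state}} for this pulse (instability
#'   already stepped).
#' @param subject a \code{\link{subject_model}}.
#' @param params a \code{\link{generator_params}}.
#' @param pulse_index,time_s frame bookkeeping.
#' @param noise optional list of fixed draws (\code{level}: 15 standard
#'   normals for h2..h8, uh1..uh7, h4; \code{u_event}, \code{u_bb}: uniforms)
#'   for reproducible substreams; drawn from the current RNG when NULL.
#' @return An \code{\link{ae_frame}}; the updated latent state (with
#'   post-event reset applied) is attached as attribute \code{"state"}, and
#'   the event probability as attribute \code{"event_prob"}.
#' @export
synth_frame <- function(pressure, state, subject, params,
                        pulse_index = 1L, time_s = pulse_index - 1,
                        noise = NULL) {
  stopifnot(pressure >= 0, inherits(state, "latent_state"))
  if (is.null(noise)) {
    noise <- list(level = rnorm(15), u_event = runif(1), u_bb = runif(1))
  }
  conc <- state$concentration
  p_eff <- subject$skull_transmission * pressure
  eff_dose <- max(0, p_eff * conc - params$dose_threshold)
  h7_mean <- params$L_max * tanh(eff_dose / params$slope_width)

  h_mean <- params$harmonic_scale * h7_mean
  uh_mean <- params$uh_scale * h7_mean + params$uh_gain * state$instability
  h4_mean <- params$h4_gain * conc

  sd <- params$level_noise_sd
  harm <- h_mean + sd * noise$level[1:7]
  uh <- uh_mean + sd * noise$level[8:14]
  h4 <- h4_mean + sd * noise$level[15]

  p_event <- plogis(params$event_beta0 +
                      params$event_beta_instability * state$instability +
                      params$event_beta_tumor * as.numeric(subject$tumor) +
                      params$event_beta_bolus * as.numeric(conc > 0.7))
  is_event <- noise$u_event < p_event
  if (is_event) {
    bb <- 6 + stats::qexp(noise$u_bb, rate = 1 / params$bb_event_mean_db)
    state$instability <- state$instability * params$inst_reset
  } else {
    bb <- min(stats::qnorm(noise$u_bb, mean = 0, sd = sd), 5.5)
  }

  fr <- ae_frame(pulse_index = pulse_index, time_s = time_s,
                 pressure_mpa = pressure, harmonic_db = harm,
                 ultraharmonic_db = uh, h4_db = h4, broadband_db = bb)
  attr(fr, "state") <- state
  attr(fr, "event_prob") <- p_event
  fr
}

pulse_log <- function(n) {
  list(
    num = matrix(NA_real_, n, 20L,
                 dimnames = list(NULL, c("time_s", "pressure_mpa",
                                         paste0("h", 2:8), paste0("uh", 1:7),
                                         "h4_db", "broadband_db",
                                         "concentration", "instability"))),
    is_event = integer(n), prediction = integer(n),
    phase = character(n), safety_action = character(n)
  )
}

log_pulse <- function(log, t, frame, phase, prediction, safety_action,
                      latent) {
  log$num[t, ] <- c(frame$time_s, frame$pressure_mpa, frame$harmonic_db,
                    frame$ultraharmonic_db, frame$h4_db, frame$broadband_db,
                    latent$concentration, latent$instability)
  log$is_event[t] <- as.integer(frame$is_event)
  log$prediction[t] <- as.integer(prediction)
  log$phase[t] <- phase
  log$safety_action[t] <- safety_action
  log
}

log_to_frame <- function(log) {
  n <- nrow(log$num)
  df <- data.frame(pulse_index = seq_len(n), log$num[, 1:2, drop = FALSE],
                   phase = log$phase, stringsAsFactors = FALSE)
  df <- cbind(df[c("pulse_index", "time_s", "phase", "pressure_mpa")],
              as.data.frame(log$num[, 3:18, drop = FALSE]),
              data.frame(is_event = log$is_event, prediction = log$prediction,
                         safety_action = log$safety_action,
                         log$num[, 19:20, drop = FALSE],
                         stringsAsFactors = FALSE))
  df
}

#' Simulate one full sonication under a controller
#'
#' Runs the per-pulse loop for one 130 s sonication: the controller proposes
#' a commanded pressure from the previous pulse's frame, the generator
#' realizes the acoustic emissions, and the frame is fed back. Randomness is
#' split into named substreams (kinetics, noise, events) derived from
#' \code{seed}, so runs are bit-reproducible and adding a consumer to one
#' substream does not shift the others.
#'
#' @param protocol a \code{\link{sonication_protocol}}.
#' @param subject a \code{\link{subject_model}}.
#' @param controller a controller from \code{\link{make_controller}}.
#' @param params a \code{\link{generator_params}}.
#' @param seed integer root seed for this run.
#' @return A \code{sonication_record}: list with the configuration echo, the
#'   controller label, and \code{pulses}, a data frame with one row per pulse
#'   (pressures, band levels, event flags, controller phase, predictions,
#'   safety actions and the latent diagnostics).
#' @export
simulate_run <- function(protocol, subject, controller, params, seed = 1L) {
  n <- protocol$n_pulses
  noise_draws <- with_seed(substream_seed(seed, "noise"), list(
    level = matrix(rnorm(n * 15L), nrow = n),
    u_bb = runif(n),
    inst = rnorm(n)
  ))
  u_event <- with_seed(substream_seed(seed, "events"), runif(n))
  kin <- with_seed(substream_seed(seed, "kinetics"), list(
    trans_jitter = exp(rnorm(1, 0, 0.05))
  ))
  subj <- subject
  subj$skull_transmission <- subject$skull_transmission * kin$trans_jitter

  cstate <- ctrl_init(controller, protocol, subject)
  latent <- latent_state(0, 0)
  prev_frame <- NULL
  log <- pulse_log(n)

  for (t in seq_len(n)) {
    time_s <- (t - 1) / protocol$prf
    dec <- tryCatch(
      ctrl_step(controller, cstate, prev_frame, t, time_s),
      error = function(e) {
        stop("controller failed at pulse ", t, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    cstate <- dec$state
    latent$concentration <- mb_concentration(time_s, subject)
    latent <- step_instability(latent, subj$skull_transmission * dec$pressure,
                               params, noise = noise_draws$inst[t])
    frame <- synth_frame(dec$pressure, latent, subj, params,
                         pulse_index = t, time_s = time_s,
                         noise = list(level = noise_draws$level[t, ],
                                      u_event = u_event[t],
                                      u_bb = noise_draws$u_bb[t]))
    latent <- attr(frame, "state")
    log <- log_pulse(log, t, frame, dec$phase, dec$prediction,
                     dec$safety_action, latent)
    prev_frame <- frame
  }

  structure(
    list(protocol = protocol, subject = subject, params = params,
         controller_label = controller$label, seed = as.integer(seed),
         pulses = log_to_frame(log)),
    class = "sonication_record"
  )
}

#' Synthetic vascular-permeability surrogate
#'
#' A saturating, monotone function of the cumulative 7th-harmonic dose of a
#' sonication, standing in for the DCE-MRI volume transfer constant K_trans
#' (which is out of scope). Linear in the dose far below saturation;
#' deterministic given the record and the subject seed.
#'
#' @param record a \code{sonication_record}.
#' @param floor background permeability (no-dose value).
#' @param amplitude saturated increase above the floor.
#' @param dose50 cumulative dose (dB-pulse units) at half saturation.
#' @param noise_sd lognormal SD of the seeded per-subject biological jitter.
#' @return Scalar surrogate permeability (1/min-like arbitrary units).
#' @export
ktrans_surrogate <- function(record, floor = 0.010, amplitude = 0.060,
                             dose50 = 4000, noise_sd = 0.10) {
  stopifnot(inherits(record, "sonication_record"))
  dose <- sum(pmax(0, record$pulses$h7))
  jitter <- with_seed(substream_seed(record$subject$seed, "ktrans"),
                      exp(rnorm(1, 0, noise_sd)))
  floor + amplitude * (dose / (dose + dose50)) * jitter
}
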