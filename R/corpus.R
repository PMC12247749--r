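#' Simulate a constant-pressure training corpus
#'
#' Emulates how the broadband predictor's training data are collected:
#' constant-pressure (open-loop) sonications across many targets with varied
#' pressures, target coordinates and tumor status. Pressures are drawn
#' uniformly over \code{pressure_range}, the tumor flag with probability
#' \code{tumor_fraction}.
#'
#' @param n_runs number of sonications.
#' @param seed integer root seed (per-run seeds are derived from it).
#' @param protocol a \code{\link{sonication_protocol}}.
#' @param params a \code{\link{generator_params}}.
#' @param species "mouse" or "rat".
#' @param pressure_range range of constant commanded pressures, MPa.
#' @param tumor_fraction fraction of tumor-bearing targets.
#' @return List of \code{sonication_record}.
#' @export
simulate_training_corpus <- function(n_runs, seed = 1L,
                                     protocol = sonication_protocol(),
                                     params = generator_params(),
                                     species = "mouse",
                                     pressure_range = c(0.12, 0.40),
                                     tumor_fraction = 0.3) {
  draws <- with_seed(substream_seed(seed, "corpus"), list(
    pressure = runif(n_runs, pressure_range[1], pressure_range[2]),
    tumor = runif(n_runs) < tumor_fraction,
    tx = runif(n_runs, -3, 3),
    ty = runif(n_runs, -3, 3),
    arrival = runif(n_runs, 5, 12)
  ))
  min_rec <- if (species == "mouse") 20 else 40
  lapply(seq_len(n_runs), function(i) {
    subj <- subject_model(species = species, tumor = draws$tumor[i],
                          target_x = draws$tx[i], target_y = draws$ty[i],
                          arrival_time_s = draws$arrival[i],
                          seed = seed + i)
    ctrl <- make_controller(controller_config(
      kind = "OL", fixed_pressure_mpa = draws$pressure[i],
      p_min = 0.05, p_max = 0.40, min_record_s = min_rec,
      tracker_pressure_mpa = protocol$tracker_pressure_mpa
    ))
    simulate_run(protocol, subj, ctrl, params, seed = seed * 1000L + i)
  })
}

#' Run one multi-arm controller comparison
#'
#' Simulates matched sonications under the four benchmark arms -- open loop
#' at the ML-CL average and maximum pressures, the plain closed loop, and the
#' ML-assisted closed loop -- over the same subjects and seeds.
#'
#' @param n_runs sonications per arm.
#' @param model trained \code{mlp_model} for the ML-CL arm.
#' @param target_db closed-loop 7th-harmonic target level, dB.
#' @param p_avg,p_max open-loop pressures, MPa (the ML-CL operating average
#'   and maximum; see \code{\link{mlcl_operating_pressures}}).
#' @param seed integer root seed.
#' @param protocol,params,species as in
#'   \code{\link{simulate_training_corpus}}.
#' @param tumor_fraction fraction of tumor-bearing targets.
#' @return Named list of arms ("OL_PAvg", "OL_PMax", "CL", "MLCL"), each a
#'   list of \code{sonication_record}.
#' @export
run_experiment_arms <- function(n_runs, model, target_db = 36,
                                p_avg = 0.25, p_max = 0.33, seed = 1L,
                                protocol = sonication_protocol(),
                                params = generator_params(),
                                species = "mouse", tumor_fraction = 0) {
  min_rec <- if (species == "mouse") 20 else 40
  mk_cfg <- function(kind, fp = NULL) {
    controller_config(kind = kind, target_db = target_db,
                      fixed_pressure_mpa = fp, min_record_s = min_rec,
                      tracker_pressure_mpa = protocol$tracker_pressure_mpa)
  }
  ctrls <- list(
    OL_PAvg = make_controller(mk_cfg("OL", p_avg)),
    OL_PMax = make_controller(mk_cfg("OL", p_max)),
    CL = make_controller(mk_cfg("CL")),
    MLCL = make_controller(mk_cfg("MLCL"), model = model)
  )
  draws <- with_seed(substream_seed(seed, "arms"), list(
    tumor = runif(n_runs) < tumor_fraction,
    tx = runif(n_runs, -3, 3),
    ty = runif(n_runs, -3, 3),
    arrival = runif(n_runs, 5, 12)
  ))
  lapply(ctrls, function(ctrl) {
    lapply(seq_len(n_runs), function(i) {
      subj <- subject_model(species = species, tumor = draws$tumor[i],
                            target_x = draws$tx[i], target_y = draws$ty[i],
                            arrival_time_s = draws$arrival[i],
                            seed = seed + i)
      simulate_run(protocol, subj, ctrl, params, seed = seed * 1000L + i)
    })
  })
}

#' Operating average and maximum pressure of ML-CL runs
#'
#' The constant pressures of the open-loop benchmark arms are defined as the
#' mean and maximum commanded pressure of ML-CL runs during their operating
#' (recording/active/ceased) phases.
#'
#' @param records list of ML-CL \code{sonication_record}.
#' @return List with \code{p_avg} and \code{p_max}, MPa.
#' @export
mlcl_operating_pressures <- function(records) {
  pres <- unlist(lapply(records, function(r) {
    p <- r$pulses
    p$pressure_mpa[p$phase %in% c("recording", "active", "ceased")]
  }))
  list(p_avg = mean(pres), p_max = max(pres))
}
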