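mk_state <- function(ctrl, phase = "active", pressure = 0.2) {
  st <- ctrl_init(ctrl, sonication_protocol(), subject_model())
  st$phase <- phase
  st$pressure <- pressure
  st
}

test_that("tracker turns on at a +10 dB H4 rise over background", {
  cfg <- controller_config(kind = "CL")
  ctrl <- make_controller(cfg)
  st <- ctrl_init(ctrl, sonication_protocol(), subject_model())
  h4 <- c(rep(0.2, 11), 10.2, 12, 14)
  for (i in seq_along(h4)) {
    st <- tracker_update(st, h4[i], i - 1, cfg)
    if (i < 12) expect_equal(st$phase, "waiting")
  }
  expect_equal(st$phase, "recording")
  expect_equal(st$on_time, 11)
})

test_that("a flat trace never leaves the waiting phase", {
  cfg <- controller_config(kind = "CL")
  st <- mk_state(make_controller(cfg), "waiting", cfg$p_init)
  for (i in 1:130) st <- tracker_update(st, 2 + 0.01 * sin(i), i - 1, cfg)
  expect_equal(st$phase, "waiting")
})

test_that("control ceases at 20% normalized H4 decay and time is checked", {
  cfg <- controller_config(kind = "CL", min_record_s = 5)
  ctrl <- make_controller(cfg)
  st <- ctrl_init(ctrl, sonication_protocol(), subject_model())
  # rise, plateau at 25 dB, then clean linear decay
  h4 <- c(rep(0, 5), seq(12, 25, length.out = 6), rep(25, 10),
          seq(25, 18, length.out = 30))
  phases <- character(length(h4))
  for (i in seq_along(h4)) {
    st <- tracker_update(st, h4[i], i - 1, cfg)
    phases[i] <- st$phase
  }
  expect_equal(st$phase, "ceased")
  first_ceased <- min(which(phases == "ceased"))
  # 20% of the 25 dB max is 20 dB, reached ~ 5/7 through the decay ramp
  expect_gt(h4[first_ceased - 1], 19)
  expect_lt(h4[first_ceased], 21.5)
  # phases never skip or revisit
  idx <- match(phases, c("waiting", "recording", "active", "ceased"))
  expect_true(all(diff(idx) >= 0))
  expect_true(all(diff(idx) <= 1))

  expect_error(tracker_update(st, 10, 0, cfg), "non-decreasing")
})

test_that("the closed-loop ramp law is multiplicative with a deadband", {
  cfg <- controller_config(kind = "CL", target_db = 36, p_init = 0.05)
  ctrl <- make_controller(cfg)
  st <- mk_state(ctrl, "active", 0.2)
  expect_equal(cl_step(st, 31, cfg), 0.2 * 1.05)   # 5 dB below target
  expect_equal(cl_step(st, 36.5, cfg), 0.2)        # inside the deadband
  expect_equal(cl_step(st, 40, cfg), 0.2 * 0.95)   # above target
  st$phase <- "waiting"
  expect_error(cl_step(st, 31, cfg), "operating")

  # 30 consecutive below-target pulses: closed-form compound growth
  cfg2 <- controller_config(kind = "CL", p_init = 0.05, p_max = 0.33)
  st2 <- mk_state(make_controller(cfg2), "active", 0.05)
  for (i in 1:30) st2$pressure <- cl_step(st2, 20, cfg2)
  expect_equal(st2$pressure, min(0.05 * 1.05^30, 0.33))
})

test_that("the reactive safety rule drops exactly 5% per event", {
  cfg <- controller_config(kind = "OL", fixed_pressure_mpa = 0.2)
  expect_equal(reactive_safety(0.20, TRUE, cfg), 0.19)
  expect_equal(reactive_safety(0.20, FALSE, cfg), 0.20)
  expect_equal(reactive_safety(reactive_safety(0.20, TRUE, cfg), TRUE, cfg),
               0.20 * 0.95^2)
  # clamped at p_min
  expect_equal(reactive_safety(0.0501, TRUE, cfg), 0.05)
})

test_that("ML-CL overrides the ramp on a positive prediction", {
  cfg <- controller_config(kind = "MLCL", target_db = 36)
  always <- constant_model(10)   # prob ~ 1
  never <- constant_model(-10)   # prob ~ 0
  ctrl <- make_controller(cfg, model = always)
  st <- mk_state(ctrl, "active", 0.26)
  st$max_h4 <- 25
  frame <- ae_frame(20, 19, 0.26, rep(30, 7), rep(15, 7), 20, 0)

  res <- mlcl_step(st, frame, always, cfg)
  expect_true(res$prediction)
  expect_equal(res$pressure, 0.26 * 0.95)
  expect_equal(res$safety_action, "predictive")

  # negative prediction defers exactly to the closed-loop law
  st$h7_hist <- c(30, 30, 30)
  res2 <- mlcl_step(st, frame, never, cfg)
  expect_false(res2$prediction)
  expect_equal(res2$pressure, cl_step(st, 30, cfg))
  expect_equal(res2$safety_action, "none")

  # prediction and a detected event on the same pulse: one drop, not two
  frame_ev <- ae_frame(20, 19, 0.26, rep(30, 7), rep(15, 7), 20, 8)
  res3 <- mlcl_step(st, frame_ev, always, cfg)
  expect_equal(res3$pressure, 0.26 * 0.95)

  # a real event with a negative prediction still reacts
  res4 <- mlcl_step(st, frame_ev, never, cfg)
  expect_equal(res4$pressure, 0.26 * 0.95)
  expect_equal(res4$safety_action, "reactive")
})

test_that("open loop holds pressure and reacts to events from the next pulse", {
  cfg <- controller_config(kind = "OL", fixed_pressure_mpa = 0.3)
  ctrl <- make_controller(cfg)
  st <- mk_state(ctrl, "waiting", 0.3)
  mk_frame <- function(t, h4, ev = FALSE) {
    ae_frame(t, t - 1, 0.3, rep(20, 7), rep(10, 7), h4,
             if (ev) 8 else 0)
  }
  pres <- numeric(40)
  frame <- NULL
  for (t in 1:40) {
    dec <- ctrl_step(ctrl, st, frame, t, t - 1)
    st <- dec$state
    pres[t] <- dec$pressure
    frame <- mk_frame(t, h4 = if (t >= 5) 20 else 0, ev = (t == 20))
  }
  expect_true(all(pres[7:20] == 0.3))
  expect_true(all(pres[22:40] == 0.3 * 0.95))
})

test_that("controller invariants hold over simulated runs", {
  model <- constant_model(-10)
  cfgs <- list(
    controller_config(kind = "OL", fixed_pressure_mpa = 0.33),
    controller_config(kind = "CL", target_db = 36),
    controller_config(kind = "MLCL", target_db = 36)
  )
  for (cfg in cfgs) {
    ctrl <- make_controller(cfg, model = if (cfg$kind == "MLCL") model)
    for (s in 1:5) {
      rec <- simulate_run(sonication_protocol(), subject_model(seed = s),
                          ctrl, generator_params(), seed = 200 + s)
      p <- rec$pulses
      op <- p$phase != "waiting"
      expect_true(all(p$pressure_mpa[op] >= cfg$p_min - 1e-12))
      expect_true(all(p$pressure_mpa <= cfg$p_max + 1e-12))
      # a safety action never precedes a pressure increase
      act <- which(p$safety_action != "none" & p$phase == "active")
      act <- act[act < nrow(p)]
      expect_true(all(p$pressure_mpa[act + 1] <= p$pressure_mpa[act] + 1e-12))
      idx <- match(p$phase, c("waiting", "recording", "active", "ceased"))
      expect_true(all(diff(idx) >= 0 & diff(idx) <= 1))
    }
  }
})
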