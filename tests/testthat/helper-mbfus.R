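# Shared fixture builders; everything is generated in code at test time.

flat_spectrum <- function(value = 1, f0 = 0.5, pulse_index = 1L) {
  grid <- default_grid()
  pulse_spectrum(grid, rep(value, length(grid)), pulse_index = pulse_index)
}

flat_baselines <- function(value = 1, f0 = 0.5) {
  setNames(rep(value, 15), names(standard_bands(f0)))
}

# Boost the power of one band's bins by `factor` on a flat spectrum.
boosted_spectrum <- function(band, factor, base = 1, f0 = 0.5) {
  grid <- default_grid()
  power <- rep(base, length(grid))
  hw <- band$half_width_khz / 1000
  idx <- abs(grid - band$center_mhz) <= hw
  power[idx] <- base * factor
  pulse_spectrum(grid, power)
}

# Minimal hand-built sonication record for dataset tests.
fake_record <- function(n = 10, event_pulses = integer(0), tumor = FALSE,
                        pressure = 0.2) {
  pulses <- data.frame(
    pulse_index = seq_len(n), time_s = seq_len(n) - 1, phase = "active",
    pressure_mpa = pressure,
    matrix(seq_len(n * 7) / 10, n, 7, dimnames = list(NULL, paste0("h", 2:8))),
    matrix(seq_len(n * 7) / 20, n, 7, dimnames = list(NULL, paste0("uh", 1:7))),
    h4_db = seq(10, 25, length.out = n), broadband_db = 0,
    is_event = as.integer(seq_len(n) %in% event_pulses),
    prediction = 0L, safety_action = "none",
    concentration = 0.5, instability = 0.1, stringsAsFactors = FALSE
  )
  structure(
    list(protocol = sonication_protocol(),
         subject = subject_model(tumor = tumor, seed = 7L),
         params = generator_params(), controller_label = "fake", seed = 1L,
         pulses = pulses),
    class = "sonication_record"
  )
}

# A 12-feature mlp_model with hand-set weights (for threshold/override tests).
constant_model <- function(output_logit) {
  structure(
    list(W1 = matrix(0, 12, 10), b1 = rep(0, 10), w2 = rep(0, 10),
         b2 = output_logit, center = rep(0, 12), scale = rep(1, 12),
         threshold = 0.5, feature_names = feature_names(12), hidden = 10L,
         history = numeric(0), stop_reason = "manual",
         config = list(seed = 0L)),
    class = "mlp_model"
  )
}

# Separable toy dataset: 2 informative of 12 features; class centers are
# ~5.7 sigma apart (~3 sigma margin per class from the boundary).
separable_toy <- function(n = 400, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, feature_names(12)))
  X[, 1] <- X[, 1] + 4 * y
  X[, 2] <- X[, 2] - 4 * y
  list(X = X, y = y)
}

# Cached small generator corpus shared across test files (built once).
.mbfus_cache <- new.env(parent = emptyenv())
small_corpus <- function(n_runs = 60, seed = 101) {
  key <- sprintf("corpus_%d_%d", n_runs, seed)
  if (is.null(.mbfus_cache[[key]])) {
    .mbfus_cache[[key]] <- simulate_training_corpus(n_runs, seed = seed)
  }
  .mbfus_cache[[key]]
}
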