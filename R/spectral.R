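#' Spectral bands for harmonic, ultra-harmonic and broadband emissions
#'
#' Frequency bands are half-integer multiples of the excitation frequency
#' \code{f0}: even half-orders give harmonics (n = 4 is the 2nd harmonic at
#' 2 f0), odd half-orders give ultra-harmonics (n = 3 is the 1st
#' ultra-harmonic at 1.5 f0). Each band spans \code{center +/- half_width}.
#' The broadband (inertial-cavitation) bin sits between harmonic lines at
#' 7.22 f0, closest to the passive cavitation detector's 3.5 MHz peak
#' sensitivity in the reference 0.5 MHz system.
#'
#' @param half_order integer n >= 2; the band center is 0.5 * n * f0.
#' @param f0 excitation frequency in MHz.
#' @param half_width half-width of the band in kHz (default 0.3).
#' @return A \code{band} object: list with \code{center_mhz},
#'   \code{half_width_khz} and \code{kind} ("harmonic" or "ultraharmonic").
#' @examples
#' make_band(14, 0.5)      # 7th harmonic, 3.5 MHz
#' make_band(3, 0.5)       # 1st ultra-harmonic, 0.75 MHz
#' @export
make_band <- function(half_order, f0, half_width = 0.3) {
  if (!is.numeric(half_order) || length(half_order) != 1L ||
      half_order < 2 || half_order != round(half_order)) {
    stop("`half_order` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0) {
    stop("`f0` must be a single positive frequency in MHz", call. = FALSE)
  }
  if (!is.numeric(half_width) || half_width <= 0) {
    stop("`half_width` must be positive (kHz)", call. = FALSE)
  }
  structure(
    list(
      center_mhz = 0.5 * half_order * f0,
      half_width_khz = half_width,
      kind = if (half_order %% 2 == 0) "harmonic" else "ultraharmonic"
    ),
    class = "band"
  )
}

#' Broadband detection band
#'
#' The between-harmonics bin at 7.22 f0 used to score inertial-cavitation
#' (broadband) emission strength.
#'
#' @inheritParams make_band
#' @return A \code{band} object with \code{kind = "broadband"}.
#' @export
broadband_band <- function(f0, half_width = 0.3) {
  b <- make_band(2, f0, half_width)
  b$center_mhz <- 7.22 * f0
  b$kind <- "broadband"
  b
}

#' The full 15-band set used by the feature extractor
#'
#' Harmonics 2--8 (names \code{h2}..\code{h8}), ultra-harmonics 1--7 at
#' 1.5 f0 .. 7.5 f0 (names \code{uh1}..\code{uh7}), and the broadband bin
#' (\code{broadband}).
#'
#' @inheritParams make_band
#' @return Named list of 15 \code{band} objects.
#' @export
standard_bands <- function(f0 = 0.5, half_width = 0.3) {
  bands <- list()
  for (k in 2:8) bands[[paste0("h", k)]] <- make_band(2L * k, f0, half_width)
  for (k in 1:7) bands[[paste0("uh", k)]] <- make_band(2L * k + 1L, f0, half_width)
  bands[["broadband"]] <- broadband_band(f0, half_width)
  bands
}

#' Per-pulse power spectrum container
#'
#' Carrier for the FFT of one recorded pulse (11 ms record by default, so
#' ~90.9 Hz bin spacing). The high-pass cutoff of the receive chain is
#' applied by zeroing bins below \code{highpass_mhz}.
#'
#' @param frequency_mhz strictly increasing, uniformly spaced grid (MHz).
#' @param power linear power per bin, finite and non-negative.
#' @param pulse_index integer pulse number >= 1.
#' @param highpass_mhz receive high-pass cutoff (default 0.6 MHz); bins below
#'   are zeroed. Use 0 to disable.
#' @return A \code{pulse_spectrum} object.
#' @export
pulse_spectrum <- function(frequency_mhz, power, pulse_index = 1L,
                           highpass_mhz = 0.6) {
  if (length(frequency_mhz) != length(power)) {
    stop("frequency and power must have equal length", call. = FALSE)
  }
  d <- diff(frequency_mhz)
  if (any(d <= 0) || (length(d) > 1 && max(abs(d - d[1])) > 1e-9 * d[1])) {
    stop("frequency grid must be strictly increasing and uniform", call. = FALSE)
  }
  if (any(!is.finite(power)) || any(power < 0)) {
    stop("power must be finite and non-negative", call. = FALSE)
  }
  if (highpass_mhz > 0) power[frequency_mhz < highpass_mhz] <- 0
  structure(
    list(frequency_mhz = frequency_mhz, power = power,
         pulse_index = as.integer(pulse_index)),
    class = "pulse_spectrum"
  )
}

#' Default frequency grid for an 11 ms record
#'
#' @param record_length_ms record duration in ms (default 11; sets the
#'   ~1/T bin spacing).
#' @param f_max_mhz top of the grid (default 4.5 MHz, above the 8th harmonic
#'   of a 0.5 MHz system).
#' @return Numeric vector of bin frequencies in MHz.
#' @export
default_grid <- function(record_length_ms = 11, f_max_mhz = 4.5) {
  df_mhz <- 1e-3 / record_length_ms # 1/T in MHz
  seq(0, f_max_mhz, by = df_mhz)
}

in_band_idx <- function(spectrum, band) {
  hw_mhz <- band$half_width_khz / 1000
  which(abs(spectrum$frequency_mhz - band$center_mhz) <= hw_mhz)
}

#' Calibrated band level in dB above baseline
#'
#' The band statistic is the mean in-band linear power (stable under changes
#' of grid resolution), referenced to a per-band baseline power:
#' \code{10 * log10(mean(in-band power) / baseline_power)}.
#'
#' @param spectrum a \code{pulse_spectrum}.
#' @param band a \code{band}.
#' @param baseline_power positive linear baseline power for this band.
#' @return Band level in dB re baseline.
#' @export
band_level_db <- function(spectrum, band, baseline_power) {
  if (!is.numeric(baseline_power) || length(baseline_power) != 1L ||
      !is.finite(baseline_power) || baseline_power <= 0) {
    stop("`baseline_power` must be a single positive number", call. = FALSE)
  }
  idx <- in_band_idx(spectrum, band)
  if (length(idx) == 0L) {
    stop(sprintf("band at %.4f MHz does not overlap the frequency grid",
                 band$center_mhz), call. = FALSE)
  }
  10 * log10(mean(spectrum$power[idx]) / baseline_power)
}

#' Broadband event rule
#'
#' A pulse is a broadband (inertial cavitation) event when its broadband
#' level is at least 6 dB above baseline noise. The tie at exactly 6.0 dB
#' counts as an event; the same rule is used everywhere in the package.
#'
#' @param broadband_db broadband level(s), dB re baseline.
#' @return Logical vector.
#' @export
detect_broadband <- function(broadband_db) {
  if (any(is.na(broadband_db)) || any(!is.finite(broadband_db))) {
    stop("`broadband_db` must be finite", call. = FALSE)
  }
  broadband_db >= 6.0
}

#' Per-pulse feature frame
#'
#' Canonical per-pulse record: harmonic levels for orders 2--8,
#' ultra-harmonic levels for orders 1--7 (1.5 f0 .. 7.5 f0), the tracker-pulse
#' 4th-harmonic level used for microbubble-kinetics gating, the broadband
#' level and the 6 dB event flag. All levels are dB re baseline.
#'
#' @param pulse_index integer >= 1.
#' @param time_s pulse time in seconds.
#' @param pressure_mpa commanded peak-negative pressure, MPa.
#' @param harmonic_db numeric length 7 (orders 2..8).
#' @param ultraharmonic_db numeric length 7 (orders 1..7).
#' @param h4_db 4th-harmonic tracking level, dB.
#' @param broadband_db broadband bin level, dB.
#' @return An \code{ae_frame} object; \code{is_event} is set by
#'   \code{\link{detect_broadband}}.
#' @export
ae_frame <- function(pulse_index, time_s, pressure_mpa, harmonic_db,
                     ultraharmonic_db, h4_db, broadband_db) {
  if (length(harmonic_db) != 7L || length(ultraharmonic_db) != 7L) {
    stop("harmonic_db and ultraharmonic_db must each have 7 entries",
         call. = FALSE)
  }
  vals <- c(harmonic_db, ultraharmonic_db, h4_db, broadband_db, pressure_mpa)
  if (any(!is.finite(vals))) stop("all frame levels must be finite", call. = FALSE)
  structure(
    list(
      pulse_index = as.integer(pulse_index), time_s = time_s,
      pressure_mpa = pressure_mpa,
      harmonic_db = setNames(as.numeric(harmonic_db), paste0("h", 2:8)),
      ultraharmonic_db = setNames(as.numeric(ultraharmonic_db), paste0("uh", 1:7)),
      h4_db = h4_db, broadband_db = broadband_db,
      is_event = detect_broadband(broadband_db)
    ),
    class = "ae_frame"
  )
}

#' Extract a calibrated feature frame from a pulse spectrum
#'
#' Converts a supplied (or simulated) power spectrum into the 15 calibrated
#' band levels of an \code{\link{ae_frame}}. Baselines are per-band linear
#' powers, typically the per-band median over pre-microbubble pulses (the
#' first pulses of a run, before the 10 dB 4th-harmonic rise).
#'
#' @param spectrum a \code{pulse_spectrum}.
#' @param baselines named numeric vector of positive linear baseline powers
#'   with names \code{h2..h8}, \code{uh1..uh7}, \code{broadband}.
#' @param f0 excitation frequency, MHz.
#' @param pressure_mpa commanded pressure for this pulse, MPa.
#' @param time_s pulse time, seconds (default pulse_index - 1 at 1 Hz PRF).
#' @param half_width band half-width, kHz.
#' @return An \code{ae_frame}. The gating \code{h4_db} equals the 4th
#'   harmonic band level of this spectrum.
#' @export
extract_frame <- function(spectrum, baselines, f0, pressure_mpa,
                          time_s = NULL, half_width = 0.3) {
  bands <- standard_bands(f0, half_width)
  need <- names(bands)
  missing <- setdiff(need, names(baselines))
  if (length(missing) > 0L) {
    stop("missing baseline power for band(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lv <- vapply(need, function(nm) {
    band_level_db(spectrum, bands[[nm]], baselines[[nm]])
  }, numeric(1))
  if (is.null(time_s)) time_s <- spectrum$pulse_index - 1
  ae_frame(
    pulse_index = spectrum$pulse_index, time_s = time_s,
    pressure_mpa = pressure_mpa,
    harmonic_db = lv[paste0("h", 2:8)],
    ultraharmonic_db = lv[paste0("uh", 1:7)],
    h4_db = lv[["h4"]], broadband_db = lv[["broadband"]]
  )
}

#' Median per-band baseline powers from pre-microbubble pulses
#'
#' @param spectra list of \code{pulse_spectrum} recorded before microbubble
#'   arrival.
#' @param f0 excitation frequency, MHz.
#' @param half_width band half-width, kHz.
#' @return Named numeric vector of baseline powers (linear units).
#' @export
baseline_powers <- function(spectra, f0, half_width = 0.3) {
  bands <- standard_bands(f0, half_width)
  vapply(bands, function(b) {
    median(vapply(spectra, function(s) mean(s$power[in_band_idx(s, b)]),
                  numeric(1)))
  }, numeric(1))
}
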