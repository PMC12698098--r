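# Fully synthetic inputs: a band-limited reference pulse and occlusion pulse
# series with a known deformation trajectory, so every other module can be
# validated without instrument data.

#' Synthetic band-limited reference pulse
#'
#' A single-cycle derivative-of-Gaussian pulse,
#' `E(t) = -(t - t0) / sigma^2 * exp(-(t - t0)^2 / (2 sigma^2))`,
#' scaled to unit peak amplitude (1 mV). Its amplitude spectrum is
#' `|S(f)| ~ f * exp(-2 pi^2 sigma^2 f^2)`, peaking at `1/(2 pi sigma)`;
#' `sigma` is set so the spectral peak sits at `centre_THz`.
#'
#' @param centre_THz Spectral peak frequency, THz (default 0.5).
#' @param bandwidth_THz Optional override for the shape parameter: when
#'   given, `sigma = 1/(2 pi bandwidth_THz)` regardless of `centre_THz`.
#' @param n Number of samples (default 512).
#' @param dt_ps Sample spacing in picoseconds (default 0.05).
#' @param t0_ps Pulse centre time; default one quarter of the record.
#' @return A [pulse_trace()], zero-mean and deterministic.
#' @export
make_reference_pulse <- function(centre_THz = 0.5, bandwidth_THz = NULL,
                                 n = 512L, dt_ps = 0.05, t0_ps = NULL) {
  stopifnot(centre_THz > 0, n >= 8, dt_ps > 0)
  sigma <- 1 / (2 * pi * if (is.null(bandwidth_THz)) centre_THz
                         else bandwidth_THz)
  t <- seq(0, by = dt_ps, length.out = n)
  if (is.null(t0_ps)) t0_ps <- n * dt_ps / 4
  a <- -(t - t0_ps) / sigma^2 * exp(-(t - t0_ps)^2 / (2 * sigma^2))
  pulse_trace(t, a / max(abs(a)))
}

#' Occlusion measurement scenario
#'
#' Parameters of a simulated window-contact measurement: a 90 s acquisition
#' at 12 pulses per second by default, with the first-layer air fraction
#' decaying from `va1_start` to `va1_end` — a fast exponential (elastic)
#' phase of time constant `decay_time_s`, optionally followed by a slow
#' linear (viscous) drift of `linear_slope` per second — and additive white
#' Gaussian amplitude noise of standard deviation `noise_sd_mV`. Defaults
#' mirror a typical in vivo volar-forearm measurement (trajectory
#' 0.57 -> 0.38 over 90 s).
#'
#' @param duration_s Measurement duration, seconds (> 0).
#' @param rate_hz Pulse acquisition rate, per second (> 0).
#' @param va1_start,va1_end Trajectory endpoints, `0 <= end <= start <= 1`.
#' @param decay_time_s Exponential time constant of the elastic phase.
#' @param linear_slope Linear (viscous-phase) decrease per second, >= 0.
#' @param noise_sd_mV Amplitude noise standard deviation, mV.
#' @param seed Integer RNG seed for the noise.
#' @return An object of class `"occlusion_scenario"`.
#' @export
occlusion_scenario <- function(duration_s = 90, rate_hz = 12,
                               va1_start = 0.57, va1_end = 0.38,
                               decay_time_s = 10, linear_slope = 0,
                               noise_sd_mV = 0.002, seed = 1L) {
  if (duration_s <= 0 || rate_hz <= 0)
    stop("duration_s and rate_hz must be positive", call. = FALSE)
  if (!(va1_end >= 0 && va1_end <= va1_start && va1_start <= 1))
    stop("require 0 <= va1_end <= va1_start <= 1", call. = FALSE)
  if (decay_time_s <= 0 || linear_slope < 0 || noise_sd_mV < 0)
    stop("decay_time_s must be > 0; linear_slope and noise_sd_mV >= 0",
         call. = FALSE)
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 va1_start = va1_start, va1_end = va1_end,
                 decay_time_s = decay_time_s, linear_slope = linear_slope,
                 noise_sd_mV = noise_sd_mV, seed = as.integer(seed)),
            class = "occlusion_scenario")
}

#' @export
print.occlusion_scenario <- function(x, ...) {
  cat(sprintf(paste0("<occlusion_scenario> %.3g s at %.3g Hz, V_A1 %.3g -> ",
                     "%.3g (tau %.3g s, slope %.3g/s), noise sd %.3g mV, ",
                     "seed %d\n"),
              x$duration_s, x$rate_hz, x$va1_start, x$va1_end,
              x$decay_time_s, x$linear_slope, x$noise_sd_mV, x$seed))
  invisible(x)
}

#' Deformation-parameter trajectory of a scenario
#'
#' `V_A1(tau) = va1_end + (va1_start - va1_end) * exp(-tau / decay_time) -
#' linear_slope * tau`, clipped to \[0, 1\]: the two-phase creep shape of
#' skin under constant stress mapped onto the air fraction.
#'
#' @param scenario An [occlusion_scenario()].
#' @param tau_s Times in seconds, within `[0, duration_s]`.
#' @return Air fraction(s), monotone non-increasing in `tau_s`.
#' @export
va1_trajectory <- function(scenario, tau_s) {
  stopifnot(inherits(scenario, "occlusion_scenario"))
  if (any(tau_s < -1e-12) || any(tau_s > scenario$duration_s + 1e-12))
    stop("tau_s outside [0, duration_s]", call. = FALSE)
  v <- scenario$va1_end +
    (scenario$va1_start - scenario$va1_end) * exp(-tau_s / scenario$decay_time_s) -
    scenario$linear_slope * tau_s
  pmin(pmax(v, 0), 1)
}

#' Generate a synthetic occlusion pulse series
#'
#' For every acquisition time on the scenario's rate grid, builds the ridge
#' stack at the trajectory's `V_A1(tau)`, synthesizes the reflected pulse
#' from the reference, and adds seeded white Gaussian noise. The exact
#' trajectory used is returned alongside the series as ground truth.
#'
#' @param scenario An [occlusion_scenario()].
#' @param config A [stack_config()] (geometry and dielectrics; its `va1`
#'   field is ignored in favour of the trajectory).
#' @param reference A [pulse_trace()].
#' @return A list with `series` ([pulse_series()]), `va1_true` (numeric,
#'   per pulse) and `tau_s`.
#' @examples
#' ref <- make_reference_pulse()
#' sc <- occlusion_scenario(duration_s = 2, rate_hz = 4, noise_sd_mV = 0)
#' g <- generate_series(sc, stack_config(), ref)
#' @export
generate_series <- function(scenario, config, reference) {
  stopifnot(inherits(scenario, "occlusion_scenario"),
            inherits(config, "stack_config"),
            inherits(reference, "pulse_trace"))
  n_pulse <- floor(scenario$duration_s * scenario$rate_hz)
  tau <- seq(0, by = 1 / scenario$rate_hz, length.out = n_pulse)
  va1 <- va1_trajectory(scenario, tau)
  cache <- forward_cache(config, reference)
  amp <- matrix(0, nrow = length(reference$time_ps), ncol = n_pulse)
  for (i in seq_len(n_pulse))
    amp[, i] <- forward_amplitude(cache, va1[i])
  if (scenario$noise_sd_mV > 0) {
    amp <- amp + with_seed(scenario$seed,
      matrix(stats::rnorm(length(amp), sd = scenario$noise_sd_mV),
             nrow = nrow(amp)))
  }
  list(series = pulse_series(tau, amp, time_ps = reference$time_ps),
       va1_true = va1, tau_s = tau)
}
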