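# Time-domain pulses, spectra, and the frequency-domain analysis quantities:
# peak-to-peak attenuation, the deconvolved response M, and per-frequency
# correlation between simulated and measured series.
#
# Spectra use the physics convention S(f) = integral x(t) e^{+2*pi*i*f*t} dt
# (consistent with e^{-iwt} fields), so multiplying a reference spectrum by
# the stack reflectance r(f) and inverting yields the reflected pulse with
# echoes delayed, not advanced.  No window functions or spectral filters are
# applied anywhere; deconvolution uses a magnitude floor mask only.

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Time-domain THz pulse
#'
#' @param time_ps Uniformly spaced times in picoseconds.
#' @param amplitude_mV Amplitudes in millivolts, same length, finite.
#' @return An object of class `"pulse_trace"`: list with `time_ps`,
#'   `amplitude_mV`, and time step `dt_ps`.
#' @export
pulse_trace <- function(time_ps, amplitude_mV) {
  t <- as.numeric(time_ps); a <- as.numeric(amplitude_mV)
  if (length(t) < 2L || length(t) != length(a))
    stop("time and amplitude must be equal-length vectors (>= 2 samples)",
         call. = FALSE)
  d <- diff(t)
  if (any(d <= 0) || (max(d) - min(d)) > 1e-9 * max(abs(t)))
    stop("time grid must be uniform and increasing", call. = FALSE)
  if (any(!is.finite(a)))
    stop("amplitudes must be finite", call. = FALSE)
  structure(list(time_ps = t, amplitude_mV = a, dt_ps = mean(d)),
            class = "pulse_trace")
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf("<pulse_trace> %d samples, dt = %.4g ps, P2P = %.4g mV\n",
              length(x$time_ps), x$dt_ps, peak_to_peak(x)))
  invisible(x)
}

#' Series of pulses over compression time
#'
#' @param tau_s Increasing measurement times in seconds since window
#'   contact, one per trace.
#' @param amplitudes Numeric matrix, one column per tau, rows on the shared
#'   time grid; or a list of [pulse_trace()] objects sharing one grid.
#' @param time_ps Shared time grid (ignored when `amplitudes` is a list of
#'   traces).
#' @return An object of class `"pulse_series"`: list with `tau_s`,
#'   `time_ps`, `amplitudes` (matrix, `length(time_ps)` x `length(tau_s)`).
#' @export
pulse_series <- function(tau_s, amplitudes, time_ps = NULL) {
  tau <- as.numeric(tau_s)
  if (length(tau) < 1L || any(diff(tau) <= 0))
    stop("tau_s must be non-empty and strictly increasing", call. = FALSE)
  if (is.list(amplitudes) && !is.matrix(amplitudes)) {
    stopifnot(all(vapply(amplitudes, inherits, TRUE, "pulse_trace")))
    time_ps <- amplitudes[[1L]]$time_ps
    for (tr in amplitudes)
      if (length(tr$time_ps) != length(time_ps) ||
          max(abs(tr$time_ps - time_ps)) > 1e-9)
        stop("all traces in a series must share one time grid", call. = FALSE)
    amplitudes <- vapply(amplitudes, function(tr) tr$amplitude_mV,
                         numeric(length(time_ps)))
  }
  amplitudes <- as.matrix(amplitudes)
  if (is.null(time_ps))
    stop("time_ps is required when amplitudes is a matrix", call. = FALSE)
  if (ncol(amplitudes) != length(tau))
    stop("amplitudes must have one column per tau", call. = FALSE)
  if (nrow(amplitudes) != length(time_ps))
    stop("amplitudes rows must match the time grid", call. = FALSE)
  pulse_trace(time_ps, amplitudes[, 1L])  # validates the grid
  structure(list(tau_s = tau, time_ps = as.numeric(time_ps),
                 amplitudes = amplitudes),
            class = "pulse_series")
}

#' @export
print.pulse_series <- function(x, ...) {
  cat(sprintf("<pulse_series> %d pulses over %.3g-%.3g s, %d samples each\n",
              length(x$tau_s), min(x$tau_s), max(x$tau_s), length(x$time_ps)))
  invisible(x)
}

#' Extract one trace from a series
#'
#' @param series A [pulse_series()].
#' @param i Trace index.
#' @return A [pulse_trace()].
#' @export
series_trace <- function(series, i) {
  stopifnot(inherits(series, "pulse_series"))
  pulse_trace(series$time_ps, series$amplitudes[, i])
}

# physics-convention spectrum at non-negative rfft frequencies
trace_spectrum <- function(amplitude, dt_ps, n_pad) {
  x <- c(amplitude, rep(0, n_pad - length(amplitude)))
  X <- stats::fft(x)
  Conj(X[seq_len(n_pad %/% 2 + 1L)])
}

# inverse of trace_spectrum: positive-frequency physics spectrum -> real signal
spectrum_to_trace <- function(S, n_pad, n_out) {
  X <- Conj(S)
  X[1L] <- complex(real = Re(X[1L]))
  X[length(X)] <- complex(real = Re(X[length(X)]))
  full <- c(X, Conj(rev(X[2:(length(X) - 1L)])))
  Re(stats::fft(full, inverse = TRUE))[seq_len(n_out)] / n_pad
}

#' Frequency grid of a reference pulse's spectrum
#'
#' The non-negative FFT frequencies of a trace after zero-padding to
#' `n_pad` samples; the grid on which a stack reflectance must be supplied
#' (or is computed) for pulse synthesis.
#'
#' @param reference A [pulse_trace()].
#' @param n_pad FFT length, a power of two >= the trace length; default the
#'   next power of two.
#' @return A [frequency_grid()] from 0 to the Nyquist frequency.
#' @export
reference_spectrum_grid <- function(reference, n_pad = NULL) {
  stopifnot(inherits(reference, "pulse_trace"))
  n <- length(reference$time_ps)
  if (is.null(n_pad)) n_pad <- next_pow2(n)
  if (n_pad < n || n_pad != next_pow2(n_pad))
    stop("n_pad must be a power of two >= the trace length", call. = FALSE)
  frequency_grid(seq(0, n_pad %/% 2) / (n_pad * reference$dt_ps))
}

#' Synthesize the reflected pulse for a given reflectance
#'
#' Forms `E_sim(t)` as the inverse transform of `r(f) * E_ref(f)`. The
#' reflectance must be sampled on (or cover) the reference's padded FFT
#' grid; a covering grid is linearly interpolated, extrapolation is an
#' error. Linear and time-invariant in the reference.
#'
#' @param r A [reflectance_spectrum()].
#' @param reference A [pulse_trace()].
#' @param n_pad FFT length (power of two), default next power of two.
#' @return A [pulse_trace()] on the reference time grid.
#' @export
synthesize_pulse <- function(r, reference, n_pad = NULL) {
  stopifnot(inherits(r, "reflectance_spectrum"),
            inherits(reference, "pulse_trace"))
  n <- length(reference$time_ps)
  if (is.null(n_pad)) n_pad <- next_pow2(n)
  fr <- as.numeric(reference_spectrum_grid(reference, n_pad))
  fg <- as.numeric(r$grid)
  if (same_grid(fg, fr)) {
    rv <- r$r
  } else {
    if (min(fg) > min(fr) + 1e-12 || max(fg) < max(fr) - 1e-12)
      stop("reflectance grid does not cover the reference spectrum; ",
           "extrapolation refused", call. = FALSE)
    rv <- complex(real = stats::approx(fg, Re(r$r), xout = fr)$y,
                  imaginary = stats::approx(fg, Im(r$r), xout = fr)$y)
  }
  S_ref <- trace_spectrum(reference$amplitude_mV, reference$dt_ps, n_pad)
  amp <- spectrum_to_trace(rv * S_ref, n_pad, n)
  pulse_trace(reference$time_ps, amp)
}

#' Peak-to-peak amplitude of a pulse
#'
#' @param trace A [pulse_trace()] (or bare numeric vector).
#' @return `max(amplitude) - min(amplitude)`, in mV.
#' @export
peak_to_peak <- function(trace) {
  a <- if (inherits(trace, "pulse_trace")) trace$amplitude_mV
       else as.numeric(trace)
  if (length(a) == 0L) stop("empty trace", call. = FALSE)
  max(a) - min(a)
}

#' Signal attenuation curve of a pulse series
#'
#' Peak-to-peak amplitude of every pulse against compression time: the
#' "occlusion curve" of a window-contact measurement.
#'
#' @param series A [pulse_series()].
#' @return A data.frame with columns `tau_s`, `p2p_mV`.
#' @export
attenuation_curve <- function(series) {
  stopifnot(inherits(series, "pulse_series"))
  data.frame(tau_s = series$tau_s,
             p2p_mV = apply(series$amplitudes, 2L, function(a) max(a) - min(a)))
}

#' Deconvolved frequency response M
#'
#' `M(f) = FFT(sample) / FFT(reference)` on the shared padded grid, with no
#' filtering or windowing. Frequencies where the reference spectral
#' magnitude falls below `floor_frac` of its peak are masked (`NA`) rather
#' than silently divided.
#'
#' @param sample,reference [pulse_trace()] objects on one time grid.
#' @param floor_frac Spectral floor as a fraction of the reference's peak
#'   spectral magnitude; default 0.01.
#' @param n_pad FFT length (power of two).
#' @return An object of class `"freq_response"`: list with `grid`
#'   ([frequency_grid()]), complex `M` (NA where masked), logical `masked`.
#' @export
deconvolved_response <- function(sample, reference, floor_frac = 0.01,
                                 n_pad = NULL) {
  stopifnot(inherits(sample, "pulse_trace"), inherits(reference, "pulse_trace"))
  if (length(sample$time_ps) != length(reference$time_ps) ||
      max(abs(sample$time_ps - reference$time_ps)) > 1e-9)
    stop("sample and reference must share one time grid", call. = FALSE)
  n <- length(reference$time_ps)
  if (is.null(n_pad)) n_pad <- next_pow2(n)
  S_ref <- trace_spectrum(reference$amplitude_mV, reference$dt_ps, n_pad)
  S_sam <- trace_spectrum(sample$amplitude_mV, sample$dt_ps, n_pad)
  masked <- Mod(S_ref) < floor_frac * max(Mod(S_ref))
  M <- S_sam / S_ref
  M[masked] <- NA_complex_
  structure(list(grid = reference_spectrum_grid(reference, n_pad),
                 M = M, masked = masked),
            class = "freq_response")
}

#' @export
print.freq_response <- function(x, ...) {
  ok <- !x$masked
  cat(sprintf("<freq_response> %d frequencies (%d unmasked), |M| in [%.3g, %.3g]\n",
              length(x$grid), sum(ok),
              min(Mod(x$M[ok])), max(Mod(x$M[ok]))))
  invisible(x)
}

# |M|(tau) matrix for a series: one row per frequency bin, one column per tau
series_response_magnitude <- function(series, reference, floor_frac = 0.01,
                                      n_pad = NULL) {
  stopifnot(inherits(series, "pulse_series"))
  n <- length(reference$time_ps)
  if (is.null(n_pad)) n_pad <- next_pow2(n)
  S_ref <- trace_spectrum(reference$amplitude_mV, reference$dt_ps, n_pad)
  masked <- Mod(S_ref) < floor_frac * max(Mod(S_ref))
  mags <- apply(series$amplitudes, 2L, function(a) {
    Mod(trace_spectrum(a, reference$dt_ps, n_pad) / S_ref)
  })
  mags[masked, ] <- NA_real_
  list(grid = reference_spectrum_grid(reference, n_pad), mag = mags,
       masked = masked)
}

#' Per-frequency change of the response magnitude across a series
#'
#' Absolute and percentage change of `|M|` from the first to the last pulse
#' of a series, over an analysis band (default 0.2-1.5 THz, the
#' high-signal-to-noise region of a typical THz system).
#'
#' @param series A [pulse_series()] with at least two pulses.
#' @param reference A [pulse_trace()] on the same time grid.
#' @param band Length-2 numeric, analysis band in THz.
#' @param floor_frac,n_pad Passed to the deconvolution.
#' @return A data.frame with columns `frequency_THz`, `m_first`, `m_last`,
#'   `delta_abs` (`|M|_last - |M|_first`) and `delta_pct`
#'   (`100 * delta_abs / |M|_first`), masked bins dropped.
#' @export
frequency_attenuation_summary <- function(series, reference,
                                          band = c(0.2, 1.5),
                                          floor_frac = 0.01, n_pad = NULL) {
  stopifnot(inherits(series, "pulse_series"))
  if (length(series$tau_s) < 2L)
    stop("need at least two pulses", call. = FALSE)
  sr <- series_response_magnitude(series, reference, floor_frac, n_pad)
  f <- as.numeric(sr$grid)
  keep <- !sr$masked & f >= band[1L] & f <= band[2L]
  m1 <- sr$mag[keep, 1L]
  m2 <- sr$mag[keep, ncol(sr$mag)]
  data.frame(frequency_THz = f[keep], m_first = m1, m_last = m2,
             delta_abs = m2 - m1, delta_pct = 100 * (m2 - m1) / m1)
}

#' Per-frequency correlation of simulated and measured attenuation
#'
#' For each requested frequency, the Pearson correlation over compression
#' time between the `|M|(tau)` curves of a simulated and a measured series
#' (each deconvolved against the same reference). Frequencies snap to the
#' nearest FFT bin.
#'
#' @param simulated,measured [pulse_series()] objects on matching tau grids
#'   with at least 3 pulses.
#' @param reference A [pulse_trace()] on the shared time grid.
#' @param frequencies_THz Frequencies at which to report the correlation.
#' @param floor_frac,n_pad Passed to the deconvolution.
#' @return A data.frame with columns `frequency_THz` (bin centres) and
#'   `pearson_r`.
#' @export
per_frequency_correlation <- function(simulated, measured, reference,
                                      frequencies_THz,
                                      floor_frac = 0.01, n_pad = NULL) {
  stopifnot(inherits(simulated, "pulse_series"),
            inherits(measured, "pulse_series"))
  if (length(simulated$tau_s) != length(measured$tau_s) ||
      max(abs(simulated$tau_s - measured$tau_s)) > 1e-9)
    stop("simulated and measured series must share the tau grid",
         call. = FALSE)
  if (length(simulated$tau_s) < 3L)
    stop("correlation undefined for fewer than 3 tau points", call. = FALSE)
  ms <- series_response_magnitude(simulated, reference, floor_frac, n_pad)
  mm <- series_response_magnitude(measured, reference, floor_frac, n_pad)
  f <- as.numeric(ms$grid)
  idx <- vapply(frequencies_THz, function(fq) which.min(abs(f - fq)), 0L)
  r <- vapply(idx, function(i) {
    if (ms$masked[i]) NA_real_ else stats::cor(ms$mag[i, ], mm$mag[i, ])
  }, 0)
  data.frame(frequency_THz = f[idx], pearson_r = r)
}

#' Align one trace to another by cross-correlation
#'
#' Shifts `x` by the integer number of samples that maximises its
#' cross-correlation with `target` (zero-filled, not circular). Used before
#' any pointwise pulse comparison.
#'
#' @param x,target [pulse_trace()] objects on one time grid.
#' @return The shifted `x` as a [pulse_trace()]; the applied lag in samples
#'   is stored in attribute `"lag"`.
#' @export
align_traces <- function(x, target) {
  stopifnot(inherits(x, "pulse_trace"), inherits(target, "pulse_trace"))
  a <- x$amplitude_mV; b <- target$amplitude_mV
  n <- length(a)
  if (n != length(b))
    stop("traces must share one time grid", call. = FALSE)
  np <- next_pow2(2L * n)
  A <- stats::fft(c(a, rep(0, np - n)))
  B <- stats::fft(c(b, rep(0, np - n)))
  cc <- Re(stats::fft(Conj(A) * B, inverse = TRUE)) / np
  # index k (0-based) of cc is correlation at lag k (mod np)
  lags <- c(0:(np %/% 2 - 1L), -(np %/% 2):-1L)
  keep <- abs(lags) < n
  best <- lags[keep][which.max(cc[keep])]
  out <- numeric(n)
  if (best >= 0) out[(1L + best):n] <- a[seq_len(n - best)]
  else out[seq_len(n + best)] <- a[(1L - best):n]
  structure(pulse_trace(x$time_ps, out), lag = best)
}

#' Simulate the reflected pulse for a stack configuration
#'
#' Convenience forward model: computes the stack reflectance on the
#' reference's padded FFT grid and synthesizes the reflected pulse.
#'
#' @param config A [stack_config()].
#' @param reference A [pulse_trace()].
#' @param va1 Air fraction of the first ridge layer; defaults to the
#'   configuration's value.
#' @param d_f_um Ridge-layer thickness; defaults to the configuration's value.
#' @param n_pad FFT length (power of two).
#' @return A [pulse_trace()].
#' @examples
#' ref <- make_reference_pulse()
#' p <- simulate_pulse(stack_config(), ref, va1 = 0.5)
#' @export
simulate_pulse <- function(config, reference, va1 = config$va1,
                           d_f_um = config$d_f_um, n_pad = NULL) {
  cache <- forward_cache(config, reference, d_f_um = d_f_um, n_pad = n_pad)
  pulse_trace(reference$time_ps, forward_amplitude(cache, va1))
}

# Precomputed objects for repeated forward simulation at varying va1.
forward_cache <- function(config, reference, d_f_um = config$d_f_um,
                          n_pad = NULL) {
  stopifnot(inherits(config, "stack_config"),
            inherits(reference, "pulse_trace"))
  n <- length(reference$time_ps)
  if (is.null(n_pad)) n_pad <- next_pow2(n)
  grid <- reference_spectrum_grid(reference, n_pad)
  list(tmpl = stack_template(config, grid, d_f_um = d_f_um),
       S_ref = trace_spectrum(reference$amplitude_mV, reference$dt_ps, n_pad),
       n = n, n_pad = n_pad, grid = grid,
       angle = config$incidence_angle_deg * pi / 180,
       polarization = config$polarization)
}

forward_amplitude <- function(cache, va1) {
  layers <- template_layers(cache$tmpl, va1)
  r <- recursive_reflectance(list(layers = layers, grid = cache$grid),
                             angle = cache$angle,
                             polarization = cache$polarization)
  spectrum_to_trace(r$r * cache$S_ref, cache$n_pad, cache$n)
}
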