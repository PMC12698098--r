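# Pulse synthesis, peak-to-peak, deconvolution and frequency-domain summaries.

flat_reflectance <- function(value, reference) {
  g <- reference_spectrum_grid(reference)
  reflectance_spectrum(g, rep(as.complex(value), length(g)))
}

test_that("synthesis with a perfect mirror and a scalar reflector is exact", {
  ref <- test_reference()
  expect_equal(synthesize_pulse(flat_reflectance(1, ref), ref)$amplitude_mV,
               ref$amplitude_mV, tolerance = 1e-12)
  half <- synthesize_pulse(flat_reflectance(-0.5, ref), ref)
  expect_equal(half$amplitude_mV, -0.5 * ref$amplitude_mV, tolerance = 1e-12)
})

test_that("a frequency-flat interface echoes the reference scaled by |r|", {
  ref <- test_reference()
  # two constant half-spaces n = 2 | 3: r = -0.2, frequency flat
  g <- reference_spectrum_grid(ref)
  st <- list(layers = list(list(eps = 4 + 0i, d_um = Inf),
                           list(eps = 9 + 0i, d_um = Inf)), grid = g)
  p <- synthesize_pulse(recursive_reflectance(st), ref)
  expect_equal(peak_to_peak(p), 0.2 * peak_to_peak(ref), tolerance = 1e-9)
})

test_that("pulse synthesis satisfies Parseval consistency", {
  ref <- test_reference()
  g <- reference_spectrum_grid(ref)
  set.seed(505)
  st <- random_stack(5, g)
  r <- recursive_reflectance(st)
  p <- synthesize_pulse(r, ref)
  n_pad <- thzskin:::next_pow2(length(ref$time_ps))
  X <- stats::fft(c(ref$amplitude_mV, rep(0, n_pad - length(ref$time_ps))))
  rv <- r$r
  full_r <- c(rv, Conj(rev(rv[2:(length(rv) - 1L)])))
  lhs <- sum(p$amplitude_mV^2)
  rhs <- sum(Mod(full_r)^2 * Mod(X)^2) / n_pad
  # the synthesized record truncates the padded tail; bound, then near-equality
  expect_lt(abs(lhs - rhs) / rhs, 1e-6)
})

test_that("peak-to-peak obeys its closed forms and homogeneity", {
  t <- seq(0, 10, by = 0.025)  # grid hits the sine extrema exactly
  expect_equal(peak_to_peak(pulse_trace(t, rep(3, length(t)))), 0)
  expect_equal(peak_to_peak(pulse_trace(t, sin(2 * pi * t / 5))), 2)
  a <- rnorm(length(t))
  expect_equal(peak_to_peak(pulse_trace(t, -2.5 * a)),
               2.5 * peak_to_peak(pulse_trace(t, a)))
})

test_that("attenuation curve follows the series, including degenerate cases", {
  ref <- test_reference()
  one <- pulse_series(1, matrix(ref$amplitude_mV), time_ps = ref$time_ps)
  expect_equal(nrow(attenuation_curve(one)), 1)
  same <- pulse_series(1:5, matrix(ref$amplitude_mV, ncol = 5,
                                   nrow = length(ref$time_ps)),
                       time_ps = ref$time_ps)
  expect_equal(diff(attenuation_curve(same)$p2p_mV), rep(0, 4))
  gen <- test_series_noiseless()
  p2p <- attenuation_curve(gen$series)$p2p_mV
  expect_true(all(diff(p2p) <= 1e-12))  # noiseless flattening only attenuates
})

test_that("deconvolution is exact for identity, delay, and synthesis round trip", {
  ref <- test_reference()
  M0 <- deconvolved_response(ref, ref)
  expect_equal(Mod(M0$M[!M0$masked]), rep(1, sum(!M0$masked)),
               tolerance = 1e-9)
  # delay by 8 samples: |M| = 1, linear phase 2*pi*f*dt*8
  del <- pulse_trace(ref$time_ps, thzskin:::shift_vec(ref$amplitude_mV, 8L))
  Md <- deconvolved_response(del, ref)
  keep <- !Md$masked & as.numeric(Md$grid) > 0.2 & as.numeric(Md$grid) < 1.5
  expect_equal(Mod(Md$M[keep]), rep(1, sum(keep)), tolerance = 1e-6)
  ph <- Arg(Md$M[keep])
  expected <- 2 * pi * as.numeric(Md$grid)[keep] * ref$dt_ps * 8
  expect_equal(sin(ph - expected), rep(0, sum(keep)), tolerance = 1e-9)
  # round trip: M recovers r on the unmasked band
  g <- reference_spectrum_grid(ref)
  r <- recursive_reflectance(build_stack(stack_config(), g))
  p <- synthesize_pulse(r, ref)
  M <- deconvolved_response(p, ref)
  band <- keep
  expect_lt(max(Mod(M$M[band] - r$r[band])), 1e-6)
})

test_that("deconvolution masks low-signal frequencies instead of dividing", {
  ref <- test_reference()
  M <- deconvolved_response(ref, ref, floor_frac = 0.05)
  f <- as.numeric(M$grid)
  expect_true(M$masked[1])              # derivative pulse has no DC energy
  expect_true(all(is.na(M$M[M$masked])))
  expect_true(any(!M$masked & f > 0.2 & f < 1.5))
})

test_that("frequency change summary: zeros for static series, -10% for scaling", {
  ref <- test_reference()
  static <- pulse_series(c(0, 1), cbind(ref$amplitude_mV, ref$amplitude_mV),
                         time_ps = ref$time_ps)
  fs0 <- frequency_attenuation_summary(static, ref)
  expect_equal(fs0$delta_abs, rep(0, nrow(fs0)), tolerance = 1e-12)
  scaled <- pulse_series(c(0, 1), cbind(ref$amplitude_mV,
                                        0.9 * ref$amplitude_mV),
                         time_ps = ref$time_ps)
  fs <- frequency_attenuation_summary(scaled, ref)
  expect_equal(fs$delta_pct, rep(-10, nrow(fs)), tolerance = 1e-9)
})

test_that("per-frequency correlation is exact for affine and anti-correlated pairs", {
  ref <- test_reference()
  gen <- test_series_noiseless()
  sim <- gen$series
  expect_equal(per_frequency_correlation(sim, sim, ref,
                                         c(0.3, 0.6, 1.0))$pearson_r,
               rep(1, 3), tolerance = 1e-9)
  # measured = affine map of simulated (per-trace scaling changes |M|(tau)
  # affinely at every frequency)
  meas <- pulse_series(sim$tau_s, 2 * sim$amplitudes, time_ps = sim$time_ps)
  expect_equal(per_frequency_correlation(sim, meas, ref,
                                         c(0.3, 0.6, 1.0))$pearson_r,
               rep(1, 3), tolerance = 1e-9)
  # anti-correlated: measured |M|(tau) reversed in tau
  rev_ser <- pulse_series(sim$tau_s, sim$amplitudes[, rev(seq_along(sim$tau_s))],
                          time_ps = sim$time_ps)
  r_rev <- per_frequency_correlation(sim, rev_ser, ref, 0.5)$pearson_r
  expect_lt(r_rev, -0.9)
  short <- pulse_series(c(0, 1), sim$amplitudes[, 1:2], time_ps = sim$time_ps)
  expect_error(per_frequency_correlation(short, short, ref, 0.5), "fewer than 3")
})

test_that("alignment finds the applied shift", {
  ref <- test_reference()
  shifted <- pulse_trace(ref$time_ps, thzskin:::shift_vec(ref$amplitude_mV, 11L))
  back <- align_traces(shifted, ref)
  expect_equal(attr(back, "lag"), -11L)
  expect_equal(back$amplitude_mV[20:200], ref$amplitude_mV[20:200],
               tolerance = 1e-12)
})
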