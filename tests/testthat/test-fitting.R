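# Bayesian optimiser, loss behaviour, and deformation-parameter extraction.

test_that("loss arithmetic: identity, single-sample difference, loop oracle", {
  t <- seq(0, 5, by = 0.05)
  a <- sin(t)
  expect_equal(thz_loss(pulse_trace(t, a), pulse_trace(t, a)), 0)
  b <- a
  b[30] <- b[30] + 2        # one sample off by 2 mV -> loss 4
  expect_equal(thz_loss(pulse_trace(t, a), pulse_trace(t, b), align = FALSE), 4)
  set.seed(909)
  x <- rnorm(64); y <- rnorm(64)
  expect_equal(thz_loss(pulse_trace(t[1:64], x), pulse_trace(t[1:64], y),
                        align = FALSE),
               sum((x - y)^2), tolerance = 1e-12)
  # squared-signal variant
  expect_equal(thz_loss(pulse_trace(t[1:64], x), pulse_trace(t[1:64], y),
                        loss_type = "squared_signal", align = FALSE),
               sum((x^2 - y^2)^2), tolerance = 1e-12)
})

test_that("the Bayesian optimiser finds smooth 1-D minima and is deterministic", {
  fn <- function(x) (x - 0.321)^2 + 0.05 * sin(20 * x)^2
  o1 <- bayes_optimize(fn, 0, 1, seed = 5)
  o2 <- bayes_optimize(fn, 0, 1, seed = 5)
  expect_identical(o1$x_best, o2$x_best)
  expect_identical(o1$y, o2$y)
  expect_lt(abs(o1$x_best - stats::optimize(fn, c(0, 1))$minimum), 5e-3)
  # collapsed bounds return the point
  oc <- bayes_optimize(fn, 0.4, 0.4, seed = 1)
  expect_equal(oc$x_best, 0.4)
  expect_equal(oc$n_eval, 1L)
})

test_that("loss surface is unimodal with the minimum at the generating value", {
  ref <- test_reference()
  cfg <- stack_config()
  for (v in c(0.3, 0.6)) {
    tr <- simulate_pulse(cfg, ref, va1 = v)
    ls <- loss_surface(tr, ref, df_um = cfg$d_f_um, config = cfg,
                       va1_grid = seq(0, 1, length.out = 51))
    expect_equal(ls$va1[which.min(ls$loss)], v, tolerance = 0.011)
    expect_equal(sum(diff(sign(diff(ls$loss))) > 0), 1)  # one interior minimum
  }
})

test_that("thickness optimisation recovers the generating d_f and obeys bounds", {
  ref <- test_reference()
  cfg <- stack_config(d_f_um = 5)  # truth 5 um
  # constant series at the fixed va1 value: unbiased recovery case
  tr <- simulate_pulse(cfg, ref, va1 = 0.5)
  ser <- pulse_series(c(0, 1, 2), matrix(tr$amplitude_mV, ncol = 3,
                                         nrow = length(ref$time_ps)),
                      time_ps = ref$time_ps)
  ctrl <- fit_control(fit_stride = 1, df_candidates = 2, n_iter = 25)
  df <- optimize_df(ser, ref, cfg, ctrl)
  expect_lt(abs(as.numeric(df) - 5), 0.5)
  expect_gte(as.numeric(df), 2)
  expect_lte(as.numeric(df), 10)
  # collapsed bounds return that point
  ctrl2 <- fit_control(df_bounds = c(4, 4), df_candidates = 1)
  expect_equal(as.numeric(optimize_df(ser, ref, cfg, ctrl2)), 4)
})

test_that("va1 extraction is accurate, warm-started and stationary on constant series", {
  ref <- test_reference()
  cfg <- stack_config()
  tr <- simulate_pulse(cfg, ref, va1 = 0.44)
  ser <- pulse_series(0:3, matrix(tr$amplitude_mV, ncol = 4,
                                  nrow = length(ref$time_ps)),
                      time_ps = ref$time_ps)
  ctrl <- fit_control(fit_stride = 1, n_iter = 20)
  fits <- fit_va1_series(ser, ref, cfg$d_f_um, cfg, ctrl)
  expect_equal(nrow(fits), 4)
  expect_true(all(abs(fits$va1 - 0.44) < 5e-3))
  expect_true(all(fits$va1 >= 0 & fits$va1 <= 1))
  expect_true(all(fits$loss >= 0))
  expect_error(fit_va1_series(ser, ref, 12, cfg, ctrl), "df_bounds")
})

test_that("fits decrease over tau for a flattening-skin series", {
  ref <- test_reference()
  cfg <- stack_config()
  gen <- test_series_noiseless()
  ctrl <- fit_control(fit_stride = 4, n_iter = 20, df_candidates = 4)
  fits <- fit_va1_series(gen$series, ref, cfg$d_f_um, cfg, ctrl)
  expect_true(all(diff(fits$va1) < 0.005))      # non-increasing within noise
  err <- abs(fits$va1 - gen$va1_true[fits$pulse_index])
  expect_lt(max(err), 0.02)
})

test_that("the full fit is reproducible and its methods are coherent", {
  ref <- test_reference()
  cfg <- stack_config()
  gen <- test_series_noiseless()
  ctrl <- fit_control(fit_stride = 4, n_iter = 15, df_candidates = 3,
                      seed = 3L)
  f1 <- fit_occlusion(gen$series, ref, cfg, ctrl)
  f2 <- fit_occlusion(gen$series, ref, cfg, ctrl)
  expect_identical(f1$df_um, f2$df_um)
  expect_identical(f1$fits$va1, f2$fits$va1)
  # methods
  expect_s3_class(f1, "thz_skin_fit")
  expect_output(print(f1), "ridge-layer thickness")
  expect_length(coef(f1), nrow(f1$fits))
  expect_equal(unname(coef(f1, "df")), f1$df_um)
  expect_equal(predict(f1, f1$fits$tau_s), f1$fits$va1)
  sim <- fitted(f1)
  expect_s3_class(sim, "pulse_series")
  expect_equal(dim(residuals(f1)),
               c(length(ref$time_ps), nrow(f1$fits)))
  # residuals of a noiseless fit are small relative to the signal
  expect_lt(max(abs(residuals(f1))), 0.05 * peak_to_peak(ref))
  s <- summary(f1)
  expect_s3_class(s, "summary.thz_skin_fit")
  expect_output(print(s), "total change")
  sims <- simulate(f1, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "pulse_series")
  # fixed-df path skips stage 1
  f3 <- fit_occlusion(gen$series, ref, cfg, ctrl, df_um = 2.5)
  expect_equal(f3$df_um, 2.5)
})
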