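# Error matrix, robustness metric and acceptable-set logic.

test_that("simulation error is zero on self-comparison and shift-invariant", {
  ref <- test_reference()
  cfg <- stack_config()
  tr <- simulate_pulse(cfg, ref, va1 = 0.4, d_f_um = 30 / 12)
  expect_equal(simulation_error(cfg, 0.4, 12, 30, tr, ref), 0,
               tolerance = 1e-18)
  # common time shift of both signals leaves the aligned error unchanged
  tr2 <- simulate_pulse(cfg, ref, va1 = 0.7, d_f_um = 30 / 12)
  e0 <- thz_loss(tr2, tr)
  sh <- 9L
  e1 <- thz_loss(pulse_trace(tr2$time_ps,
                             thzskin:::shift_vec(tr2$amplitude_mV, sh)),
                 pulse_trace(tr$time_ps,
                             thzskin:::shift_vec(tr$amplitude_mV, sh)))
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("loss equals the brute-force sum of squared differences", {
  set.seed(606)
  t <- seq(0, 10, by = 0.05)
  a <- rnorm(length(t)); b <- rnorm(length(t))
  manual <- 0
  for (i in seq_along(a)) manual <- manual + (a[i] - b[i])^2
  expect_equal(thz_loss(pulse_trace(t, a), pulse_trace(t, b), align = FALSE),
               manual, tolerance = 1e-12)
})

test_that("error matrix has the requested shape and row-wise minimum at truth", {
  ref <- test_reference()
  cfg <- stack_config()
  meas <- simulate_pulse(cfg, ref, va1 = 0.5, d_f_um = 30 / 12)  # truth L = 12
  em1 <- build_error_matrix(cfg, meas, ref, 30, va1_grid = 0.5,
                            layer_grid = 12)
  expect_s3_class(em1, "error_matrix")
  expect_equal(dim(em1$errors), c(1, 1))
  expect_lt(em1$errors[1, 1], 1e-18)
  em <- build_error_matrix(cfg, meas, ref, 30, va1_grid = c(0.3, 0.5, 0.7),
                           layer_grid = c(4, 8, 12, 15))
  expect_equal(dim(em$errors), c(3, 4))
  expect_true(all(em$errors >= 0))
  # the row at the generating va1 attains its minimum at the generating L
  expect_equal(em$layer_counts[which.min(em$errors[2, ])], 12)
})

test_that("robustness metric matches a hand-computed 3x3 matrix", {
  em <- structure(list(va1_values = c(0.1, 0.5, 0.9), layer_counts = 1:3,
                       errors = matrix(c(1, 2, 3,
                                         2, 2, 2,
                                         5, 1, 0), nrow = 3),
                       d_um = 30), class = "error_matrix")
  met <- robustness_metric(em)
  means <- c(2, 2, 2)
  sds <- c(stats::sd(c(1, 2, 3)), 0, stats::sd(c(5, 1, 0)))
  expect_equal(met$metric, means / max(means) + sds / max(sds),
               tolerance = 1e-12)
  # all-equal matrix: all metrics equal
  em$errors <- matrix(4, 3, 3)
  expect_equal(diff(robustness_metric(em)$metric), c(0, 0))
  # dominance: a column with smallest mean and sd is the strict minimum
  em$errors <- matrix(c(1, 1, 1, 4, 6, 8, 9, 9, 15), nrow = 3)
  met <- robustness_metric(em)
  expect_equal(which.min(met$metric), 1L)
  expect_true(all(met$metric[-1] > met$metric[1]))
})

test_that("robustness metric is invariant to shuffling the V_A1 axis", {
  set.seed(707)
  em <- structure(list(va1_values = seq(0, 1, length.out = 6),
                       layer_counts = 1:5,
                       errors = matrix(rexp(30), nrow = 6), d_um = 30),
                  class = "error_matrix")
  m0 <- robustness_metric(em)$metric
  perm <- sample(6)
  em$errors <- em$errors[perm, ]
  em$va1_values <- em$va1_values[perm]
  expect_equal(robustness_metric(em)$metric, m0, tolerance = 1e-12)
})

test_that("acceptable set applies the 5% rule and always keeps the argmin", {
  expect_equal(acceptable_set(c(1.0, 1.04, 1.10), L = 5:7), c(5L, 6L))
  expect_equal(acceptable_set(c(1.0, 1.04, 1.10), tolerance = 0, L = 5:7), 5L)
  expect_equal(acceptable_set(3.2, L = 9L), 9L)
  set.seed(808)
  for (k in 1:10) {
    v <- rexp(12)
    expect_true(which.min(v) %in% acceptable_set(v))
  }
})

test_that("layer-count selection intersects per-height sets or fails loudly", {
  ref <- test_reference()
  cfg <- stack_config()
  sc <- occlusion_scenario(duration_s = 5, rate_hz = 2)
  gen <- generate_series(sc, cfg, ref)
  meas <- series_trace(gen$series, 5)
  sel <- select_layer_count(cfg, meas, ref, d_values_um = c(30, 45))
  expect_true(as.numeric(sel) %in% 1:15)
  sets <- attr(sel, "sets")
  expect_length(sets, 2)
  expect_true(all(as.numeric(sel) <= unlist(sets)[
    unlist(sets) %in% Reduce(intersect, sets)]))
  # a sweep including a height far below the generating one has no consensus
  err <- tryCatch(select_layer_count(cfg, meas, ref,
                                     d_values_um = c(15, 30, 45, 60)),
                  error = identity)
  if (inherits(err, "no_consensus_error")) {
    expect_named(err$sets, c("d=15um", "d=30um", "d=45um", "d=60um"))
  } else {
    expect_true(as.numeric(err) %in% 1:15)
  }
})
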