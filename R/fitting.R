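# Fitting the layered model to a pulse series: ridge-layer thickness d_f is
# optimised once with the deformation parameter fixed at 0.5, then V_A1 is
# extracted per measurement time by Bayesian optimisation of a least-squares
# pulse-matching loss.

#' Fitting control parameters
#'
#' @param va1_bounds Search bounds for the first-layer air fraction
#'   (default `c(0, 1)`).
#' @param df_bounds Search bounds for the ridge-layer thickness in
#'   micrometres (default `c(2, 10)`).
#' @param fit_stride Fit every `fit_stride`-th pulse of the series
#'   (default 10).
#' @param n_init,n_iter Initial design size and iteration budget of the
#'   Bayesian optimiser (defaults 10 and 40).
#' @param seed Integer seed governing all optimiser randomness.
#' @param loss_type `"difference"` (default): squared L2 norm of the signal
#'   difference. `"squared_signal"`: squared L2 norm of the difference of
#'   squared signals, available for sensitivity checks.
#' @param align Align simulated to measured pulses by cross-correlation
#'   before the pointwise loss (default `TRUE`).
#' @param df_candidates Number of stride-selected pulses on which the
#'   thickness optimisation is tried; the (pulse, d_f) pair with the lowest
#'   loss wins (default 32).
#' @param n_pad FFT length for pulse synthesis (power of two; default next
#'   power of two of the reference length).
#' @return An object of class `"fit_control"`.
#' @export
fit_control <- function(va1_bounds = c(0, 1), df_bounds = c(2, 10),
                        fit_stride = 10L, n_init = 10L, n_iter = 40L,
                        seed = 1L, loss_type = c("difference", "squared_signal"),
                        align = TRUE, df_candidates = 32L, n_pad = NULL) {
  loss_type <- match.arg(loss_type)
  if (length(va1_bounds) != 2L || diff(va1_bounds) < 0 ||
      va1_bounds[1] < 0 || va1_bounds[2] > 1)
    stop("va1_bounds must be an ordered interval within [0, 1]", call. = FALSE)
  if (length(df_bounds) != 2L || diff(df_bounds) < 0 || df_bounds[1] <= 0)
    stop("df_bounds must be an ordered positive interval", call. = FALSE)
  if (fit_stride < 1) stop("fit_stride must be >= 1", call. = FALSE)
  structure(list(va1_bounds = as.numeric(va1_bounds),
                 df_bounds = as.numeric(df_bounds),
                 fit_stride = as.integer(fit_stride),
                 n_init = as.integer(n_init), n_iter = as.integer(n_iter),
                 seed = as.integer(seed), loss_type = loss_type,
                 align = isTRUE(align),
                 df_candidates = as.integer(df_candidates), n_pad = n_pad),
            class = "fit_control")
}

# --- internal fast loss on amplitude vectors ---------------------------------

align_lag <- function(a, b) {
  n <- length(a)
  np <- next_pow2(2L * n)
  A <- stats::fft(c(a, rep(0, np - n)))
  B <- stats::fft(c(b, rep(0, np - n)))
  cc <- Re(stats::fft(Conj(A) * B, inverse = TRUE)) / np
  lags <- c(0:(np %/% 2 - 1L), -(np %/% 2):-1L)
  keep <- abs(lags) < n
  lags[keep][which.max(cc[keep])]
}

shift_vec <- function(a, lag) {
  n <- length(a)
  out <- numeric(n)
  if (lag >= 0) out[(1L + lag):n] <- a[seq_len(n - lag)]
  else out[seq_len(n + lag)] <- a[(1L - lag):n]
  out
}

loss_amp <- function(sim, meas, loss_type = "difference", align = TRUE) {
  if (align) {
    lag <- align_lag(sim, meas)
    if (lag != 0L) sim <- shift_vec(sim, lag)
  }
  if (loss_type == "difference") sum((sim - meas)^2)
  else sum((sim^2 - meas^2)^2)
}

#' Pulse-matching loss
#'
#' The squared L2 norm of the pointwise difference between a simulated and a
#' measured pulse, after cross-correlation alignment:
#' `sum_t (E_sim(t) - E_meas(t))^2`. The `"squared_signal"` variant
#' `sum_t (E_sim^2 - E_meas^2)^2` is available for sensitivity checks.
#'
#' @param sim,meas [pulse_trace()] objects on one time grid.
#' @param loss_type,align See [fit_control()].
#' @return Non-negative scalar.
#' @export
thz_loss <- function(sim, meas, loss_type = c("difference", "squared_signal"),
                     align = TRUE) {
  loss_type <- match.arg(loss_type)
  stopifnot(inherits(sim, "pulse_trace"), inherits(meas, "pulse_trace"))
  if (length(sim$time_ps) != length(meas$time_ps) ||
      max(abs(sim$time_ps - meas$time_ps)) > 1e-9)
    stop("pulses must share one time grid", call. = FALSE)
  loss_amp(sim$amplitude_mV, meas$amplitude_mV, loss_type, align)
}

stride_indices <- function(n, stride) seq(1L, n, by = stride)

#' Optimise the ridge-layer thickness
#'
#' Finds `d_f` within `control$df_bounds` minimising the pulse-matching loss
#' with the deformation parameter fixed at `va1_fixed = 0.5`, by
#' Gaussian-process Bayesian optimisation. Because the fixed `va1` is only
#' consistent with a pulse whose true deformation state is near that value,
#' the optimisation is run on each of `control$df_candidates`
#' stride-selected pulses and the (pulse, `d_f`) pair achieving the lowest
#' loss is returned.
#'
#' @param series A [pulse_series()].
#' @param reference A [pulse_trace()] on the same time grid.
#' @param config A [stack_config()].
#' @param control A [fit_control()].
#' @param va1_fixed Air fraction held fixed during the thickness search
#'   (default 0.5).
#' @return `d_f` in micrometres, with attributes `"loss"` (best loss),
#'   `"pulse_index"` (winning pulse), `"converged"`, and `"candidates"`
#'   (per-candidate data.frame).
#' @export
optimize_df <- function(series, reference, config = stack_config(),
                        control = fit_control(), va1_fixed = 0.5) {
  stopifnot(inherits(series, "pulse_series"),
            inherits(reference, "pulse_trace"),
            inherits(config, "stack_config"),
            inherits(control, "fit_control"))
  n_tau <- length(series$tau_s)
  idx <- stride_indices(n_tau, control$fit_stride)
  if (length(idx) > control$df_candidates)
    idx <- idx[unique(round(seq(1L, length(idx),
                                length.out = control$df_candidates)))]
  results <- lapply(seq_along(idx), function(k) {
    meas <- series$amplitudes[, idx[k]]
    fn <- function(df) {
      cache <- forward_cache(config, reference, d_f_um = df,
                             n_pad = control$n_pad)
      loss_amp(forward_amplitude(cache, va1_fixed), meas,
               control$loss_type, control$align)
    }
    bayes_optimize(fn, control$df_bounds[1], control$df_bounds[2],
                   n_init = control$n_init, n_iter = control$n_iter,
                   seed = control$seed + 1000L + k)
  })
  losses <- vapply(results, `[[`, 0, "y_best")
  best <- which.min(losses)
  cand <- data.frame(pulse_index = idx,
                     tau_s = series$tau_s[idx],
                     df_um = vapply(results, `[[`, 0, "x_best"),
                     loss = losses)
  if (!results[[best]]$converged)
    warning("thickness optimiser returned best-so-far (degenerate surrogate)")
  structure(results[[best]]$x_best, loss = losses[best],
            pulse_index = idx[best],
            converged = results[[best]]$converged, candidates = cand)
}

#' Extract the deformation parameter per measurement time
#'
#' For every `fit_stride`-th pulse of the series, finds the first-layer air
#' fraction minimising the pulse-matching loss at the fixed ridge-layer
#' thickness `df_um`, by Gaussian-process Bayesian optimisation. Each
#' search is warm-started at the previous time's optimum (the first from
#' the centre of the bounds), exploiting the slow variation of the
#' deformation trajectory.
#'
#' @param series A [pulse_series()].
#' @param reference A [pulse_trace()] on the same time grid.
#' @param df_um Ridge-layer thickness (e.g. from [optimize_df()]); must lie
#'   within `control$df_bounds`.
#' @param config A [stack_config()].
#' @param control A [fit_control()].
#' @return A data.frame with one row per fitted pulse: `pulse_index`,
#'   `tau_s`, `va1`, `loss`, `rmse_mV`, `n_eval`, `converged`.
#' @export
fit_va1_series <- function(series, reference, df_um, config = stack_config(),
                           control = fit_control()) {
  stopifnot(inherits(series, "pulse_series"),
            inherits(reference, "pulse_trace"),
            inherits(config, "stack_config"),
            inherits(control, "fit_control"))
  df_um <- as.numeric(df_um)
  if (df_um < control$df_bounds[1] - 1e-9 ||
      df_um > control$df_bounds[2] + 1e-9)
    stop("df_um outside control$df_bounds", call. = FALSE)
  cache <- forward_cache(config, reference, d_f_um = df_um,
                         n_pad = control$n_pad)
  idx <- stride_indices(length(series$tau_s), control$fit_stride)
  prev <- mean(control$va1_bounds)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    meas <- series$amplitudes[, idx[k]]
    fn <- function(v) loss_amp(forward_amplitude(cache, v), meas,
                               control$loss_type, control$align)
    opt <- bayes_optimize(fn, control$va1_bounds[1], control$va1_bounds[2],
                          n_init = control$n_init, n_iter = control$n_iter,
                          init = prev, seed = control$seed + k)
    prev <- opt$x_best
    rmse <- sqrt(opt$y_best / length(meas))
    out[[k]] <- data.frame(pulse_index = idx[k], tau_s = series$tau_s[idx[k]],
                           va1 = opt$x_best, loss = opt$y_best,
                           rmse_mV = if (control$loss_type == "difference")
                                       rmse else NA_real_,
                           n_eval = opt$n_eval, converged = opt$converged)
  }
  do.call(rbind, out)
}

#' Loss surface over the deformation parameter
#'
#' The pulse-matching loss of one measured pulse evaluated on a grid of
#' first-layer air fractions at fixed ridge-layer thickness; an
#' identifiability diagnostic (for a well-posed fit the surface is unimodal
#' with a clear minimum that moves with measurement time).
#'
#' @param trace A measured [pulse_trace()].
#' @param reference A [pulse_trace()] on the same time grid.
#' @param df_um Ridge-layer thickness, micrometres.
#' @param config A [stack_config()].
#' @param va1_grid Air-fraction grid (default 101 points on \[0, 1\]).
#' @param control A [fit_control()] (loss type / alignment / padding).
#' @return A data.frame with columns `va1`, `loss`.
#' @export
loss_surface <- function(trace, reference, df_um, config = stack_config(),
                         va1_grid = seq(0, 1, length.out = 101L),
                         control = fit_control()) {
  stopifnot(inherits(trace, "pulse_trace"), inherits(reference, "pulse_trace"))
  if (length(va1_grid) < 1L) stop("va1_grid must be nonempty", call. = FALSE)
  cache <- forward_cache(config, reference, d_f_um = df_um,
                         n_pad = control$n_pad)
  meas <- trace$amplitude_mV
  data.frame(va1 = va1_grid,
             loss = vapply(va1_grid, function(v)
               loss_amp(forward_amplitude(cache, v), meas,
                        control$loss_type, control$align), 0))
}

#' Fit the layered skin-deformation model to an occlusion pulse series
#'
#' The package's main modelling entry point. Two stages: (1) the
#' ridge-layer thickness `d_f` is optimised with the deformation parameter
#' fixed at 0.5 ([optimize_df()]); (2) the first-layer air fraction `V_A1`
#' is extracted at every `fit_stride`-th pulse by Bayesian optimisation of
#' the pulse-matching loss ([fit_va1_series()]). Both stages are
#' deterministic given `control$seed`.
#'
#' @param series A measured (or synthetic) [pulse_series()].
#' @param reference A reference [pulse_trace()] on the same time grid.
#' @param config A [stack_config()] describing window, layers and
#'   dielectrics.
#' @param control A [fit_control()].
#' @param df_um Optional fixed ridge-layer thickness; skips stage (1).
#' @return An object of class `"thz_skin_fit"` with fields `df_um`,
#'   `fits` (per-tau data.frame), `series`, `reference`, `config`,
#'   `control`, `call`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' ref <- make_reference_pulse()
#' sc <- occlusion_scenario(duration_s = 5, rate_hz = 2, noise_sd_mV = 0)
#' gen <- generate_series(sc, stack_config(), ref)
#' fit <- fit_occlusion(gen$series, ref,
#'                      control = fit_control(fit_stride = 5, n_iter = 15))
#' coef(fit)
#' }
#' @export
fit_occlusion <- function(series, reference, config = stack_config(),
                          control = fit_control(), df_um = NULL) {
  cl <- match.call()
  if (is.null(df_um)) {
    df_opt <- optimize_df(series, reference, config, control)
  } else {
    df_opt <- structure(as.numeric(df_um), candidates = NULL,
                        loss = NA_real_, converged = TRUE)
  }
  fits <- fit_va1_series(series, reference, as.numeric(df_opt),
                         config, control)
  structure(list(df_um = as.numeric(df_opt),
                 df_diagnostics = attributes(df_opt),
                 fits = fits, series = series, reference = reference,
                 config = config, control = control, call = cl),
            class = "thz_skin_fit")
}

#' @export
print.thz_skin_fit <- function(x, ...) {
  cat("Layered skin-deformation model fit\n")
  cat(sprintf("  ridge-layer thickness d_f: %.3f um (%d layers, total %.1f um)\n",
              x$df_um, x$config$L, x$df_um * x$config$L))
  cat(sprintf("  fitted pulses: %d of %d (stride %d)\n",
              nrow(x$fits), length(x$series$tau_s), x$control$fit_stride))
  cat(sprintf("  V_A1: %.3f at tau = %.2g s  ->  %.3f at tau = %.3g s\n",
              x$fits$va1[1], x$fits$tau_s[1],
              x$fits$va1[nrow(x$fits)], x$fits$tau_s[nrow(x$fits)]))
  invisible(x)
}

#' @export
coef.thz_skin_fit <- function(object, parameter = c("va1", "df"), ...) {
  parameter <- match.arg(parameter)
  if (parameter == "df") return(c(d_f_um = object$df_um))
  stats::setNames(object$fits$va1, sprintf("tau=%.3gs", object$fits$tau_s))
}

#' Predict the deformation trajectory at new times
#'
#' Linear interpolation of the fitted `V_A1` series (constant beyond the
#' fitted range).
#'
#' @param object A [fit_occlusion()] result.
#' @param tau_s Times in seconds; default the fitted times.
#' @param ... Unused.
#' @return Numeric vector of air fractions.
#' @export
predict.thz_skin_fit <- function(object, tau_s = object$fits$tau_s, ...) {
  stats::approx(object$fits$tau_s, object$fits$va1, xout = tau_s,
                rule = 2)$y
}

#' @export
fitted.thz_skin_fit <- function(object, ...) {
  cache <- forward_cache(object$config, object$reference,
                         d_f_um = object$df_um, n_pad = object$control$n_pad)
  amp <- vapply(object$fits$va1, function(v) forward_amplitude(cache, v),
                numeric(length(object$reference$time_ps)))
  pulse_series(object$fits$tau_s, amp, time_ps = object$reference$time_ps)
}

#' @export
residuals.thz_skin_fit <- function(object, ...) {
  sim <- fitted(object)
  res <- matrix(0, nrow = length(object$reference$time_ps),
                ncol = nrow(object$fits))
  for (k in seq_len(ncol(res))) {
    s <- sim$amplitudes[, k]
    m <- object$series$amplitudes[, object$fits$pulse_index[k]]
    if (object$control$align) s <- shift_vec(s, align_lag(s, m))
    res[, k] <- m - s
  }
  dimnames(res) <- list(NULL, sprintf("tau=%.3gs", object$fits$tau_s))
  res
}

#' @export
summary.thz_skin_fit <- function(object, ...) {
  p2p <- apply(object$series$amplitudes[, object$fits$pulse_index,
                                        drop = FALSE],
               2L, function(a) max(a) - min(a))
  structure(list(df_um = object$df_um,
                 n_fit = nrow(object$fits),
                 va1_first = object$fits$va1[1],
                 va1_last = object$fits$va1[nrow(object$fits)],
                 delta_va1 = object$fits$va1[1] -
                   object$fits$va1[nrow(object$fits)],
                 p2p_drop_mV = p2p[1] - p2p[length(p2p)],
                 cor_va1_p2p = if (nrow(object$fits) >= 3)
                   stats::cor(object$fits$va1, p2p) else NA_real_,
                 rmse_mV = object$fits$rmse_mV,
                 fits = object$fits),
            class = "summary.thz_skin_fit")
}

#' @export
print.summary.thz_skin_fit <- function(x, ...) {
  cat("Layered skin-deformation model fit\n")
  cat(sprintf("  d_f = %.3f um; %d fitted pulses\n", x$df_um, x$n_fit))
  cat(sprintf("  V_A1: %.3f -> %.3f  (total change %.3f)\n",
              x$va1_first, x$va1_last, x$delta_va1))
  cat(sprintf("  P2P drop over fit: %.4g mV\n", x$p2p_drop_mV))
  cat(sprintf("  cor(V_A1, P2P) = %.3f\n", x$cor_va1_p2p))
  if (!all(is.na(x$rmse_mV)))
    cat(sprintf("  per-pulse RMSE: median %.4g mV (max %.4g)\n",
                stats::median(x$rmse_mV), max(x$rmse_mV)))
  invisible(x)
}

#' Plot a fitted deformation trajectory
#'
#' Two panels: the extracted `V_A1(tau)` series, and the measured
#' peak-to-peak attenuation curve with the fitted pulses marked.
#'
#' @param x A [fit_occlusion()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.thz_skin_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$fits$tau_s, x$fits$va1, type = "b", pch = 16, cex = 0.6,
                 xlab = "compression time tau (s)",
                 ylab = expression(V[A1]), ...)
  ac <- attenuation_curve(x$series)
  graphics::plot(ac$tau_s, ac$p2p_mV, type = "l", col = "grey50",
                 xlab = "compression time tau (s)", ylab = "P2P (mV)")
  graphics::points(x$fits$tau_s,
                   ac$p2p_mV[x$fits$pulse_index], pch = 16, cex = 0.5)
  invisible(x)
}

#' Simulate pulse series from a fitted model
#'
#' Re-synthesizes the series implied by the fitted trajectory on the
#' original tau grid (trajectory linearly interpolated between fitted
#' times) and adds Gaussian noise with the residual standard deviation.
#'
#' @param object A [fit_occlusion()] result.
#' @param nsim Number of series to simulate.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` [pulse_series()] objects.
#' @export
simulate.thz_skin_fit <- function(object, nsim = 1, seed = 1L, ...) {
  cache <- forward_cache(object$config, object$reference,
                         d_f_um = object$df_um, n_pad = object$control$n_pad)
  tau <- object$series$tau_s
  va1 <- predict(object, tau)
  clean <- vapply(va1, function(v) forward_amplitude(cache, v),
                  numeric(length(object$reference$time_ps)))
  sd_res <- stats::sd(residuals(object))
  with_seed(seed, lapply(seq_len(nsim), function(i)
    pulse_series(tau, clean + matrix(stats::rnorm(length(clean), sd = sd_res),
                                     nrow = nrow(clean)),
                 time_ps = object$reference$time_ps)))
}
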