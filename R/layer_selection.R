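# Robustness analysis for choosing the number of ridge layers L: simulate
# the signal over a grid of (V_A1, L) at fixed total ridge height d, score
# each L by combining the mean and standard deviation of the error across
# V_A1, and keep L values within 5% of the minimum.

#' Squared-L2 simulation error for one parameter combination
#'
#' Simulates the reflected pulse for `L` ridge layers of thickness
#' `d_um / L` at air fraction `va1`, aligns it to the measured pulse, and
#' returns the squared L2 norm of the difference.
#'
#' @param config A [stack_config()] (its `L`, `d_f_um`, `va1` fields are
#'   overridden).
#' @param va1 First-layer air fraction.
#' @param L Number of ridge layers.
#' @param d_um Total ridge height in micrometres; the layer thickness is
#'   `d_um / L`.
#' @param measured A measured [pulse_trace()].
#' @param reference A reference [pulse_trace()] on the same time grid.
#' @param loss_type,align,n_pad See [fit_control()].
#' @return Non-negative scalar.
#' @export
simulation_error <- function(config, va1, L, d_um, measured, reference,
                             loss_type = "difference", align = TRUE,
                             n_pad = NULL) {
  stopifnot(inherits(config, "stack_config"),
            inherits(measured, "pulse_trace"),
            inherits(reference, "pulse_trace"))
  cfg <- config
  cfg$L <- as.integer(L)
  cache <- forward_cache(cfg, reference, d_f_um = d_um / L, n_pad = n_pad)
  loss_amp(forward_amplitude(cache, va1), measured$amplitude_mV,
           loss_type, align)
}

#' Error matrix over the (V_A1, L) grid
#'
#' Fully populated matrix of [simulation_error()] values: one row per
#' `va1_grid` value, one column per layer count, all at total ridge height
#' `d_um`.
#'
#' @inheritParams simulation_error
#' @param va1_grid Air-fraction values (rows); default 10 points spanning
#'   \[0, 1\].
#' @param layer_grid Layer counts (columns); default 1..15.
#' @return An object of class `"error_matrix"`: list with `va1_values`,
#'   `layer_counts`, `errors` (matrix), `d_um`.
#' @export
build_error_matrix <- function(config, measured, reference, d_um,
                               va1_grid = seq(0, 1, length.out = 10L),
                               layer_grid = 1:15,
                               loss_type = "difference", align = TRUE,
                               n_pad = NULL) {
  if (length(va1_grid) < 1L || length(layer_grid) < 1L)
    stop("va1_grid and layer_grid must be nonempty", call. = FALSE)
  errors <- matrix(0, nrow = length(va1_grid), ncol = length(layer_grid))
  for (j in seq_along(layer_grid)) {
    L <- as.integer(layer_grid[j])
    cfg <- config
    cfg$L <- L
    cache <- forward_cache(cfg, reference, d_f_um = d_um / L, n_pad = n_pad)
    for (i in seq_along(va1_grid))
      errors[i, j] <- loss_amp(forward_amplitude(cache, va1_grid[i]),
                               measured$amplitude_mV, loss_type, align)
  }
  structure(list(va1_values = as.numeric(va1_grid),
                 layer_counts = as.integer(layer_grid),
                 errors = errors, d_um = d_um),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> %d V_A1 values x %d layer counts (d = %.3g um)\n",
              length(x$va1_values), length(x$layer_counts), x$d_um))
  invisible(x)
}

#' Robustness metric per layer count
#'
#' For each layer count, combines the mean and standard deviation of the
#' error across all air-fraction values:
#' `metric(L) = 2 * (w * mean_L / max(mean) + (1 - w) * sd_L / max(sd))`.
#' With the default equal weight `w = 0.5` this is
#' `mean_L / max(mean) + sd_L / max(sd)` — both terms scale-free and
#' max-normalised. Lower is better.
#'
#' @param em An [build_error_matrix()] result.
#' @param weight Weight on the mean term, in \[0, 1\] (default 0.5).
#' @return A data.frame with columns `L`, `mean_error`, `sd_error`,
#'   `metric`.
#' @export
robustness_metric <- function(em, weight = 0.5) {
  stopifnot(inherits(em, "error_matrix"))
  if (weight < 0 || weight > 1)
    stop("weight must be in [0, 1]", call. = FALSE)
  m <- apply(em$errors, 2L, mean)
  s <- if (nrow(em$errors) > 1L) apply(em$errors, 2L, stats::sd)
       else rep(0, ncol(em$errors))
  mn <- if (max(m) > 0) m / max(m) else m
  sn <- if (max(s) > 0) s / max(s) else s
  data.frame(L = em$layer_counts, mean_error = m, sd_error = s,
             metric = 2 * (weight * mn + (1 - weight) * sn))
}

#' Acceptable layer counts within tolerance of the best metric
#'
#' @param metrics A [robustness_metric()] data.frame (or a numeric vector
#'   of metric values named/paired with layer counts via `L`).
#' @param tolerance Relative tolerance (default 0.05): counts with
#'   `metric <= (1 + tolerance) * min(metric)` are accepted.
#' @param L Layer counts, required when `metrics` is a bare numeric vector.
#' @return Integer vector of accepted layer counts (always contains the
#'   argmin).
#' @export
acceptable_set <- function(metrics, tolerance = 0.05, L = NULL) {
  if (is.data.frame(metrics)) {
    L <- metrics$L
    v <- metrics$metric
  } else {
    v <- as.numeric(metrics)
    if (is.null(L)) L <- seq_along(v)
  }
  if (length(v) < 1L) stop("metrics must be nonempty", call. = FALSE)
  sort(L[v <= (1 + tolerance) * min(v)])
}

#' Select the number of ridge layers across total ridge heights
#'
#' Runs the robustness analysis at each total ridge height in `d_values_um`
#' and returns the smallest layer count present in every acceptable set.
#' With no consensus the per-height sets are attached to the error.
#'
#' @inheritParams build_error_matrix
#' @param d_values_um Total ridge heights to sweep (default 15, 30, 45,
#'   60 um).
#' @param tolerance Acceptable-set tolerance (default 0.05).
#' @param weight Metric weight (see [robustness_metric()]).
#' @return Integer layer count, with attribute `"sets"` (named list of
#'   per-height acceptable sets) and `"metrics"` (list of metric
#'   data.frames).
#' @export
select_layer_count <- function(config, measured, reference,
                               d_values_um = c(15, 30, 45, 60),
                               va1_grid = seq(0, 1, length.out = 10L),
                               layer_grid = 1:15,
                               tolerance = 0.05, weight = 0.5,
                               loss_type = "difference", align = TRUE,
                               n_pad = NULL) {
  if (length(d_values_um) < 1L)
    stop("need at least one total ridge height", call. = FALSE)
  sets <- list(); mets <- list()
  for (d in d_values_um) {
    em <- build_error_matrix(config, measured, reference, d,
                             va1_grid = va1_grid, layer_grid = layer_grid,
                             loss_type = loss_type, align = align,
                             n_pad = n_pad)
    met <- robustness_metric(em, weight = weight)
    key <- sprintf("d=%gum", d)
    mets[[key]] <- met
    sets[[key]] <- acceptable_set(met, tolerance = tolerance)
  }
  consensus <- Reduce(intersect, sets)
  if (length(consensus) == 0L) {
    cond <- structure(class = c("no_consensus_error", "error", "condition"),
                      list(message = paste0(
                             "no layer count is acceptable at every total ",
                             "ridge height; per-height sets attached"),
                           call = sys.call(), sets = sets))
    stop(cond)
  }
  structure(min(consensus), sets = sets, metrics = mets)
}
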