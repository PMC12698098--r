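# Frequency grids and frequency-dependent complex permittivities.
#
# Sign convention (used everywhere in the package): time dependence e^{-i w t},
# so a passive medium has Im(eps) >= 0 and Im(n) >= 0, and a wave accumulates
# phase e^{+i delta} across a layer.  See the methods vignette.

#' Speed of light in micrometres per picosecond
#'
#' Convenient for THz work: with frequency in THz (= 1/ps) and lengths in
#' micrometres, `lambda_um = c_um_ps() / f_THz`.
#'
#' @return Scalar, 299.792458 um/ps.
#' @export
c_um_ps <- function() 299.792458

#' Construct a uniform frequency grid
#'
#' @param frequencies_THz Numeric vector of frequencies in THz; must be
#'   non-negative, strictly increasing and uniformly spaced (to 1e-9
#'   relative) with at least two points.
#'
#' @return An object of class `"freq_grid"`: the frequency vector with the
#'   spacing stored in attribute `"df"`.
#' @examples
#' g <- frequency_grid(seq(0, 3, by = 0.05))
#' @export
frequency_grid <- function(frequencies_THz) {
  f <- as.numeric(frequencies_THz)
  if (length(f) < 2L)
    stop("a frequency grid needs at least two points", call. = FALSE)
  if (any(!is.finite(f)) || min(f) < 0)
    stop("frequencies must be finite and non-negative", call. = FALSE)
  d <- diff(f)
  if (any(d <= 0))
    stop("frequencies must be strictly increasing", call. = FALSE)
  if ((max(d) - min(d)) > 1e-9 * max(abs(f)))
    stop("frequency grid must be uniformly spaced", call. = FALSE)
  structure(f, df = mean(d), class = "freq_grid")
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("<freq_grid> %d points, %.4g to %.4g THz (step %.4g THz)\n",
              length(x), min(x), max(x), attr(x, "df")))
  invisible(x)
}

is_freq_grid <- function(x) inherits(x, "freq_grid")

#' Construct a material spectrum
#'
#' Bundles a complex relative permittivity sampled on a frequency grid.
#' Passivity is enforced: `Im(eps) >= 0` at every frequency (time dependence
#' `e^{-i w t}`); a tiny negative imaginary part (> -1e-12) is clipped to 0.
#'
#' @param grid A [frequency_grid()].
#' @param permittivity Complex (or real) vector of the same length as `grid`.
#' @param label Optional material name.
#' @return An object of class `"material_spectrum"` with fields `grid`,
#'   `eps`, `label`.
#' @export
material_spectrum <- function(grid, permittivity, label = "") {
  if (!is_freq_grid(grid)) grid <- frequency_grid(grid)
  eps <- as.complex(permittivity)
  if (length(eps) != length(grid))
    stop("permittivity length must match the frequency grid", call. = FALSE)
  im <- Im(eps)
  if (any(im < -1e-12))
    stop("permittivity violates passivity: Im(eps) < 0 (convention e^{-iwt})",
         call. = FALSE)
  eps <- complex(real = Re(eps), imaginary = pmax(im, 0))
  structure(list(grid = grid, eps = eps, label = as.character(label)),
            class = "material_spectrum")
}

#' @export
print.material_spectrum <- function(x, ...) {
  cat(sprintf("<material_spectrum> %s: %d frequencies, eps %.3g%+.3gi ... %.3g%+.3gi\n",
              if (nzchar(x$label)) x$label else "(unnamed)", length(x$grid),
              Re(x$eps[1]), Im(x$eps[1]),
              Re(x$eps[length(x$eps)]), Im(x$eps[length(x$eps)])))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a) == length(b) && max(abs(a - b)) <= 1e-9 * max(abs(b), 1)
}

#' Debye relaxation model
#'
#' A sum of Debye relaxation terms,
#' `eps(f) = eps_inf + sum_k delta_eps_k / (1 - i * 2*pi*f * tau_k)`,
#' under the package's `e^{-iwt}` convention (so `Im(eps) >= 0`).
#'
#' @param eps_inf High-frequency permittivity (dimensionless).
#' @param delta_eps Numeric vector of relaxation strengths, each >= 0.
#' @param tau_ps Numeric vector of relaxation times in picoseconds, each > 0,
#'   same length as `delta_eps`.
#' @return An object of class `"debye_model"`.
#' @seealso [debye_permittivity()], [water_debye_model()]
#' @export
debye_model <- function(eps_inf, delta_eps = numeric(), tau_ps = numeric()) {
  if (length(delta_eps) != length(tau_ps))
    stop("delta_eps and tau_ps must have the same length", call. = FALSE)
  if (any(delta_eps < 0) || any(tau_ps <= 0))
    stop("require delta_eps >= 0 and tau_ps > 0", call. = FALSE)
  if (length(delta_eps) == 0L && eps_inf <= 0)
    stop("invalid material: no relaxation terms and eps_inf <= 0", call. = FALSE)
  structure(list(eps_inf = eps_inf, delta_eps = as.numeric(delta_eps),
                 tau_ps = as.numeric(tau_ps)),
            class = "debye_model")
}

#' Literature double-Debye model for liquid water at THz frequencies
#'
#' Default water dispersion: a double-Debye fit with static permittivity
#' 78.4, intermediate value 4.9, high-frequency value 3.5 and relaxation
#' times 8.24 ps (cooperative) and 0.18 ps (fast), a parameter set in common
#' use for room-temperature water below ~2 THz. Override by passing any
#' [debye_model()] where a water spectrum is accepted.
#'
#' @return A [debye_model()].
#' @export
water_debye_model <- function() {
  debye_model(eps_inf = 3.5, delta_eps = c(73.5, 1.4), tau_ps = c(8.24, 0.18))
}

#' Evaluate a Debye model on a frequency grid
#'
#' @param model A [debye_model()].
#' @param grid A [frequency_grid()].
#' @param label Material name attached to the result.
#' @return A [material_spectrum()].
#' @examples
#' g <- frequency_grid(seq(0, 2, by = 0.02))
#' w <- debye_permittivity(water_debye_model(), g, label = "water")
#' @export
debye_permittivity <- function(model, grid, label = "") {
  stopifnot(inherits(model, "debye_model"))
  if (!is_freq_grid(grid)) grid <- frequency_grid(grid)
  f <- as.numeric(grid)
  eps <- rep(complex(real = model$eps_inf), length(f))
  for (k in seq_along(model$delta_eps)) {
    eps <- eps + model$delta_eps[k] /
      (1 - 1i * 2 * pi * f * model$tau_ps[k])
  }
  material_spectrum(grid, eps, label = label)
}

#' Nondispersive lossless material from a refractive index
#'
#' `eps = n^2` at every frequency. Used for the quartz imaging window
#' (n = 1.98) and for air (n = 1).
#'
#' @param n Real refractive index, > 0.
#' @param grid A [frequency_grid()].
#' @param label Material name.
#' @return A [material_spectrum()].
#' @export
constant_material <- function(n, grid, label = "") {
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("n must be a positive scalar", call. = FALSE)
  if (!is_freq_grid(grid)) grid <- frequency_grid(grid)
  material_spectrum(grid, rep(complex(real = n^2), length(grid)), label = label)
}

# principal complex cube root; inputs with Im >= 0 stay in the upper half
# plane; dimensions (matrix layouts) are preserved
ccbrt <- function(z) {
  d <- dim(z)
  out <- exp(log(as.complex(z)) / 3)
  dim(out) <- d
  out
}

#' Landau-Lifshitz-Looyenga two-phase effective permittivity
#'
#' Cube-root volume mixing,
#' `eps_eff = ((1 - v_air) * eps_skin^(1/3) + v_air * eps_air^(1/3))^3`,
#' evaluated elementwise with the principal branch of the complex cube root.
#' The rule accommodates arbitrarily shaped inclusions, which suits the
#' irregular skin/air geometry of compressed surface ridges.
#'
#' @param eps_skin,eps_air Complex permittivities (scalars or equal-length
#'   vectors): host and inclusion phases.
#' @param v_air Volume fraction of the `eps_air` phase, in \[0, 1\].
#' @return Complex vector of effective permittivities.
#' @examples
#' lll_mix(8, 1, 0.5)  # (0.5*2 + 0.5*1)^3 = 3.375
#' @export
lll_mix <- function(eps_skin, eps_air, v_air) {
  if (!is.numeric(v_air) || length(v_air) != 1L || v_air < 0 || v_air > 1)
    stop("v_air must be a scalar volume fraction in [0, 1]", call. = FALSE)
  (( (1 - v_air) * ccbrt(eps_skin) + v_air * ccbrt(eps_air) ))^3
}

#' Effective permittivity of skin at a given hydration
#'
#' Skin is treated as a two-phase effective medium of a "dry" biological
#' background and bound water, mixed by the same cube-root
#' (Landau-Lifshitz-Looyenga) rule as the ridge layers, with the water
#' volume fraction equal to the hydration.
#'
#' @param hydration Water volume fraction in \[0, 1\].
#' @param water [material_spectrum()] of the water phase.
#' @param dry [material_spectrum()] of the dry background; must share
#'   `water`'s grid.
#' @return A [material_spectrum()].
#' @export
skin_permittivity <- function(hydration, water, dry) {
  stopifnot(inherits(water, "material_spectrum"),
            inherits(dry, "material_spectrum"))
  if (!same_grid(water$grid, dry$grid))
    stop("water and dry spectra must share one frequency grid", call. = FALSE)
  if (!is.numeric(hydration) || length(hydration) != 1L ||
      hydration < 0 || hydration > 1)
    stop("hydration must be a volume fraction in [0, 1]", call. = FALSE)
  eps <- lll_mix(dry$eps, water$eps, hydration)
  material_spectrum(water$grid, eps,
                    label = sprintf("skin (hydration %.3f)", hydration))
}

#' Hydration as a function of depth into the ridge layers
#'
#' Depth profile of the water volume fraction across the ridge-layer region,
#' rising from `surface_h` at the skin surface (quartz contact) to `bottom_h`
#' at the bottom of the deepest ridge layer. Defaults 0.20 and 0.65 follow
#' Raman-derived stratum corneum water gradients. The default interpolant is
#' piecewise linear; `method = "cosine"` gives a smooth half-cosine ramp with
#' the same endpoints.
#'
#' @param depth_um Depth(s) in micrometres, within `[0, total_um]`.
#' @param total_um Total ridge height (L * d_f) in micrometres, > 0.
#' @param surface_h,bottom_h Hydration endpoints, `0 <= surface_h <=
#'   bottom_h <= 1`.
#' @param method `"linear"` (default) or `"cosine"`.
#' @return Numeric vector of hydrations, monotone non-decreasing in depth.
#' @examples
#' hydration_profile(c(0, 15, 30), 30)  # 0.20, 0.425, 0.65
#' @export
hydration_profile <- function(depth_um, total_um,
                              surface_h = 0.20, bottom_h = 0.65,
                              method = c("linear", "cosine")) {
  method <- match.arg(method)
  if (!is.numeric(total_um) || length(total_um) != 1L || total_um <= 0)
    stop("total_um must be a positive scalar", call. = FALSE)
  if (surface_h < 0 || bottom_h > 1 || surface_h > bottom_h)
    stop("require 0 <= surface_h <= bottom_h <= 1", call. = FALSE)
  if (any(depth_um < -1e-12) || any(depth_um > total_um * (1 + 1e-12)))
    stop("depth_um outside [0, total_um]", call. = FALSE)
  u <- pmin(pmax(depth_um / total_um, 0), 1)
  w <- switch(method,
              linear = u,
              cosine = (1 - cos(pi * u)) / 2)
  surface_h + (bottom_h - surface_h) * w
}

#' Read or write a material spectrum as CSV
#'
#' Columns `frequency_THz, eps_real, eps_imag`.
#'
#' @param x A [material_spectrum()].
#' @param path File path.
#' @param label Label for the material read back.
#' @return `read_material_spectrum()` returns a [material_spectrum()];
#'   `write_material_spectrum()` returns `path` invisibly.
#' @export
write_material_spectrum <- function(x, path) {
  stopifnot(inherits(x, "material_spectrum"))
  utils::write.csv(data.frame(frequency_THz = as.numeric(x$grid),
                              eps_real = Re(x$eps), eps_imag = Im(x$eps)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_material_spectrum
#' @export
read_material_spectrum <- function(path, label = "") {
  d <- utils::read.csv(path)
  need <- c("frequency_THz", "eps_real", "eps_imag")
  if (!all(need %in% names(d)))
    stop("material CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  material_spectrum(frequency_grid(d$frequency_THz),
                    complex(real = d$eps_real, imaginary = d$eps_imag),
                    label = label)
}
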