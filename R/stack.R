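# The layered system: quartz window | L skin-air ridge layers | bulk skin.

#' Air volume fraction of each ridge layer
#'
#' Squared-cosine depth profile of the air fraction across the ridge layers,
#' `V_A(N) = V_A1 * cos^2((N - 1) * pi / (2 L))` for `N = 1..L`: the first
#' (topmost) layer carries the deformation parameter `V_A1` and the fraction
#' decays over a quarter period so the deepest layer approaches zero.
#' `V_A1 = 0` is perfectly flattened skin (no trapped air anywhere).
#'
#' @param va1 Air fraction of the first ridge layer, in \[0, 1\].
#' @param L Number of ridge layers, >= 1.
#' @return Numeric vector of length `L`, non-increasing, within \[0, 1\].
#' @examples
#' air_fraction_profile(0.5, 2)  # 0.50 0.25
#' @export
air_fraction_profile <- function(va1, L) {
  if (!is.numeric(va1) || length(va1) != 1L || va1 < 0 || va1 > 1)
    stop("va1 must be a scalar in [0, 1]", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != round(L))
    stop("L must be a positive integer", call. = FALSE)
  N <- seq_len(L)
  va1 * cos((N - 1) * pi / (2 * L))^2
}

#' Stack configuration
#'
#' Parameters of the layered model. Defaults reproduce the reference
#' configuration: a 2 mm quartz window of index 1.98, twelve ridge layers of
#' 2.5 um each (total ridge height 30 um), hydration rising from 0.20 at the
#' surface to 0.65 at the bottom of the deepest layer, normal incidence.
#'
#' @param quartz_n Quartz refractive index.
#' @param quartz_thickness_mm Quartz window thickness (used only when
#'   `include_quartz_layer = TRUE`).
#' @param L Number of ridge layers (integer, 1-30).
#' @param d_f_um Ridge-layer thickness in micrometres; each layer is equally
#'   thick, total ridge height is `L * d_f_um`.
#' @param va1 Air volume fraction of the first ridge layer.
#' @param hydration_surface,hydration_bottom Hydration profile endpoints.
#' @param hydration_method Interpolant for [hydration_profile()].
#' @param incidence_angle_deg Angle of incidence in the quartz, degrees.
#' @param polarization `"s"` or `"p"` (irrelevant at normal incidence).
#' @param eps_dry Real permittivity of the dry biological background.
#' @param water_model [debye_model()] for the water phase.
#' @param bulk_hydration Hydration of the bulk skin half-space; by default
#'   the bottom-layer value, so bulk skin continues the profile.
#' @param bulk_spectrum Optional [material_spectrum()] for bulk skin measured
#'   independently; overrides `bulk_hydration` when supplied.
#' @param include_quartz_layer If `TRUE` the quartz window is a finite layer
#'   with air as the incidence medium; by default the window is the
#'   semi-infinite incidence medium, the standard referencing for
#'   window-contact reflection probes (front-face echoes are separated in
#'   time and removed when the measurement is referenced).
#' @return An object of class `"stack_config"` (a validated list).
#' @export
stack_config <- function(quartz_n = 1.98,
                         quartz_thickness_mm = 2,
                         L = 12L,
                         d_f_um = 2.5,
                         va1 = 0.5,
                         hydration_surface = 0.20,
                         hydration_bottom = 0.65,
                         hydration_method = "linear",
                         incidence_angle_deg = 0,
                         polarization = "s",
                         eps_dry = 2.5,
                         water_model = water_debye_model(),
                         bulk_hydration = NULL,
                         bulk_spectrum = NULL,
                         include_quartz_layer = FALSE) {
  fail <- function(field, msg)
    stop(sprintf("invalid stack configuration: %s %s", field, msg),
         call. = FALSE)
  if (!is.numeric(quartz_n) || quartz_n <= 0) fail("quartz_n", "must be > 0")
  if (!is.numeric(quartz_thickness_mm) || quartz_thickness_mm <= 0)
    fail("quartz_thickness_mm", "must be > 0")
  if (!is.numeric(L) || L != round(L) || L < 1 || L > 30)
    fail("L", "must be an integer in 1..30")
  if (!is.numeric(d_f_um) || d_f_um <= 0) fail("d_f_um", "must be > 0")
  if (!is.numeric(va1) || va1 < 0 || va1 > 1) fail("va1", "must be in [0, 1]")
  if (hydration_surface < 0 || hydration_bottom > 1 ||
      hydration_surface > hydration_bottom)
    fail("hydration_surface/hydration_bottom",
         "must satisfy 0 <= surface <= bottom <= 1")
  if (!polarization %in% c("s", "p")) fail("polarization", "must be 's' or 'p'")
  if (!is.numeric(eps_dry) || eps_dry <= 0) fail("eps_dry", "must be > 0")
  if (!inherits(water_model, "debye_model"))
    fail("water_model", "must be a debye_model")
  if (is.null(bulk_hydration)) bulk_hydration <- hydration_bottom
  if (bulk_hydration < 0 || bulk_hydration > 1)
    fail("bulk_hydration", "must be in [0, 1]")
  if (!is.null(bulk_spectrum) && !inherits(bulk_spectrum, "material_spectrum"))
    fail("bulk_spectrum", "must be a material_spectrum or NULL")
  structure(list(quartz_n = quartz_n,
                 quartz_thickness_mm = quartz_thickness_mm,
                 L = as.integer(L), d_f_um = d_f_um, va1 = va1,
                 hydration_surface = hydration_surface,
                 hydration_bottom = hydration_bottom,
                 hydration_method = hydration_method,
                 incidence_angle_deg = incidence_angle_deg,
                 polarization = polarization,
                 eps_dry = eps_dry, water_model = water_model,
                 bulk_hydration = bulk_hydration,
                 bulk_spectrum = bulk_spectrum,
                 include_quartz_layer = include_quartz_layer),
            class = "stack_config")
}

#' @export
print.stack_config <- function(x, ...) {
  cat(sprintf(paste0("<stack_config> quartz n=%.3g | %d ridge layers x %.3g um",
                     " (total %.3g um), V_A1=%.3g | hydration %.2f -> %.2f\n"),
              x$quartz_n, x$L, x$d_f_um, x$L * x$d_f_um, x$va1,
              x$hydration_surface, x$hydration_bottom))
  invisible(x)
}

# Per-layer skin (no-air) permittivities and fixed media for a configuration;
# everything that does not depend on va1, so repeated reflectance evaluations
# during fitting only redo the air mixing and the Fresnel recursion.
stack_template <- function(config, grid, d_f_um = config$d_f_um,
                           L = config$L) {
  if (!is_freq_grid(grid)) grid <- frequency_grid(grid)
  water <- debye_permittivity(config$water_model, grid, label = "water")
  dry <- material_spectrum(grid, rep(complex(real = config$eps_dry),
                                     length(grid)), label = "dry background")
  total <- L * d_f_um
  centres <- (seq_len(L) - 0.5) * d_f_um
  h <- hydration_profile(centres, total,
                         surface_h = config$hydration_surface,
                         bottom_h = config$hydration_bottom,
                         method = config$hydration_method)
  skin <- matrix(0i, nrow = length(grid), ncol = L)
  for (N in seq_len(L))
    skin[, N] <- skin_permittivity(h[N], water, dry)$eps
  bulk <- if (!is.null(config$bulk_spectrum)) {
    if (!same_grid(config$bulk_spectrum$grid, grid))
      stop("bulk_spectrum grid does not match the requested grid",
           call. = FALSE)
    config$bulk_spectrum$eps
  } else {
    skin_permittivity(config$bulk_hydration, water, dry)$eps
  }
  list(grid = grid, L = L, d_f_um = d_f_um,
       eps_quartz = rep(complex(real = config$quartz_n^2), length(grid)),
       eps_air = rep(complex(real = 1), length(grid)),
       cbrt_skin = ccbrt(skin),          # length(grid) x L
       cbrt_air = ccbrt(complex(real = 1)),
       eps_bulk = bulk,
       hydration = h,
       angle_rad = config$incidence_angle_deg * pi / 180,
       polarization = config$polarization,
       include_quartz_layer = isTRUE(config$include_quartz_layer),
       quartz_d_um = config$quartz_thickness_mm * 1000)
}

# Layer list (eps vectors + thicknesses) for a template at a given va1.
template_layers <- function(tmpl, va1) {
  va <- air_fraction_profile(va1, tmpl$L)
  layers <- vector("list", tmpl$L + 2L + tmpl$include_quartz_layer)
  i <- 1L
  if (tmpl$include_quartz_layer) {
    layers[[i]] <- list(eps = tmpl$eps_air, d_um = Inf, label = "air")
    i <- i + 1L
    layers[[i]] <- list(eps = tmpl$eps_quartz, d_um = tmpl$quartz_d_um,
                        label = "quartz window")
  } else {
    layers[[i]] <- list(eps = tmpl$eps_quartz, d_um = Inf,
                        label = "quartz window")
  }
  for (N in seq_len(tmpl$L)) {
    i <- i + 1L
    eps <- ((1 - va[N]) * tmpl$cbrt_skin[, N] + va[N] * tmpl$cbrt_air)^3
    layers[[i]] <- list(eps = eps, d_um = tmpl$d_f_um,
                        label = sprintf("ridge layer %d (V_A=%.3f)", N, va[N]))
  }
  layers[[i + 1L]] <- list(eps = tmpl$eps_bulk, d_um = Inf, label = "bulk skin")
  layers
}

#' Build the layered ridge model
#'
#' Assembles the full stratified system for a configuration: the quartz
#' incidence medium, `L` skin-air effective-medium ridge layers (air fraction
#' from [air_fraction_profile()], skin hydration from [hydration_profile()]
#' sampled at each layer's centre depth `(N - 1/2) d_f`, mixed by
#' [lll_mix()]), and the bulk skin half-space.
#'
#' @param config A [stack_config()].
#' @param grid A [frequency_grid()].
#' @return An object of class `"ridge_stack"`: list with `layers` (each a
#'   list `eps`, `d_um`, `label`; half-spaces have `d_um = Inf`), `grid`,
#'   `config`, and the per-layer `air_fractions` and `hydration`.
#' @examples
#' st <- build_stack(stack_config(va1 = 0.5), frequency_grid(seq(0, 2, 0.1)))
#' @export
build_stack <- function(config, grid) {
  stopifnot(inherits(config, "stack_config"))
  tmpl <- stack_template(config, grid)
  structure(list(layers = template_layers(tmpl, config$va1),
                 grid = tmpl$grid, config = config,
                 air_fractions = air_fraction_profile(config$va1, config$L),
                 hydration = tmpl$hydration),
            class = "ridge_stack")
}

#' @export
print.ridge_stack <- function(x, ...) {
  cat(sprintf("<ridge_stack> %d media on %d frequencies\n",
              length(x$layers), length(x$grid)))
  for (l in x$layers) {
    d <- if (is.infinite(l$d_um)) "half-space" else sprintf("%7.2f um", l$d_um)
    cat(sprintf("  %-28s %s\n", l$label, d))
  }
  invisible(x)
}
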