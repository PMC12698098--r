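# Complex reflectance of the stratified stack: the production path is the
# recursive Fresnel relation; a characteristic-matrix (transfer-matrix)
# implementation is kept as an independent oracle.
#
# Convention e^{-iwt}: passive eps has Im >= 0, a layer contributes a
# round-trip factor e^{+2i delta}, and the normal component of the complex
# wavevector q = sqrt(eps - eps_in sin^2 theta) takes the branch Im(q) >= 0
# so transmitted waves decay into lossy media.

# branch-fixed normal wavevector component (n cos theta)
q_normal <- function(eps, kx2) {
  q <- sqrt(as.complex(eps) - kx2)
  flip <- Im(q) < 0 | (Im(q) == 0 & Re(q) < 0)
  q[flip] <- -q[flip]
  q
}

eta_pol <- function(q, eps, polarization) {
  if (polarization == "s") q else eps / q
}

#' Single-interface Fresnel reflection coefficient
#'
#' Reflection coefficient of the interface between two half-spaces, with
#' complex Snell refraction for oblique incidence. For p polarization the
#' coefficient is expressed in the admittance convention `r = (eta_a -
#' eta_b)/(eta_a + eta_b)` with `eta = eps/q`, so s and p coincide exactly at
#' normal incidence.
#'
#' @param eps_a,eps_b Complex permittivities (scalars or equal-length
#'   vectors) of the incidence and transmission media.
#' @param angle Angle of incidence in medium a, radians.
#' @param polarization `"s"` or `"p"`.
#' @return Complex reflection coefficient(s).
#' @examples
#' interface_coefficient(1, 1.98^2)  # (1 - 1.98)/(1 + 1.98)
#' @export
interface_coefficient <- function(eps_a, eps_b, angle = 0,
                                  polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  eps_a <- as.complex(eps_a); eps_b <- as.complex(eps_b)
  kx2 <- eps_a * sin(angle)^2
  qa <- q_normal(eps_a, kx2); qb <- q_normal(eps_b, kx2)
  ea <- eta_pol(qa, eps_a, polarization)
  eb <- eta_pol(qb, eps_b, polarization)
  (ea - eb) / (ea + eb)
}

#' Phase thickness of an internal layer
#'
#' The one-way optical phase `delta = (2 pi / lambda) * n * d * cos(theta)`
#' accumulated across a finite layer, evaluated with the layer's own complex
#' index and internal propagation angle (via the conserved transverse
#' wavevector of the incidence medium).
#'
#' @param layer A list with fields `eps` (complex permittivity, scalar or
#'   one value per frequency) and `d_um` (thickness, micrometres); a
#'   half-space (`d_um = Inf`) is an error.
#' @param frequency_THz Frequencies in THz.
#' @param angle Angle of incidence in the incidence medium, radians.
#' @param eps_incidence Permittivity of the incidence medium (for Snell);
#'   irrelevant at normal incidence.
#' @return Complex phase(s) in radians, `Im >= 0` for passive layers.
#' @export
phase_thickness <- function(layer, frequency_THz, angle = 0,
                            eps_incidence = 1) {
  if (is.null(layer$d_um) || !is.finite(layer$d_um))
    stop("phase thickness is undefined for a half-space", call. = FALSE)
  kx2 <- as.complex(eps_incidence) * sin(angle)^2
  q <- q_normal(layer$eps, kx2)
  2 * pi * frequency_THz * layer$d_um * q / c_um_ps()
}

#' Reflectance spectrum container
#'
#' @param grid A [frequency_grid()].
#' @param r Complex reflection coefficients, one per frequency; `|r|` may
#'   not exceed 1 beyond 1e-9 (passive stack).
#' @return An object of class `"reflectance_spectrum"` with fields `grid`, `r`.
#' @export
reflectance_spectrum <- function(grid, r) {
  if (!is_freq_grid(grid)) grid <- frequency_grid(grid)
  r <- as.complex(r)
  if (length(r) != length(grid))
    stop("r length must match the frequency grid", call. = FALSE)
  if (any(Mod(r) > 1 + 1e-9))
    stop("|r| > 1: stack is not passive under the stated convention",
         call. = FALSE)
  structure(list(grid = grid, r = r), class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %d frequencies, |r| in [%.4g, %.4g]\n",
              length(x$grid), min(Mod(x$r)), max(Mod(x$r))))
  invisible(x)
}

# normalize any stack-like object to list(layers=..., grid=...)
as_layer_stack <- function(stack) {
  if (inherits(stack, "ridge_stack"))
    return(list(layers = stack$layers, grid = stack$grid))
  if (is.list(stack) && !is.null(stack$layers) && !is.null(stack$grid))
    return(list(layers = stack$layers, grid = frequency_grid(stack$grid)))
  stop("stack must be a ridge_stack or a list with fields 'layers' and 'grid'",
       call. = FALSE)
}

stack_eps_matrix <- function(ls) {
  nf <- length(ls$grid)
  vapply(ls$layers, function(l) {
    e <- as.complex(l$eps)
    if (length(e) == 1L) rep(e, nf) else e
  }, complex(nf))
}

#' Total reflection coefficient by the recursive Fresnel relation
#'
#' Evaluates `r_i = (r_{i,i+1} + r_{i+1} e^{2 i delta_{i+1}}) /
#' (1 + r_{i,i+1} r_{i+1} e^{2 i delta_{i+1}})` bottom-up from the deepest
#' interface, returning the overall coefficient seen from the incidence
#' medium at every grid frequency. `delta_{i+1}` is the phase thickness of
#' the layer being stepped across (the i+1-th medium), computed from that
#' layer's own complex index and internal angle.
#'
#' @param stack A [build_stack()] result, or any list with fields `layers`
#'   (each `eps`, `d_um`) and `grid`; the first and last media are
#'   half-spaces.
#' @param angle Angle of incidence in the incidence medium, radians.
#' @param polarization `"s"` or `"p"`.
#' @return A [reflectance_spectrum()].
#' @seealso [transfer_matrix_reflectance()] for the independent
#'   characteristic-matrix implementation.
#' @export
recursive_reflectance <- function(stack, angle = 0,
                                  polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  ls <- as_layer_stack(stack)
  n_media <- length(ls$layers)
  if (n_media < 2L)
    stop("stack must contain at least two media", call. = FALSE)
  eps <- stack_eps_matrix(ls)
  f <- as.numeric(ls$grid)
  kx2 <- eps[, 1L] * sin(angle)^2
  q <- eps
  eta <- eps
  for (j in seq_len(n_media)) {
    q[, j] <- q_normal(eps[, j], kx2)
    eta[, j] <- eta_pol(q[, j], eps[, j], polarization)
  }
  r <- (eta[, n_media - 1L] - eta[, n_media]) /
       (eta[, n_media - 1L] + eta[, n_media])
  if (n_media > 2L) {
    for (i in seq(n_media - 2L, 1L)) {
      d <- ls$layers[[i + 1L]]$d_um
      delta <- 2 * pi * f * d * q[, i + 1L] / c_um_ps()
      ph <- exp(2i * delta)
      rij <- (eta[, i] - eta[, i + 1L]) / (eta[, i] + eta[, i + 1L])
      r <- (rij + r * ph) / (1 + rij * r * ph)
    }
  }
  reflectance_spectrum(ls$grid, r)
}

#' Total reflection coefficient by 2x2 characteristic matrices
#'
#' Independent oracle for [recursive_reflectance()]: multiplies the
#' characteristic matrix `[[cos d, -i sin d / eta], [-i eta sin d, cos d]]` of
#' every internal layer and forms `r = (eta_in B - C)/(eta_in B + C)` with
#' `(B, C)' = M (1, eta_out)'`.
#'
#' @inheritParams recursive_reflectance
#' @return A [reflectance_spectrum()].
#' @export
transfer_matrix_reflectance <- function(stack, angle = 0,
                                        polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  ls <- as_layer_stack(stack)
  n_media <- length(ls$layers)
  if (n_media < 2L)
    stop("stack must contain at least two media", call. = FALSE)
  eps <- stack_eps_matrix(ls)
  f <- as.numeric(ls$grid)
  nf <- length(f)
  kx2 <- eps[, 1L] * sin(angle)^2
  m11 <- rep(1 + 0i, nf); m12 <- rep(0i, nf)
  m21 <- rep(0i, nf);     m22 <- rep(1 + 0i, nf)
  if (n_media > 2L) {
    for (j in seq(2L, n_media - 1L)) {
      qj <- q_normal(eps[, j], kx2)
      etaj <- eta_pol(qj, eps[, j], polarization)
      delta <- 2 * pi * f * ls$layers[[j]]$d_um * qj / c_um_ps()
      cd <- cos(delta); sd <- sin(delta)
      a <- cd; b <- -1i * sd / etaj; cc <- -1i * etaj * sd; dd <- cd
      t11 <- m11 * a + m12 * cc
      t12 <- m11 * b + m12 * dd
      t21 <- m21 * a + m22 * cc
      t22 <- m21 * b + m22 * dd
      m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
    }
  }
  q_in <- q_normal(eps[, 1L], kx2)
  q_out <- q_normal(eps[, n_media], kx2)
  eta_in <- eta_pol(q_in, eps[, 1L], polarization)
  eta_out <- eta_pol(q_out, eps[, n_media], polarization)
  B <- m11 + m12 * eta_out
  C <- m21 + m22 * eta_out
  reflectance_spectrum(ls$grid, (eta_in * B - C) / (eta_in * B + C))
}

#' Write a reflectance spectrum as CSV
#'
#' Columns `frequency_THz, r_real, r_imag`.
#'
#' @param x A [reflectance_spectrum()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_reflectance <- function(x, path) {
  stopifnot(inherits(x, "reflectance_spectrum"))
  utils::write.csv(data.frame(frequency_THz = as.numeric(x$grid),
                              r_real = Re(x$r), r_imag = Im(x$r)),
                   path, row.names = FALSE)
  invisible(path)
}
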