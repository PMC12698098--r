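# Minimal 1-D Bayesian optimisation with a Gaussian-process surrogate and
# expected-improvement acquisition.  Deliberately small: squared-exponential
# kernel, lengthscale chosen each iteration by marginal likelihood over a
# short candidate list, EI maximised on a dense grid.  Deterministic given
# the seed.

gp_sqexp <- function(x1, x2, lengthscale) {
  d <- outer(x1, x2, "-") / lengthscale
  exp(-0.5 * d * d)
}

# log marginal likelihood of standardized y under SE kernel + nugget
gp_loglik <- function(x, y, lengthscale, nugget) {
  K <- gp_sqexp(x, x, lengthscale) + diag(nugget, length(x))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  -0.5 * sum(y * alpha) - sum(log(diag(ch))) - 0.5 * length(y) * log(2 * pi)
}

# posterior mean and sd at xs
gp_posterior <- function(x, y, xs, lengthscale, nugget) {
  K <- gp_sqexp(x, x, lengthscale) + diag(nugget, length(x))
  ch <- chol(K)
  Ks <- gp_sqexp(xs, x, lengthscale)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  mu <- drop(Ks %*% alpha)
  v <- forwardsolve(t(ch), t(Ks))
  s2 <- pmax(1 - colSums(v * v), 1e-12)
  list(mu = mu, sd = sqrt(s2))
}

#' Minimise a 1-D function by Gaussian-process Bayesian optimisation
#'
#' Space-filling initial design, then expected-improvement iterations with a
#' squared-exponential Gaussian process refit at every step (lengthscale by
#' marginal likelihood over a small candidate set). All randomness is
#' governed by `seed`; two calls with identical arguments give identical
#' results.
#'
#' @param fn Scalar function of one variable to minimise.
#' @param lower,upper Search bounds (`lower <= upper`; equal bounds return
#'   that point immediately).
#' @param n_init Number of initial design points (default 10).
#' @param n_iter Number of EI iterations after the design (default 40).
#' @param init Optional numeric vector of extra starting points (e.g. a
#'   warm start from a previous fit), evaluated before the design.
#' @param seed Integer seed.
#' @param tol_x Duplicate-proposal guard: proposals closer than `tol_x` times
#'   the range to an existing point are replaced by the largest-gap midpoint.
#' @return List with `x_best`, `y_best`, `x` and `y` (all evaluations),
#'   `converged` (logical; `FALSE` flags a best-so-far return after a
#'   degenerate surrogate), `n_eval`.
#' @export
bayes_optimize <- function(fn, lower, upper, n_init = 10L, n_iter = 40L,
                           init = NULL, seed = 1L, tol_x = 1e-3) {
  stopifnot(is.function(fn), lower <= upper)
  if (upper - lower < .Machine$double.eps * max(1, abs(lower))) {
    y0 <- fn(lower)
    return(list(x_best = lower, y_best = y0, x = lower, y = y0,
                converged = TRUE, n_eval = 1L))
  }
  rng <- upper - lower
  xs_grid <- seq(lower, upper, length.out = 512L)
  x <- with_seed(seed, {
    jitter <- stats::runif(n_init, -0.5, 0.5) / n_init
    pts <- lower + rng * ((seq_len(n_init) - 0.5) / n_init + jitter)
    pmin(pmax(pts, lower), upper)
  })
  if (length(init)) x <- unique(c(pmin(pmax(init, lower), upper), x))
  y <- vapply(x, fn, 0)
  ok <- TRUE
  for (it in seq_len(n_iter)) {
    mu_y <- mean(y); sd_y <- stats::sd(y)
    if (!is.finite(sd_y) || sd_y <= 0) { ok <- FALSE; break }
    z <- (y - mu_y) / sd_y
    u <- (x - lower) / rng
    ug <- (xs_grid - lower) / rng
    cand_ls <- c(0.05, 0.1, 0.2, 0.4)
    ll <- vapply(cand_ls, function(l) gp_loglik(u, z, l, 1e-8), 0)
    ls <- cand_ls[which.max(ll)]
    post <- gp_posterior(u, z, ug, ls, 1e-8)
    zbest <- min(z)
    imp <- zbest - post$mu
    s <- post$sd
    ei <- imp * stats::pnorm(imp / s) + s * stats::dnorm(imp / s)
    # keep proposals away from existing points
    mind <- vapply(ug, function(g) min(abs(g - u)), 0)
    ei[mind < tol_x] <- -Inf
    if (all(!is.finite(ei))) break
    x_new <- xs_grid[which.max(ei)]
    y_new <- fn(x_new)
    x <- c(x, x_new); y <- c(y, y_new)
  }
  i <- which.min(y)
  list(x_best = x[i], y_best = y[i], x = x, y = y,
       converged = ok, n_eval = length(y))
}
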