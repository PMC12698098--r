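# Shared fixtures, built in code and cached per test run.

.fix_env <- new.env(parent = emptyenv())

fix <- function(name, expr) {
  if (!exists(name, envir = .fix_env)) assign(name, force(expr), .fix_env)
  get(name, envir = .fix_env)
}

# coarse grid for dielectric/stack checks
tiny_grid <- function() frequency_grid(seq(0, 3, by = 0.25))

# short reference pulse: 25.6 ps record, 5 THz Nyquist — fast unit tests
test_reference <- function() fix("ref256", make_reference_pulse(n = 256L,
                                                                dt_ps = 0.1))

# a short noiseless synthetic series (8 s at 2 Hz)
test_series_noiseless <- function() fix("gen0", {
  sc <- occlusion_scenario(duration_s = 8, rate_hz = 2, noise_sd_mV = 0)
  generate_series(sc, stack_config(), test_reference())
})

# random passive stack on a given grid: nl lossy internal layers
random_stack <- function(nl, grid) {
  layers <- c(
    list(list(eps = complex(real = runif(1, 1, 5)), d_um = Inf)),
    lapply(seq_len(nl), function(i)
      list(eps = complex(real = runif(1, 1, 8), imaginary = runif(1, 0, 3)),
           d_um = runif(1, 1, 200))),
    list(list(eps = complex(real = runif(1, 1, 8),
                            imaginary = runif(1, 0, 3)), d_um = Inf)))
  list(layers = layers, grid = grid)
}
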