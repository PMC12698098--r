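# Single-interface coefficients, phase thickness, and the equivalence of the
# recursive Fresnel relation with the characteristic-matrix oracle.

test_that("interface coefficient matches the closed form and limits", {
  expect_equal(interface_coefficient(4, 4), 0 + 0i)
  # air | quartz at normal incidence: (1 - 1.98)/(1 + 1.98)
  expect_equal(interface_coefficient(1, 1.98^2),
               complex(real = (1 - 1.98) / (1 + 1.98)), tolerance = 1e-12)
  # s and p coincide at normal incidence in the admittance convention
  ea <- complex(real = 2.3, imaginary = 0.4)
  eb <- complex(real = 6.1, imaginary = 1.2)
  expect_equal(interface_coefficient(ea, eb, 0, "s"),
               interface_coefficient(ea, eb, 0, "p"), tolerance = 1e-12)
})

test_that("phase thickness evaluates the quarter-wave and direct cases", {
  lam <- c_um_ps() / 1  # wavelength at 1 THz, um
  qw <- list(eps = 4 + 0i, d_um = lam / (4 * 2))
  expect_equal(phase_thickness(qw, 1), complex(real = pi / 2),
               tolerance = 1e-12)
  expect_equal(phase_thickness(list(eps = 4 + 0i, d_um = 0), 1), 0 + 0i)
  # n = 2, d = 75 um, f = 1 THz: 2*pi*2*75/lambda
  expect_equal(phase_thickness(list(eps = 4 + 0i, d_um = 75), 1),
               complex(real = 2 * pi * 2 * 75 / lam), tolerance = 1e-12)
  expect_error(phase_thickness(list(eps = 4 + 0i, d_um = Inf), 1),
               "half-space")
})

test_that("recursion base case equals the single-interface coefficient", {
  g <- frequency_grid(c(0.5, 1, 1.5))
  st <- list(layers = list(list(eps = 2 + 0i, d_um = Inf),
                           list(eps = complex(real = 5, imaginary = 1.5),
                                d_um = Inf)), grid = g)
  for (pol in c("s", "p")) for (ang in c(0, 0.4)) {
    r <- recursive_reflectance(st, ang, pol)$r
    expect_equal(r, interface_coefficient(rep(2 + 0i, 3),
                                          rep(complex(real = 5, imaginary = 1.5), 3),
                                          ang, pol), tolerance = 1e-14)
  }
})

test_that("a zero-thickness layer is a no-op anywhere in the stack", {
  g <- frequency_grid(seq(0.2, 2, by = 0.2))
  set.seed(303)
  for (k in 1:20) {
    st <- random_stack(sample(1:8, 1), g)
    r0 <- recursive_reflectance(st)$r
    pos <- sample(seq_len(length(st$layers) - 1L), 1)
    st2 <- st
    st2$layers <- append(st$layers,
                         list(list(eps = complex(real = runif(1, 1, 8),
                                                 imaginary = runif(1, 0, 2)),
                                   d_um = 0)), after = pos)
    expect_equal(recursive_reflectance(st2)$r, r0, tolerance = 1e-12)
  }
})

test_that("recursive and transfer-matrix reflectances agree on random stacks", {
  g <- frequency_grid(seq(0, 3, by = 0.1))
  set.seed(404)
  worst <- 0
  for (k in 1:30) {
    st <- random_stack(sample(1:30, 1), g)
    ang <- runif(1, 0, 0.6)
    pol <- sample(c("s", "p"), 1)
    r1 <- recursive_reflectance(st, ang, pol)$r
    r2 <- transfer_matrix_reflectance(st, ang, pol)$r
    worst <- max(worst, max(Mod(r1 - r2)))
    expect_true(all(Mod(r1) <= 1 + 1e-9))
  }
  expect_lt(worst, 1e-10)
})

test_that("transfer matrix reproduces the quarter-wave antireflection null", {
  n1 <- 1; n3 <- 4; n2 <- sqrt(n1 * n3)
  g <- frequency_grid(c(0.5, 1, 1.5))
  d <- c_um_ps() / (1 * n2) / 4
  st <- list(layers = list(list(eps = n1^2 + 0i, d_um = Inf),
                           list(eps = n2^2 + 0i, d_um = d),
                           list(eps = n3^2 + 0i, d_um = Inf)), grid = g)
  rt <- transfer_matrix_reflectance(st)$r
  expect_lt(Mod(rt[2]), 1e-12)                         # null at design f
  expect_equal(Mod(rt[1]), Mod(rt[3]), tolerance = 1e-12)  # symmetry about it
})

test_that("lossless stack conserves energy: |r|^2 + impedance-weighted |t|^2 = 1", {
  # for a lossless symmetric two half-space system |r|^2 + (q2/q1)|t|^2 = 1
  g <- frequency_grid(c(0.5, 1))
  e1 <- 2.25 + 0i; e2 <- 9 + 0i
  r <- interface_coefficient(e1, e2)
  t <- 1 + r
  expect_equal(Mod(r)^2 + (sqrt(Re(e2)) / sqrt(Re(e1))) * Mod(t)^2, 1,
               tolerance = 1e-12)
})

test_that("reflectance is smooth in V_A1 and in layer thickness", {
  g <- frequency_grid(seq(0.2, 1.6, by = 0.2))
  cfg <- stack_config()
  vs <- seq(0.3, 0.5, by = 0.01)
  rs <- vapply(vs, function(v)
    Mod(recursive_reflectance(build_stack(stack_config(va1 = v), g))$r[4]), 0)
  # finite differences of a smooth curve vary slowly
  expect_lt(max(abs(diff(diff(rs)))), 1e-3)
  ds <- seq(2, 3, by = 0.05)
  rd <- vapply(ds, function(d)
    Mod(recursive_reflectance(build_stack(stack_config(d_f_um = d), g))$r[4]), 0)
  expect_lt(max(abs(diff(diff(rd)))), 1e-3)
})
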