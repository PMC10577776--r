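test_that("Hessian of model systems is exact, symmetric and warns off stationarity", {
  s <- make_harmonic(0.01)
  sys <- molecular_system(s)
  expect_equal(compute_hessian(sys), matrix(1e-4, 1, 1), ignore_attr = TRUE)
  # analytic vs finite-difference path on Morse
  m <- morse_nh()
  m_fd <- potential_surface(m$energy, m$gradient, hessian = NULL, dim = 1,
                            kind = "morse-fd")
  q <- 0.15
  Ha <- surface_hessian(m, q)
  Hf <- surface_hessian(m_fd, q)
  expect_lt(abs(Ha - Hf) / abs(Ha), 1e-6)
  # symmetrization contract: an asymmetric raw Hessian comes back symmetric
  asym <- potential_surface(function(q) 0, function(q) c(0, 0),
                            hessian = function(q) matrix(c(1, 2, 0, 1), 2, 2),
                            dim = 2)
  H <- surface_hessian(asym, c(0, 0))
  expect_identical(H, t(H))
  off <- molecular_system(m, coords = 0.4)
  expect_warning(compute_hessian(off), "not a stationary point")
})

test_that("mode analysis recovers model frequencies and flags imaginary modes", {
  s <- make_harmonic(c(0.01, 0.016))
  sys <- molecular_system(s)
  b <- normal_mode_analysis(compute_hessian(sys), sys)
  expect_equal(b$freq, c(0.01, 0.016), tolerance = 1e-6)
  expect_lt(max(abs(crossprod(b$modes) - diag(2))), 1e-10)
  # saddle point: one negative eigenvalue flagged, never dropped
  saddle <- potential_surface(function(q) 0.5 * (1e-4 * q[1]^2 - 2e-4 * q[2]^2),
                              function(q) c(1e-4 * q[1], -2e-4 * q[2]),
                              function(q) diag(c(1e-4, -2e-4)), dim = 2)
  bs <- normal_mode_analysis(compute_hessian(molecular_system(saddle)),
                             molecular_system(saddle))
  expect_equal(bs$n_modes, 2L)
  expect_equal(nrow(bs$imaginary), 1L)
  expect_error(normal_mode_analysis(matrix(c(0, 1e-3, 2e-3, 0), 2, 2),
                                    molecular_system(s)), "symmetric")
})

test_that("harmonic diatomic: one vibration at sqrt(2k/m), five projected modes", {
  k <- 0.1; ms <- 1837
  dia <- make_spring_cluster(rbind(c(0, 0, 0), c(2, 0, 0)),
                             masses = c(ms, ms),
                             bonds = matrix(c(1, 2), 1, 2), k = k)
  sys <- molecular_system(dia, coords = c(0, 0, 0, 2, 0, 0), masses = c(ms, ms))
  b <- normal_mode_analysis(compute_hessian(sys), sys)
  expect_equal(b$n_modes, 1L)
  expect_equal(b$n_projected, 5L)
  expect_equal(b$freq, sqrt(2 * k / ms), tolerance = 1e-6)
})

test_that("rigid translation changes no retained frequency", {
  ms <- c(29164, 1837, 1837)   # O-like + 2 H-like
  X0 <- rbind(c(0, 0, 0), c(1.8, 0, 0), c(-0.5, 1.7, 0))
  surf <- make_spring_cluster(X0, ms, bonds = rbind(c(1, 2), c(1, 3), c(2, 3)),
                              k = 0.2)
  f <- function(shift) {
    X <- sweep(X0, 2L, -shift)
    s <- make_spring_cluster(X, ms, bonds = rbind(c(1, 2), c(1, 3), c(2, 3)),
                             k = 0.2)
    sys <- molecular_system(s, coords = as.vector(t(X)), masses = ms)
    normal_mode_analysis(compute_hessian(sys), sys)$freq
  }
  expect_equal(f(c(0, 0, 0)), f(c(0.7, -1.2, 3.1)), tolerance = 1e-8)
})

test_that("normal-mode transforms round-trip and respect orthonormality", {
  s <- make_harmonic(c(0.01, 0.016))
  sys <- molecular_system(s)
  b <- normal_mode_analysis(compute_hessian(sys), sys)
  # equilibrium maps to the origin
  z <- cart_to_nm(b$q_eq, c(0, 0), b)
  expect_equal(z$q_nm, c(0, 0))
  set.seed(7)
  qr_ <- stats::rnorm(2); pr <- stats::rnorm(2)
  z <- cart_to_nm(qr_, pr, b)
  back <- nm_to_cart(z$q_nm, z$p_nm, b)
  expect_equal(back$q_cart, qr_, tolerance = 1e-12)
  expect_equal(back$p_cart, pr, tolerance = 1e-12)
  # displacement along mode column j reads as delta * e_j
  delta <- 0.3
  z <- cart_to_nm(b$q_eq + delta * b$modes[, 2], c(0, 0), b)
  expect_equal(z$q_nm, c(0, delta), tolerance = 1e-12)
  expect_error(cart_to_nm(1, 1, b), "dimension mismatch")
})

test_that("harmonic initial conditions quantize per-mode energies", {
  s <- make_harmonic(0.01)
  sys <- molecular_system(s)
  b <- normal_mode_analysis(compute_hessian(sys), sys)
  ic0 <- harmonic_initial_conditions(b, 0)
  expect_equal(ic0$p_nm, 0.1)
  ic1 <- harmonic_initial_conditions(b, 1)
  expect_equal(0.5 * sum(ic1$p_nm^2), 0.015)   # (3/2) h-bar omega
  expect_error(harmonic_initial_conditions(b, -1), "non-negative")
  # two-mode ZPE trajectory conserves E = (omega1 + omega2) / 2
  s2 <- make_harmonic(c(0.01, 0.016))
  sys2 <- molecular_system(s2)
  b2 <- normal_mode_analysis(compute_hessian(sys2), sys2)
  ic <- harmonic_initial_conditions(b2, 0)
  tr <- propagate(s2, ic$p_nm, ic$q_nm, dt = 10, n_steps = 300)
  expect_equal(ic$energy, 0.013)
  expect_lt(max(abs(tr$E - 0.013)) / 0.013, 1e-2)
})

test_that("nm_surface reproduces dynamics of the native surface", {
  c12 <- 3e-5
  s <- make_harmonic(c(0.01, 0.012), matrix(c(0, c12, c12, 0), 2, 2))
  sys <- molecular_system(s)
  b <- normal_mode_analysis(compute_hessian(sys), sys)
  nms <- nm_surface(s, b)
  # in the normal-mode frame the Hessian at equilibrium is diagonal
  H <- surface_hessian(nms, c(0, 0))
  expect_lt(abs(H[1, 2]), 1e-12)
  expect_equal(sort(diag(H)), sort(b$freq^2), tolerance = 1e-10)
})
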