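test_that("harmonic orbit closes and the monodromy follows cos/sin blocks", {
  w <- 0.01
  s <- make_harmonic(w)
  Tp <- 2 * pi / w
  dtv <- Tp / 6400
  tr <- propagate(s, p0 = sqrt(w), q0 = 0, dt = dtv, n_steps = 6400)
  n <- length(tr$time)
  amp <- sqrt(w) / w   # orbit amplitude in q
  expect_lt(abs(tr$q[n, ] - tr$q[1, ]) / amp, 1e-6)
  expect_lt(abs(tr$p[n, ] - tr$p[1, ]) / sqrt(w), 1e-6)
  # closed-form monodromy of the harmonic oscillator
  expect_lt(max(abs(tr$Mqq[1, 1, ] - cos(w * tr$time))), 5e-4)
  expect_lt(max(abs(tr$Mqp[1, 1, ] - sin(w * tr$time) / w)), 5e-2)
  expect_lt(max(abs(tr$Mpq[1, 1, ] + w * sin(w * tr$time))), 5e-6)
  # identity monodromy, zero action and zero phase at t = 0
  expect_equal(tr$Mqq[1, 1, 1], 1)
  expect_equal(tr$S[1], 0)
})

test_that("a system resting at the minimum stays there with zero action", {
  s <- make_harmonic(0.01)
  tr <- propagate(s, p0 = 0, q0 = 0, dt = 10, n_steps = 200)
  expect_true(all(tr$q == 0))
  expect_true(all(tr$S == 0))
})

test_that("monodromy stays symplectic to 1e-6 on harmonic and Morse at dt = 10", {
  for (s in list(make_harmonic(0.01), morse_nh())) {
    tr <- propagate(s, p0 = sqrt(if (s$kind == "morse") s$parameters$omega else 0.01),
                    q0 = 0, dt = 10, n_steps = 2500)
    expect_lt(max(symplectic_defect(tr)), 1e-6)
  }
})

test_that("harmonic ZPE action matches the closed form S = sin(2wt)/4", {
  tr <- ho_traj_fine()
  w <- 0.01
  # velocity Verlet runs at the renormalized frequency w (1 + (w dt)^2 / 24)
  w_eff <- w * (1 + (w * tr$dt)^2 / 24)
  expect_lt(max(abs(tr$S - sin(2 * w_eff * tr$time) / 4)), 1e-2)
  # secular part of S + E t grows as (hbar w / 2) t
  n <- length(tr$time)
  Tt <- tr$time[n]
  expect_equal((tr$S[n] + tr$E[1] * Tt - sin(2 * w * Tt) / 4) / Tt, w / 2,
               tolerance = 1e-4)
})

test_that("dt-halving shows the second-order energy-fluctuation signature", {
  m <- morse_nh()
  w <- m$parameters$omega
  fl <- vapply(c(10, 5), function(dtv) {
    propagate(m, sqrt(w), 0, dt = dtv,
              n_steps = round(25000 / dtv))$metadata$energy_fluctuation
  }, numeric(1))
  expect_gt(fl[1] / fl[2], 3)
  expect_lt(fl[1] / fl[2], 5)
})

test_that("propagation rejects bad steps, divergent forces and drifting energy", {
  s <- make_harmonic(0.01)
  expect_error(propagate(s, 0.1, 0, dt = -1), "dt must be positive")
  # unstable step (omega * dt > 2): fluctuation guard trips with step index
  expect_error(propagate(s, 0.1, 0, dt = 250, n_steps = 50),
               "fluctuation.*step")
  bad <- potential_surface(function(q) q^4, function(q) c(NaN), dim = 1)
  expect_error(propagate(bad, 0.1, 0.1, dt = 1, n_steps = 5), "non-finite force")
})

test_that("Herman-Kluk phase follows -wt/2 on the harmonic with matched width", {
  tr <- ho_traj_fine()
  expect_equal(tr$phi[1], 0)
  expect_equal(tr$hk_modulus[1], 1)
  expect_lt(max(abs(tr$phi + 0.01 * tr$time / 2)), 5e-3)
  expect_lt(max(abs(tr$hk_modulus - 1)), 1e-3)
})

test_that("free-particle prefactor grows in modulus with bounded phase", {
  free <- potential_surface(function(q) 0, function(q) 0,
                            function(q) matrix(0, 1, 1), dim = 1)
  tr <- propagate(free, p0 = 0.05, q0 = 0, dt = 10, n_steps = 500,
                  fluct_tol = Inf)
  tr <- hk_prefactor_phase(tr, gamma = 1)
  expect_true(all(diff(tr$hk_modulus) > 0))
  expect_true(all(abs(tr$phi) <= pi / 4 + 1e-12))
  # analytic check: |C_t|^2 = sqrt(1 + (gamma t / 2)^2)
  expect_equal(tr$hk_modulus^2, sqrt(1 + (tr$time / 2)^2), tolerance = 1e-10)
})

test_that("prefactor phase requires valid widths and flags determinant zeros", {
  tr <- propagate(make_harmonic(0.01), 0.1, 0, dt = 10, n_steps = 20)
  expect_error(hk_prefactor_phase(tr, gamma = -1), "positive")
  expect_error(hk_prefactor_phase(tr, gamma = c(1, 2)), "length")
})

test_that("trajectories round-trip through the plain-text container", {
  s <- make_harmonic(c(0.01, 0.016))
  tr <- propagate(s, sqrt(c(0.01, 0.016)), c(0, 0), dt = 10, n_steps = 40)
  tr <- hk_prefactor_phase(tr, gamma = c(0.01, 0.016))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$q, tr$q, ignore_attr = TRUE)
  expect_equal(back$p, tr$p, ignore_attr = TRUE)
  expect_equal(back$Mqp, tr$Mqp)
  expect_equal(back$S, tr$S)
  expect_equal(back$phi, tr$phi)
  expect_equal(back$dt, tr$dt)
})
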