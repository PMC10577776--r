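# identity-basis helper: treat surface coordinates themselves as the modes
identity_basis <- function(freqs) {
  structure(list(q_eq = numeric(length(freqs)), freq = freqs,
                 modes = diag(length(freqs)), n_modes = length(freqs),
                 masses = rep(1, length(freqs)),
                 imaginary = tibble::tibble(), n_projected = 0L,
                 cartesian = FALSE),
            class = "normal_mode_basis")
}

test_that("greedy partition follows coupling strength with deterministic ties", {
  # no couplings: all singletons
  s0 <- make_harmonic(c(0.01, 0.012, 0.014))
  b0 <- identity_basis(c(0.01, 0.012, 0.014))
  p0 <- partition_modes(b0, s0, max_size = 2, threshold = 1e-8)
  expect_equal(lapply(p0, function(x) x$indices), list(1L, 2L, 3L))
  # two modes coupled above threshold join
  C <- matrix(0, 2, 2); C[1, 2] <- C[2, 1] <- 3e-5
  s2 <- make_harmonic(c(0.01, 0.012), C)
  p2 <- partition_modes(identity_basis(c(0.01, 0.012)), s2,
                        max_size = 2, threshold = 1e-6)
  expect_equal(lapply(p2, function(x) x$indices), list(c(1L, 2L)))
  # chain a-b strong, b-c weak, max_size 2: {a,b}, {c}
  C3 <- matrix(0, 3, 3)
  C3[1, 2] <- C3[2, 1] <- 5e-5
  C3[2, 3] <- C3[3, 2] <- 1e-5
  s3 <- make_harmonic(c(0.01, 0.012, 0.014), C3)
  p3 <- partition_modes(identity_basis(c(0.01, 0.012, 0.014)), s3,
                        max_size = 2, threshold = 1e-6)
  expect_equal(lapply(p3, function(x) x$indices), list(c(1L, 2L), 3L))
  # partition covers every mode exactly once
  idx <- sort(unlist(lapply(p3, function(x) x$indices)))
  expect_equal(idx, 1:3)
})

test_that("displaced-Hessian probing detects cubic coupling invisible at equilibrium", {
  h <- make_hbond_mimic(coupling = 6e-7)
  b <- identity_basis(c(h$parameters$omega_stretch, h$parameters$omega_bath))
  p_eq <- partition_modes(b, h, max_size = 2, threshold = 1e-9)
  expect_equal(lapply(p_eq, function(x) x$indices), list(1L, 2L))
  p_disp <- partition_modes(b, h, max_size = 2, threshold = 1e-9,
                            displacement = 1)
  expect_equal(lapply(p_disp, function(x) x$indices), list(c(1L, 2L)))
})

test_that("subspace projection on separable surfaces equals the 1D spectrum", {
  tr2 <- ho2_traj()
  grid <- seq(800, 1400, 1)
  ref1 <- single_ref(sqrt(0.01), 0.01)
  s1 <- make_harmonic(0.01)
  tr1 <- propagate(s1, sqrt(0.01), 0, dt = 5, n_steps = 5000)
  tr1 <- hk_prefactor_phase(tr1, gamma = 0.01)
  target <- ta_scivr_spectrum(tr1, ref1, grid = grid)
  for (pm in c("difference", "clamped")) {
    dsp <- dc_spectrum(tr2, 1, ref1, grid = grid, potential_mode = pm)
    expect_lt(max(abs(dsp$intensity - target$intensity)) / max(target$intensity),
              1e-8)
  }
})

test_that("the full-space subspace reproduces ta_scivr_spectrum exactly", {
  tr2 <- ho2_traj()
  refF <- single_ref(sqrt(c(0.01, 0.016)), c(0.01, 0.016))
  grid <- seq(2600, 3100, 1)
  tsp <- ta_scivr_spectrum(tr2, refF, grid = grid)
  for (pm in c("difference", "clamped")) {
    dsp <- dc_spectrum(tr2, c(1, 2), refF, grid = grid, potential_mode = pm)
    expect_lt(max(abs(dsp$intensity - tsp$intensity)) / max(tsp$intensity), 1e-10)
  }
})

test_that("harmonic subspace peaks sit at the exact subspace levels", {
  tr2 <- ho2_traj()
  # mode 2 subspace, parity -1 on its fundamental: E = 3/2 * omega_2
  ref <- reference_state(c(1, -1),
                         list(coherent_state(sqrt(0.016), 0, 0.016),
                              coherent_state(-sqrt(0.016), 0, 0.016)))
  dsp <- dc_spectrum(tr2, 2, ref, grid = seq(5000, 5600, 1))
  pk <- pick_peaks(dsp, 0.5)
  # velocity Verlet renormalizes the frequency by (1 + (w dt)^2/24) at dt = 5
  expect_lt(abs(pk$position[1] - au_to_wavenumber(1.5 * 0.016)), 3)
  expect_lt(spectrum_meta(dsp)$max_symplectic_defect, 1e-8)
})

test_that("stretch-subspace projection shows the same red shift as the full space", {
  # subspace spectra exclude the bath ZPE, so the comparable quantity is the
  # stretch fundamental transition E1 - E0, not the absolute peak position
  strongest <- function(sp) {
    pk <- pick_peaks(sp, 0.5)
    pk$position[which.max(pk$height)]
  }
  transition_pair <- function(coupling) {
    h <- make_hbond_mimic(coupling = coupling)
    w <- c(h$parameters$omega_stretch, h$parameters$omega_bath)
    tr <- propagate(h, sqrt(w), c(0, 0), dt = 10, n_steps = 2500)
    tr <- hk_prefactor_phase(tr, gamma = w)
    ref1 <- function(par) reference_state(c(1, par),
      list(coherent_state(sqrt(w[1]), 0, w[1]),
           coherent_state(-sqrt(w[1]), 0, w[1])))
    refF <- function(par) reference_state(c(1, par),
      list(coherent_state(sqrt(w), c(0, 0), w),
           coherent_state(sqrt(w) * c(-1, 1), c(0, 0), w)))
    sub <- strongest(dc_spectrum(tr, 1, ref1(-1), grid = seq(4200, 5600, 1))) -
      strongest(dc_spectrum(tr, 1, ref1(+1), grid = seq(1300, 2400, 1)))
    full <- strongest(ta_scivr_spectrum(tr, refF(-1), grid = seq(4200, 5600, 1))) -
      strongest(ta_scivr_spectrum(tr, refF(+1), grid = seq(1300, 2400, 1)))
    c(sub = sub, full = full)
  }
  p0 <- transition_pair(0)
  pc <- transition_pair(6e-7)
  expect_lt(pc["sub"], p0["sub"])          # projected spectrum red-shifts
  expect_lt(pc["full"], p0["full"])        # in the same direction as full space
  # projection error below the finite-T linewidth
  expect_lt(abs(pc["sub"] - pc["full"]), 49)
})

test_that("subspace validation catches malformed inputs", {
  tr2 <- ho2_traj()
  expect_error(mode_subspace(c(1, 1)), "unique")
  expect_error(dc_spectrum(tr2, 3, single_ref(0.1, 0.01)), "exceed")
  expect_error(dc_spectrum(tr2, c(1, 2), single_ref(0.1, 0.01)),
               "does not match the subspace")
})
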