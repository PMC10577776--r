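test_that("coherent-state overlap matches the closed Gaussian form", {
  g <- coherent_state(0.3, -0.2, 1.5)
  expect_equal(coherent_overlap(g, g), 1 + 0i)
  # 1D, Gamma = 1, centers two apart in position: |overlap| = exp(-1)
  a <- coherent_state(0, 0, 1); b <- coherent_state(0, 2, 1)
  expect_equal(Mod(coherent_overlap(a, b)), exp(-1))
  # same separation in momentum (Gamma^-1 weighting)
  expect_equal(Mod(coherent_overlap(coherent_state(0, 0, 1),
                                    coherent_state(2, 0, 1))), exp(-1))
  far <- coherent_state(0, 15, 1)
  expect_lt(Mod(coherent_overlap(a, far)), 1e-10)
  expect_error(coherent_overlap(a, coherent_state(0, 0, 2)), "width matrices")
  expect_error(coherent_overlap(a, coherent_state(c(0, 0), c(0, 0), 1)),
               "dimension")
  # property: |overlap| never exceeds 1
  set.seed(11)
  for (i in 1:50) {
    x <- coherent_state(stats::rnorm(2), stats::rnorm(2), c(0.5, 2))
    y <- coherent_state(stats::rnorm(2), stats::rnorm(2), c(0.5, 2))
    expect_lte(Mod(coherent_overlap(x, y)), 1 + 1e-12)
  }
})

test_that("reference states validate their terms", {
  g <- coherent_state(0, 0, 1)
  expect_error(reference_state(numeric(0), list()), "at least one")
  expect_error(reference_state(c(0, 0), list(g, g)), "not all coefficients")
  expect_error(reference_state(1, list(g, g)), "one coefficient per")
  expect_error(reference_state(c(1, 1), list(g, coherent_state(0, 0, 2))),
               "same width")
})

test_that("TA SCIVR is exact on the harmonic oscillator", {
  tr <- ho_traj_fine()
  w <- 0.01
  # parity +1 amplifies even levels, parity -1 the odd ones
  even <- ta_scivr_spectrum(tr, parity_ref_1d(w, +1), grid = seq(700, 6000, 1))
  odd <- ta_scivr_spectrum(tr, parity_ref_1d(w, -1), grid = seq(700, 6000, 1))
  pe <- pick_peaks(even, 0.05)
  po <- pick_peaks(odd, 0.5)
  lev <- au_to_wavenumber((0:2 + 0.5) * w)
  expect_true(peak_near(pe, lev[1], 1))
  expect_true(peak_near(po, lev[2], 1))
  expect_true(peak_near(pe, lev[3], 1))
})

test_that("MC parity references suppress the opposite-parity progression", {
  tr <- ho_traj_fine()
  w <- 0.01
  grid <- seq(700, 6000, 1)
  odd <- ta_scivr_spectrum(tr, parity_ref_1d(w, -1), grid = grid)
  at <- function(s, E) s$intensity[which.min(abs(s$wavenumber - E))]
  zpe <- au_to_wavenumber(0.5 * w); fund <- au_to_wavenumber(1.5 * w)
  expect_gt(at(odd, fund) / at(odd, zpe), 1e2)
  even <- ta_scivr_spectrum(tr, parity_ref_1d(w, +1), grid = grid)
  expect_gt(at(even, zpe) / at(even, fund), 1e2)
})

test_that("parity spectra sum to twice the single-state spectra (bilinearity)", {
  tr <- ho_traj_fine()
  w <- 0.01
  grid <- seq(900, 3500, 2)
  odd <- ta_scivr_spectrum(tr, parity_ref_1d(w, -1), grid = grid)
  even <- ta_scivr_spectrum(tr, parity_ref_1d(w, +1), grid = grid)
  s1 <- ta_scivr_spectrum(tr, single_ref(sqrt(w), w), grid = grid)
  s2 <- ta_scivr_spectrum(tr, single_ref(-sqrt(w), w), grid = grid)
  lhs <- odd$intensity + even$intensity
  rhs <- 2 * (s1$intensity + s2$intensity)
  expect_lt(max(abs(lhs - rhs)) / max(rhs), 1e-10)
})

test_that("a reference orthogonal to the visited region gives a null spectrum", {
  tr <- ho_traj_fine()
  far <- reference_state(1, list(coherent_state(0, 200, 0.01)))
  sp <- ta_scivr_spectrum(tr, far, grid = seq(900, 1300, 1))
  near <- ta_scivr_spectrum(tr, single_ref(sqrt(0.01), 0.01),
                            grid = seq(900, 1300, 1))
  expect_lt(max(sp$intensity) / max(near$intensity), 1e-10)
})

test_that("tailored single trajectories reproduce Morse levels against the oracle", {
  m <- morse_nh()
  w <- m$parameters$omega
  oracle <- au_to_wavenumber(as.numeric(grid_oracle(m, n_states = 2)))
  sp0 <- ta_scivr_spectrum(morse_traj(0), single_ref(sqrt(w), w),
                           grid = seq(1500, 2100, 1))
  expect_lt(abs(pick_peaks(sp0, 0.5)$position[1] - oracle[1]), 20)
  sp1 <- ta_scivr_spectrum(morse_traj(1), single_ref(sqrt(3 * w), w),
                           grid = seq(5000, 5600, 1))
  expect_lt(abs(pick_peaks(sp1, 0.5)$position[1] - oracle[2]), 20)
})

test_that("spectra demand the prefactor phase and matching dimensions", {
  s <- make_harmonic(0.01)
  tr <- propagate(s, sqrt(0.01), 0, dt = 10, n_steps = 50)
  expect_error(ta_scivr_spectrum(tr, single_ref(0.1, 0.01)),
               "hk_prefactor_phase")
  tr <- hk_prefactor_phase(tr, 0.01)
  expect_error(ta_scivr_spectrum(tr, single_ref(c(0.1, 0.1), c(0.01, 0.01))),
               "does not match")
})

test_that("mc_reference builds the two-term flipped-momentum combination", {
  s <- make_harmonic(c(0.01, 0.016))
  sys <- molecular_system(s)
  b <- normal_mode_analysis(compute_hessian(sys), sys)
  ref <- mc_reference(b, mode = 2, parity = -1)
  expect_length(ref$states, 2L)
  expect_equal(ref$coefficients, as.complex(c(1, -1)))
  expect_equal(ref$states[[1]]$p, sqrt(c(0.01, 0.016)))
  expect_equal(ref$states[[2]]$p, sqrt(c(0.01, 0.016)) * c(1, -1))
  expect_equal(ref$gamma, b$freq)
  expect_error(mc_reference(b, 5), "out of range")
})
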