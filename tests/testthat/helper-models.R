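# shared fixtures, built once per test run and memoized

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# reference NH-stretch-scale Morse oscillator (proton-like mass)
morse_nh <- function() make_morse(D = 0.25, alpha = 1, mass = 1836)

# 1D harmonic ZPE trajectory at fine time step with prefactor phase
ho_traj_fine <- function() fixture("ho_traj_fine", function() {
  s <- make_harmonic(0.01)
  tr <- propagate(s, p0 = sqrt(0.01), q0 = 0, dt = 2, n_steps = 12500)
  hk_prefactor_phase(tr, gamma = 0.01)
})

# Morse trajectories tailored to a target level's harmonic energy
morse_traj <- function(quanta) {
  fixture(paste0("morse_traj_", quanta), function() {
    m <- morse_nh()
    w <- m$parameters$omega
    tr <- propagate(m, p0 = sqrt((2 * quanta + 1) * w), q0 = 0,
                    dt = 5, n_steps = 5000)
    hk_prefactor_phase(tr, gamma = w)
  })
}

# separable 2D harmonic trajectory (for DC projection contracts)
ho2_traj <- function() fixture("ho2_traj", function() {
  s <- make_harmonic(c(0.01, 0.016))
  tr <- propagate(s, p0 = sqrt(c(0.01, 0.016)), q0 = c(0, 0),
                  dt = 5, n_steps = 5000)
  hk_prefactor_phase(tr, gamma = c(0.01, 0.016))
})

single_ref <- function(p0, gamma) {
  reference_state(1, list(coherent_state(p0, numeric(length(p0)), gamma)))
}

parity_ref_1d <- function(omega, parity) {
  reference_state(c(1, parity),
                  list(coherent_state(sqrt(omega), 0, omega),
                       coherent_state(-sqrt(omega), 0, omega)))
}

# pairwise-spring cluster in Cartesian coordinates (FD Hessian path)
make_spring_cluster <- function(coords0, masses, bonds, k = 0.1) {
  n <- nrow(coords0)
  r0 <- apply(bonds, 1L, function(b) {
    sqrt(sum((coords0[b[1], ] - coords0[b[2], ])^2))
  })
  energy <- function(q) {
    X <- matrix(q, ncol = 3L, byrow = TRUE)
    sum(vapply(seq_len(nrow(bonds)), function(i) {
      d <- X[bonds[i, 1], ] - X[bonds[i, 2], ]
      0.5 * k * (sqrt(sum(d^2)) - r0[i])^2
    }, numeric(1)))
  }
  gradient <- function(q) {
    X <- matrix(q, ncol = 3L, byrow = TRUE)
    G <- matrix(0, n, 3L)
    for (i in seq_len(nrow(bonds))) {
      a <- bonds[i, 1]; b <- bonds[i, 2]
      d <- X[a, ] - X[b, ]
      r <- sqrt(sum(d^2))
      f <- k * (r - r0[i]) * d / r
      G[a, ] <- G[a, ] + f
      G[b, ] <- G[b, ] - f
    }
    as.vector(t(G))
  }
  potential_surface(energy, gradient, hessian = NULL, dim = 3L * n,
                    kind = "spring-cluster", coords = "cartesian",
                    masses = rep(masses, each = 3L))
}

peak_near <- function(peaks, target, tol) {
  any(abs(peaks$position - target) <= tol)
}
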