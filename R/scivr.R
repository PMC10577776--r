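#' Coherent states and reference states
#'
#' A coherent state is a minimum-uncertainty Gaussian wavepacket
#' \eqn{|g(p, q)\rangle} with diagonal positive width matrix \eqn{\Gamma}; a
#' reference state is a finite combination \eqn{|\Psi\rangle = \sum_k c_k
#' |g(p_k, q_k)\rangle}, the device the multiple-coherent (MC) scheme uses to
#' amplify chosen transitions.
#'
#' @param p,q phase-space center (mass-scaled normal coordinates).
#' @param gamma positive vector: diagonal of the width matrix \eqn{\Gamma}.
#' @return `coherent_state()` an object of class `coherent_state`.
#' @export
coherent_state <- function(p, q, gamma) {
  p <- as.numeric(p); q <- as.numeric(q); gamma <- as.numeric(gamma)
  if (length(gamma) == 1L) gamma <- rep(gamma, length(p))
  stopifnot(length(p) == length(q), length(gamma) == length(p))
  if (any(gamma <= 0)) stop("all width-matrix entries must be positive")
  structure(list(p = p, q = q, gamma = gamma), class = "coherent_state")
}

#' @param coefficients complex coefficients \eqn{c_k}, at least one nonzero.
#' @param states list of [coherent_state()]s sharing one \eqn{\Gamma}.
#' @return `reference_state()` an object of class `reference_state`.
#' @rdname coherent_state
#' @export
reference_state <- function(coefficients, states) {
  if (length(states) < 1L) stop("a reference state needs at least one term")
  if (length(coefficients) != length(states))
    stop("one coefficient per coherent state required")
  if (all(Mod(as.complex(coefficients)) == 0))
    stop("not all coefficients may be zero")
  g0 <- states[[1]]$gamma
  for (s in states) {
    if (!isTRUE(all.equal(s$gamma, g0)))
      stop("all coherent states in a reference must share the same width matrix")
  }
  structure(list(coefficients = as.complex(coefficients), states = states,
                 gamma = g0, dim = length(g0)),
            class = "reference_state")
}

#' Closed-form overlap of two coherent states
#'
#' \deqn{\langle g_a|g_b\rangle = \exp\Big(-\tfrac14 (q_a-q_b)^T\Gamma(q_a-q_b)
#'  - \tfrac{1}{4\hbar^2}(p_a-p_b)^T\Gamma^{-1}(p_a-p_b)
#'  + \tfrac{i}{2\hbar}(p_a+p_b)^T(q_b-q_a)\Big)}
#' for equal width matrices (\eqn{\hbar = 1}); the modulus never exceeds 1.
#'
#' @param a,b [coherent_state()]s of equal dimension and width.
#' @return A complex scalar.
#' @examples
#' g <- coherent_state(0, 0, 1)
#' coherent_overlap(g, g)  # exactly 1
#' @export
coherent_overlap <- function(a, b) {
  if (length(a$p) != length(b$p)) stop("coherent states differ in dimension")
  if (!isTRUE(all.equal(a$gamma, b$gamma)))
    stop("unsupported case: coherent states with different width matrices")
  dq <- a$q - b$q
  dp <- a$p - b$p
  exp(-0.25 * sum(a$gamma * dq^2) -
        0.25 * sum(dp^2 / a$gamma) +
        0.5i * sum((a$p + b$p) * (b$q - a$q)))
}

#' Multiple-coherent (MC) reference state for one mode
#'
#' Builds the two-term reference
#' \eqn{|\Psi\rangle = |g(p_{eq}, q_{eq})\rangle \pm |g(\tilde p, q_{eq})\rangle}
#' where \eqn{p_{eq}} carries harmonic zero-point momenta and \eqn{\tilde p}
#' equals \eqn{p_{eq}} with the sign of component \eqn{j} flipped. Parity
#' \eqn{-1} annihilates even-quantum lines of mode \eqn{j} (amplifying the
#' fundamental); parity \eqn{+1} amplifies the ZPE line.
#'
#' @param basis a [normal_mode_analysis()] result.
#' @param mode target mode index \eqn{j}.
#' @param parity `+1` or `-1`.
#' @param gamma width vector; defaults to the standard SCIVR choice
#'   \eqn{\Gamma_j = \omega_j}.
#' @return A [reference_state()] in normal-mode coordinates.
#' @export
mc_reference <- function(basis, mode, parity = c(-1, 1), gamma = NULL) {
  parity <- as.numeric(parity)[1]
  if (!parity %in% c(-1, 1)) stop("parity must be +1 or -1")
  if (mode < 1L || mode > basis$n_modes) stop("mode index out of range")
  if (is.null(gamma)) gamma <- basis$freq
  ic <- harmonic_initial_conditions(basis, quanta = 0)
  p_eq <- ic$p_nm
  p_flip <- p_eq
  p_flip[mode] <- -p_flip[mode]
  q0 <- numeric(basis$n_modes)
  reference_state(c(1, parity),
                  list(coherent_state(p_eq, q0, gamma),
                       coherent_state(p_flip, q0, gamma)))
}

# <Psi | g(p_t, q_t)> time series for a trajectory
.reference_overlap_series <- function(trajectory, reference) {
  n <- length(trajectory$time)
  gam <- reference$gamma
  out <- complex(n)
  for (k in seq_along(reference$states)) {
    st <- reference$states[[k]]
    dq <- sweep(trajectory$q, 2L, st$q)      # q_t - q_ref
    dp <- sweep(trajectory$p, 2L, st$p)
    sp <- sweep(trajectory$p, 2L, -st$p)     # p_t + p_ref
    # <g_ref | g_t>: a = ref, b = t in the closed form
    logmod <- -0.25 * drop(dq^2 %*% gam) - 0.25 * drop(dp^2 %*% (1 / gam))
    phase <- 0.5 * rowSums(sp * dq)          # (p_ref + p_t).(q_t - q_ref)/2
    out <- out + Conj(reference$coefficients[k]) * exp(logmod + 1i * phase)
  }
  out
}

#' Time-averaged SCIVR power spectrum from a single trajectory
#'
#' \deqn{I(E) = \frac{1}{(2\pi\hbar)^{N_v}}\,\frac{1}{2\pi\hbar T}
#'   \left|\int_0^T dt\, \langle\Psi|g_t(p_0,q_0)\rangle\,
#'   e^{i\left(S_t + E t + \phi_t\right)/\hbar}\right|^2}
#' in the separable approximation, where the Herman-Kluk prefactor enters
#' only through its phase \eqn{\phi_t}. Exact on quadratic potentials (peaks
#' at \eqn{\sum_j (n_j + \tfrac12)\hbar\omega_j}); near-exact for the
#' 1D Morse at zero-point-energy conditions.
#'
#' @param trajectory a [propagate()] result with the prefactor phase attached
#'   (see [hk_prefactor_phase()]); its `gamma` must match the reference's.
#' @param reference a [reference_state()] in the trajectory's coordinates.
#' @param grid energy grid in cm\eqn{^{-1}}.
#' @return An [new_spectrum()] tibble with method `"ta-scivr"`.
#' @export
ta_scivr_spectrum <- function(trajectory, reference,
                              grid = seq(0, 4000, by = 1)) {
  if (is.null(trajectory$phi))
    stop("trajectory carries no prefactor phase; run hk_prefactor_phase() first")
  if (reference$dim != trajectory$dim)
    stop("reference dimension (", reference$dim,
         ") does not match the trajectory (", trajectory$dim, ")")
  if (!is.null(trajectory$gamma) &&
      !isTRUE(all.equal(trajectory$gamma, reference$gamma)))
    stop("width matrix of the reference differs from the one used for the prefactor phase")
  ov <- .reference_overlap_series(trajectory, reference)
  f <- ov * exp(1i * (trajectory$S + trajectory$phi))
  tt <- trajectory$time
  Tt <- tt[length(tt)]
  E <- wavenumber_to_au(grid)
  I <- ft_intensity(tt, f, E) / ((2 * pi)^trajectory$dim * 2 * pi * Tt)
  new_spectrum(grid, I, method = "ta-scivr", mode = NA, total_time = Tt,
               extra = list(n_v = trajectory$dim, dt = trajectory$dt))
}
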