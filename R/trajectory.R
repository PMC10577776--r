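#' Symplectic propagation with monodromy, action and energy accumulation
#'
#' Velocity-Verlet propagation of a single classical trajectory on a
#' unit-mass (mass-scaled) [potential_surface()], accumulating alongside the
#' phase-space point: the four monodromy blocks
#' \eqn{M_{qq} = \partial q_t/\partial q_0} etc. (updated with the same
#' kick-drift-kick splitting, using the local Hessian), the classical action
#' \eqn{S_t = \int_0^t (T - V)\,dt'} by the trapezoidal rule on the step
#' grid, and the total energy. Each kick and drift factor is exactly
#' symplectic, so the assembled monodromy satisfies \eqn{M^T J M = J} to
#' roundoff.
#'
#' Energy conservation is monitored two ways: the bounded step-scale
#' fluctuation \eqn{\max_t |E(t)-E(0)|/|E(0)|} (an intrinsic
#' \eqn{O(\omega^2 dt^2)} property of the integrator, checked against
#' `fluct_tol` and reported with the first offending step) and the secular
#' drift, the linear trend of \eqn{E(t)} after the integrator's bounded
#' shadow-Hamiltonian oscillation has been regressed out (see the package
#' vignette), times the total time and relative to \eqn{|E(0)|} (checked
#' against `drift_tol`; this is the quantity that stays at roundoff for a
#' symplectic integrator).
#'
#' @param surface a mass-scaled [potential_surface()].
#' @param p0,q0 initial momenta and coordinates (mass-scaled normal
#'   coordinates).
#' @param dt time step (atomic units), default 10.
#' @param n_steps number of steps; default covers 25 000 au, the finite-time
#'   resolution that produces ~50 cm\eqn{^{-1}} linewidths.
#' @param drift_tol bound on the relative secular energy drift.
#' @param fluct_tol bound on the relative instantaneous energy fluctuation.
#' @param hessian_step finite-difference step for the monodromy Hessian when
#'   the surface has no analytic one.
#' @return An object of class `sc_trajectory`: `time`, `q`/`p` (step x mode
#'   matrices), monodromy arrays `Mqq`,`Mqp`,`Mpq`,`Mpp` (mode x mode x
#'   step), `S` (action), `E` (energy), `dt`, `surface`, and `metadata`
#'   (energy fluctuation, secular drift, symplectic defect).
#' @export
propagate <- function(surface, p0, q0, dt = 10, n_steps = 2500,
                      drift_tol = 1e-6, fluct_tol = 1e-2,
                      hessian_step = 1e-3) {
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 1) stop("n_steps must be at least 1")
  d <- surface$dim
  stopifnot(length(p0) == d, length(q0) == d)

  n <- n_steps + 1L
  q <- matrix(0, n, d); p <- matrix(0, n, d)
  Mqq <- array(0, c(d, d, n)); Mqp <- array(0, c(d, d, n))
  Mpq <- array(0, c(d, d, n)); Mpp <- array(0, c(d, d, n))
  S <- numeric(n); E <- numeric(n)

  hess <- function(qv) surface_hessian(surface, qv, step = hessian_step)

  qc <- as.numeric(q0); pc <- as.numeric(p0)
  Aqq <- diag(d); Aqp <- matrix(0, d, d)
  Apq <- matrix(0, d, d); App <- diag(d)

  # shadow-energy regressors for the secular-drift estimator
  r_pKp <- numeric(n); r_gg <- numeric(n)

  V <- surface$energy(qc)
  g <- surface$gradient(qc)
  K <- hess(qc)
  lag_prev <- 0.5 * sum(pc^2) - V

  q[1L, ] <- qc; p[1L, ] <- pc
  Mqq[, , 1L] <- Aqq; Mqp[, , 1L] <- Aqp; Mpq[, , 1L] <- Apq; Mpp[, , 1L] <- App
  E[1L] <- 0.5 * sum(pc^2) + V
  r_pKp[1L] <- drop(pc %*% K %*% pc); r_gg[1L] <- sum(g^2)
  E0 <- E[1L]

  for (k in seq_len(n_steps)) {
    # half kick
    ph <- pc - 0.5 * dt * g
    Apq_h <- Apq - 0.5 * dt * K %*% Aqq
    App_h <- App - 0.5 * dt * K %*% Aqp
    # drift
    qc <- qc + dt * ph
    Aqq <- Aqq + dt * Apq_h
    Aqp <- Aqp + dt * App_h
    # new forces
    g <- surface$gradient(qc)
    if (any(!is.finite(g))) stop("non-finite force at step ", k)
    K <- hess(qc)
    V <- surface$energy(qc)
    # half kick
    pc <- ph - 0.5 * dt * g
    Apq <- Apq_h - 0.5 * dt * K %*% Aqq
    App <- App_h - 0.5 * dt * K %*% Aqp

    i <- k + 1L
    q[i, ] <- qc; p[i, ] <- pc
    Mqq[, , i] <- Aqq; Mqp[, , i] <- Aqp; Mpq[, , i] <- Apq; Mpp[, , i] <- App
    kin <- 0.5 * sum(pc^2)
    E[i] <- kin + V
    r_pKp[i] <- drop(pc %*% K %*% pc); r_gg[i] <- sum(g^2)
    lag <- kin - V
    S[i] <- S[i - 1L] + 0.5 * dt * (lag_prev + lag)
    lag_prev <- lag
  }

  denom <- max(abs(E0), 1e-12)
  fluct <- abs(E - E0) / denom
  if (any(fluct > fluct_tol)) {
    stop(sprintf("relative energy fluctuation %.3g exceeds %.3g at step %d",
                 max(fluct), fluct_tol, which(fluct > fluct_tol)[1L] - 1L))
  }
  tgrid <- dt * (0:n_steps)
  drift <- .secular_drift(tgrid, E, r_pKp, r_gg)
  if (drift > drift_tol) {
    first_bad <- which(fluct == max(fluct))[1L] - 1L
    stop(sprintf("relative secular energy drift %.3g exceeds %.3g (largest deviation at step %d)",
                 drift, drift_tol, first_bad))
  }

  structure(
    list(time = tgrid, q = q, p = p,
         Mqq = Mqq, Mqp = Mqp, Mpq = Mpq, Mpp = Mpp,
         S = S, E = E, phi = NULL, gamma = NULL,
         dt = dt, n_steps = as.integer(n_steps), dim = d,
         surface = surface,
         metadata = list(energy_fluctuation = max(fluct),
                         energy_drift = drift,
                         total_time = dt * n_steps)),
    class = "sc_trajectory"
  )
}

#' @export
print.sc_trajectory <- function(x, ...) {
  cat("<sc_trajectory>", x$dim, "modes,", x$n_steps, "steps, dt =", x$dt,
      "au (T =", x$metadata$total_time, "au)\n")
  cat(sprintf("  energy fluctuation %.3g, secular drift %.3g\n",
              x$metadata$energy_fluctuation, x$metadata$energy_drift))
  if (!is.null(x$phi)) cat("  Herman-Kluk prefactor phase attached\n")
  invisible(x)
}

# Secular energy drift of a symplectic trajectory, as |slope| * T / |E0|.
# The bounded O(dt^2) energy oscillation of velocity Verlet is removed by
# regressing E(t) on its shadow-Hamiltonian correction terms (p^T V'' p and
# |grad V|^2 along the path) plus sinusoids at the dominant periodogram
# frequencies of the residual; the coefficient of t is the genuinely secular
# component.
.secular_drift <- function(tt, E, r_pKp, r_gg, K = 10L) {
  n <- length(E)
  if (n < 8L) return(0)
  denom <- max(abs(E[1L]), 1e-12)
  Tt <- tt[n] - tt[1L]
  X <- cbind(1, tt, r_pKp, r_gg)
  if (n >= 64L) {
    res <- qr.resid(qr(X), E)
    sp <- Mod(stats::fft(res - mean(res)))[seq_len(n %/% 2L)]
    sp[1:3] <- 0
    top <- order(sp, decreasing = TRUE)[seq_len(min(K, length(sp)))]
    bins <- unique(unlist(lapply(top, function(k) (k - 1L):(k + 1L))))
    bins <- bins[bins >= 3L & bins <= n %/% 2L]
    dtg <- tt[2L] - tt[1L]
    for (k in bins) {
      w <- 2 * pi * (k - 1L) / (n * dtg)
      X <- cbind(X, sin(w * tt), cos(w * tt))
    }
  }
  b <- qr.coef(qr(X), E)[2L]
  if (is.na(b)) b <- 0
  abs(b) * Tt / denom
}

#' Symplectic defect of the accumulated monodromy
#'
#' Frobenius norm of \eqn{M^T J M - J} per stored step, where
#' \eqn{M = [[M_{qq}, M_{qp}], [M_{pq}, M_{pp}]]}.
#'
#' @param trajectory an [propagate()] result.
#' @return Numeric vector, one defect per stored step.
#' @export
symplectic_defect <- function(trajectory) {
  d <- trajectory$dim
  J <- rbind(cbind(matrix(0, d, d), diag(d)),
             cbind(-diag(d), matrix(0, d, d)))
  n <- length(trajectory$time)
  vapply(seq_len(n), function(i) {
    M <- rbind(cbind(trajectory$Mqq[, , i], trajectory$Mqp[, , i]),
               cbind(trajectory$Mpq[, , i], trajectory$Mpp[, , i]))
    sqrt(sum((t(M) %*% J %*% M - J)^2))
  }, numeric(1))
}

#' Herman-Kluk prefactor phase along a trajectory
#'
#' Computes the continuous phase \eqn{\phi_t} of the Herman-Kluk
#' pre-exponential factor
#' \deqn{C_t = \sqrt{\det\tfrac12\left(M_{qq} + \Gamma^{-1} M_{pp} \Gamma
#'   - i\hbar M_{qp}\Gamma + \tfrac{i}{\hbar}\Gamma^{-1} M_{pq}\right)}}
#' with diagonal positive width matrix \eqn{\Gamma}. The square-root branch
#' is tracked by unwrapping the argument of the determinant between
#' consecutive steps (never a principal-value square root), so \eqn{\phi_t}
#' is continuous with \eqn{\phi_0 = 0}. Under this sign convention the 1D
#' harmonic oscillator with \eqn{\Gamma = \omega} gives
#' \eqn{C_t = e^{-i\omega t/2}}, i.e. \eqn{\phi_t = -\omega t / 2}.
#'
#' @param trajectory a [propagate()] result.
#' @param gamma positive vector: the diagonal of \eqn{\Gamma} (default
#'   \eqn{\Gamma_j = \omega_j} read from the surface Hessian at the initial
#'   point is *not* assumed; pass it explicitly).
#' @return The trajectory with `phi` (radians, continuous), `hk_modulus`
#'   (\eqn{|C_t|}) and `gamma` attached.
#' @export
hk_prefactor_phase <- function(trajectory, gamma) {
  d <- trajectory$dim
  gamma <- as.numeric(gamma)
  if (length(gamma) == 1L) gamma <- rep(gamma, d)
  if (length(gamma) != d || any(gamma <= 0))
    stop("gamma must be a positive vector of length ", d)
  n <- length(trajectory$time)
  Gi <- 1 / gamma
  detv <- complex(n)
  for (i in seq_len(n)) {
    A <- trajectory$Mqq[, , i] + Gi * trajectory$Mpp[, , i] * rep(gamma, each = d) -
      1i * trajectory$Mqp[, , i] * rep(gamma, each = d) +
      1i * Gi * trajectory$Mpq[, , i]
    detv[i] <- det_complex(0.5 * A)
  }
  if (any(Mod(detv) < 1e-10)) {
    stop("Herman-Kluk determinant passes through zero along the trajectory; reduce dt")
  }
  arg <- Arg(detv)
  darg <- diff(arg)
  darg <- darg - 2 * pi * round(darg / (2 * pi))
  if (any(abs(darg) > 0.9 * pi)) {
    warning("large per-step jumps in the prefactor argument; phase unwrapping may be unreliable, reduce dt")
  }
  phi <- 0.5 * c(0, cumsum(darg))
  trajectory$phi <- phi
  trajectory$hk_modulus <- sqrt(Mod(detv))
  trajectory$gamma <- gamma
  trajectory
}

# determinant of a complex matrix: Gaussian elimination with partial
# pivoting (base det() is real-only)
det_complex <- function(A) {
  if (length(A) == 1L) return(A[[1]])
  d <- nrow(A)
  if (d == 1L) return(A[1, 1])
  if (d == 2L) return(A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  A <- as.matrix(A)
  det <- 1 + 0i
  for (k in seq_len(d - 1L)) {
    piv <- which.max(Mod(A[k:d, k])) + k - 1L
    if (Mod(A[piv, k]) == 0) return(0 + 0i)
    if (piv != k) {
      A[c(k, piv), ] <- A[c(piv, k), ]
      det <- -det
    }
    det <- det * A[k, k]
    idx <- (k + 1L):d
    A[idx, ] <- A[idx, ] - outer(A[idx, k] / A[k, k], A[k, ])
  }
  det * A[d, d]
}

#' Write / read a trajectory as plain text
#'
#' Multi-column TSV (time, coordinates, momenta, flattened monodromy blocks,
#' action, energy, and the prefactor phase when present) preceded by a single
#' `#`-prefixed JSON metadata header recording `dt`, dimensionality and the
#' surface kind. `read_trajectory()` restores the numeric content (the
#' surface itself is not serialized).
#'
#' @param trajectory an `sc_trajectory`.
#' @param path destination / source file.
#' @return `write_trajectory()` the path, invisibly; `read_trajectory()` an
#'   `sc_trajectory` without the `surface` field.
#' @export
write_trajectory <- function(trajectory, path) {
  d <- trajectory$dim
  n <- length(trajectory$time)
  flat <- function(A) t(matrix(A, nrow = d * d))
  df <- cbind(time = trajectory$time, trajectory$q, trajectory$p,
              flat(trajectory$Mqq), flat(trajectory$Mqp),
              flat(trajectory$Mpq), flat(trajectory$Mpp),
              S = trajectory$S, E = trajectory$E)
  cn <- c("time", paste0("q", 1:d), paste0("p", 1:d),
          paste0("Mqq", 1:(d * d)), paste0("Mqp", 1:(d * d)),
          paste0("Mpq", 1:(d * d)), paste0("Mpp", 1:(d * d)), "S", "E")
  if (!is.null(trajectory$phi)) {
    df <- cbind(df, phi = trajectory$phi)
    cn <- c(cn, "phi")
  }
  colnames(df) <- cn
  meta <- list(dt = trajectory$dt, dim = d, n_steps = trajectory$n_steps,
               surface_kind = trajectory$surface$kind,
               gamma = trajectory$gamma,
               units = "hartree atomic units")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
  utils::write.table(format(as.data.frame(df), digits = 17, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# ")) stop("missing metadata header in ", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", header))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  d <- meta$dim
  n <- nrow(df)
  unflat <- function(prefix) {
    A <- array(0, c(d, d, n))
    cols <- as.matrix(df[paste0(prefix, 1:(d * d))])
    for (i in seq_len(n)) A[, , i] <- matrix(cols[i, ], d, d)
    A
  }
  structure(
    list(time = df$time,
         q = as.matrix(df[paste0("q", 1:d)]),
         p = as.matrix(df[paste0("p", 1:d)]),
         Mqq = unflat("Mqq"), Mqp = unflat("Mqp"),
         Mpq = unflat("Mpq"), Mpp = unflat("Mpp"),
         S = df$S, E = df$E,
         phi = if ("phi" %in% names(df)) df$phi else NULL,
         gamma = meta$gamma,
         dt = meta$dt, n_steps = meta$n_steps, dim = d,
         surface = NULL,
         metadata = list(total_time = meta$dt * meta$n_steps)),
    class = "sc_trajectory"
  )
}
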