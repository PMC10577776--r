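#' Potential-energy-surface objects
#'
#' A `potential_surface` bundles closures for the energy (hartree), gradient
#' and (optionally) Hessian at a geometry. Built-in model surfaces operate on
#' mass-scaled coordinates (bohr times sqrt of electron mass), so every degree
#' of freedom carries unit mass and the classical equations of motion need no
#' mass matrix; surfaces read from Cartesian engines carry
#' `coords = "cartesian"` together with per-atom masses and are mass-weighted
#' by the normal-mode layer before propagation.
#'
#' @param energy function of a numeric vector returning a scalar (hartree).
#' @param gradient function returning the gradient vector (hartree per
#'   mass-scaled bohr).
#' @param hessian optional function returning the symmetric second-derivative
#'   matrix; when absent, consumers fall back to finite differences of the
#'   gradient.
#' @param dim dimensionality (number of coordinates).
#' @param kind short tag, e.g. `"harmonic"`, `"morse"`, `"hbond-mimic"`.
#' @param parameters named list of defining parameters, kept for provenance.
#' @param coords `"mass_scaled"` (unit-mass) or `"cartesian"`.
#' @param masses per-coordinate masses (electron-mass units); required for
#'   Cartesian surfaces, implicit unit masses otherwise.
#' @param levels optional `quantum_levels` object attached by constructors
#'   that know their spectrum in closed form.
#' @param flags character vector of warnings raised at construction.
#' @return An object of class `potential_surface`.
#' @export
potential_surface <- function(energy, gradient, hessian = NULL, dim,
                              kind = "custom", parameters = list(),
                              coords = c("mass_scaled", "cartesian"),
                              masses = NULL, levels = NULL,
                              flags = character()) {
  coords <- match.arg(coords)
  stopifnot(is.function(energy), is.function(gradient),
            is.null(hessian) || is.function(hessian),
            length(dim) == 1L, dim >= 1L)
  if (coords == "cartesian") {
    if (is.null(masses)) stop("Cartesian surfaces require per-coordinate masses")
    if (length(masses) != dim) stop("length(masses) must equal dim")
    if (any(masses <= 0)) stop("all masses must be positive")
  }
  structure(
    list(energy = energy, gradient = gradient, hessian = hessian,
         dim = as.integer(dim), kind = kind, parameters = parameters,
         coords = coords, masses = masses, levels = levels, flags = flags),
    class = "potential_surface"
  )
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("<potential_surface> kind:", x$kind, " dim:", x$dim,
      " coords:", x$coords, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Evaluate a potential surface
#'
#' @param surface a [potential_surface()].
#' @param q coordinate vector.
#' @param step finite-difference step for the Hessian fallback (mass-scaled
#'   bohr).
#' @return `surface_energy()` a scalar, `surface_gradient()` a vector,
#'   `surface_hessian()` a symmetric matrix (analytic when available, central
#'   finite differences of the gradient otherwise).
#' @export
surface_energy <- function(surface, q) {
  stopifnot(length(q) == surface$dim)
  surface$energy(q)
}

#' @rdname surface_energy
#' @export
surface_gradient <- function(surface, q) {
  stopifnot(length(q) == surface$dim)
  surface$gradient(q)
}

#' @rdname surface_energy
#' @export
surface_hessian <- function(surface, q, step = 1e-3) {
  stopifnot(length(q) == surface$dim)
  if (!is.null(surface$hessian)) {
    H <- surface$hessian(q)
  } else {
    d <- surface$dim
    H <- matrix(0, d, d)
    for (j in seq_len(d)) {
      e <- numeric(d); e[j] <- step
      H[, j] <- (surface$gradient(q + e) - surface$gradient(q - e)) / (2 * step)
    }
  }
  (H + t(H)) / 2
}

#' Quantum level sets
#'
#' Ordered eigenenergies (hartree) of a model Hamiltonian with their
#' provenance: `"closed-form"` for analytic formulas, `"grid-oracle"` for
#' sinc-DVR diagonalization.
#'
#' @param energies strictly increasing numeric vector (hartree).
#' @param provenance `"closed-form"` or `"grid-oracle"`.
#' @param v_min potential minimum (hartree); all levels must lie above it.
#' @return A `quantum_levels` object (numeric vector with attributes).
#' @export
quantum_levels <- function(energies, provenance = c("closed-form", "grid-oracle"),
                           v_min = 0) {
  provenance <- match.arg(provenance)
  if (any(diff(energies) <= 0)) stop("quantum levels must be strictly increasing")
  if (any(energies <= v_min)) stop("quantum levels must lie above the potential minimum")
  structure(energies, provenance = provenance, v_min = v_min,
            class = "quantum_levels")
}

#' @export
print.quantum_levels <- function(x, ...) {
  cat("<quantum_levels> provenance:", attr(x, "provenance"), "\n")
  print(unclass(x)[seq_len(min(length(x), 10L))])
  invisible(x)
}

#' Export quantum levels as a two-column table
#'
#' @param levels a [quantum_levels()] object.
#' @param path destination file (plain text: index, hartree).
#' @export
write_levels <- function(levels, path) {
  df <- data.frame(index = seq_along(levels) - 1L,
                   energy_hartree = as.numeric(levels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonic model surface with optional bilinear couplings
#'
#' \deqn{V(q) = \tfrac12 \sum_j \omega_j^2 q_j^2 + \sum_{i<j} c_{ij} q_i q_j}
#' in mass-scaled coordinates. The Hessian is constant,
#' \eqn{H = \mathrm{diag}(\omega^2) + C}; construction fails if it is not
#' positive definite (the offending eigenvalue is named).
#'
#' @param omega positive per-mode frequencies (hartree).
#' @param coupling optional symmetric matrix of off-diagonal couplings
#'   (hartree\eqn{^2}); the diagonal is ignored.
#' @return A [potential_surface()], with exact `quantum_levels` attached for
#'   the uncoupled case (sums of \eqn{(n+\tfrac12)\omega_j} are delegated to
#'   the grid oracle for coupled surfaces).
#' @examples
#' s <- make_harmonic(0.01)
#' surface_energy(s, 1.0)  # 5e-5 hartree
#' @export
make_harmonic <- function(omega, coupling = NULL) {
  omega <- as.numeric(omega)
  if (any(omega <= 0)) stop("harmonic frequencies must be positive")
  d <- length(omega)
  H <- diag(omega^2, d)
  if (!is.null(coupling)) {
    coupling <- as.matrix(coupling)
    if (!isTRUE(all.equal(dim(coupling), c(d, d), check.attributes = FALSE)))
      stop("coupling matrix must be ", d, " x ", d)
    if (max(abs(coupling - t(coupling))) > 1e-12)
      stop("coupling matrix must be symmetric")
    C <- coupling; diag(C) <- 0
    H <- H + C
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop(sprintf("coupled harmonic Hessian is not positive definite (eigenvalue %.6g)",
                 min(ev)))
  }
  lv <- NULL
  if (is.null(coupling) && d == 1L) {
    lv <- quantum_levels((seq_len(40) - 0.5) * omega, "closed-form")
  }
  force(H)
  potential_surface(
    energy = function(q) 0.5 * drop(crossprod(q, H %*% q)),
    gradient = function(q) drop(H %*% q),
    hessian = function(q) H,
    dim = d, kind = if (d == 1L) "harmonic" else "coupled-harmonic",
    parameters = list(omega = omega, coupling = coupling, hessian = H),
    levels = lv
  )
}

#' Morse oscillator surface with closed-form levels
#'
#' \deqn{V(r) = D(1 - e^{-\alpha r})^2} for a particle of mass \eqn{m};
#' internally the coordinate is mass-scaled (\eqn{x = \sqrt{m}\, r}), so the
#' effective range parameter is \eqn{\beta = \alpha/\sqrt m} and the harmonic
#' frequency \eqn{\omega = \alpha\sqrt{2D/m}}. Bound levels follow
#' \deqn{E_n = \hbar\omega(n+\tfrac12) - \frac{(\hbar\omega)^2}{4D}(n+\tfrac12)^2.}
#'
#' @param D dissociation energy (hartree), positive.
#' @param alpha range parameter (1/bohr), positive.
#' @param mass particle mass (electron-mass units), positive.
#' @return A [potential_surface()] with attached closed-form `quantum_levels`
#'   for all bound states.
#' @examples
#' s <- make_morse(D = 0.25, alpha = 1, mass = 1836)
#' s$parameters$omega                 # 0.016502 hartree
#' diff(s$levels[1:2])                # fundamental, ~0.015957 hartree
#' @export
make_morse <- function(D, alpha, mass) {
  if (D <= 0 || alpha <= 0 || mass <= 0)
    stop("Morse parameters D, alpha and mass must all be positive")
  beta <- alpha / sqrt(mass)
  omega <- alpha * sqrt(2 * D / mass)
  n_bound <- floor(2 * D / omega - 0.5)
  if (n_bound < 0) stop("Morse well too shallow to bind any state")
  lv <- morse_levels(D, alpha, mass, n_max = n_bound)
  potential_surface(
    energy = function(q) {
      u <- 1 - exp(-beta * q[1])
      D * u * u
    },
    gradient = function(q) {
      e <- exp(-beta * q[1])
      2 * D * beta * e * (1 - e)
    },
    hessian = function(q) {
      e <- exp(-beta * q[1])
      matrix(2 * D * beta^2 * (2 * e * e - e), 1, 1)
    },
    dim = 1L, kind = "morse",
    parameters = list(D = D, alpha = alpha, mass = mass,
                      beta = beta, omega = omega, n_bound = n_bound),
    levels = lv
  )
}

#' Closed-form Morse eigenvalues
#'
#' @inheritParams make_morse
#' @param n_max highest level index requested (0-based).
#' @return A [quantum_levels()] object with levels \eqn{E_0 \ldots E_{n_max}}.
#' @export
morse_levels <- function(D, alpha, mass, n_max) {
  omega <- alpha * sqrt(2 * D / mass)
  n_bound <- floor(2 * D / omega - 0.5)
  if (n_max > n_bound) {
    stop(sprintf("level %d requested but the well binds only %d states (n <= %d)",
                 n_max, n_bound + 1L, n_bound))
  }
  n <- 0:n_max
  E <- omega * (n + 0.5) - (omega * (n + 0.5))^2 / (4 * D)
  quantum_levels(E, "closed-form")
}

#' Two-mode hydrogen-bond mimic
#'
#' The minimal anharmonic model of a hydrogen-bonded X-H stretch: a fast
#' stretch coordinate \eqn{r} bilinearly coupled through \eqn{c\,r^2 R} to a
#' slow "bath" coordinate \eqn{R} standing in for the donor-acceptor distance,
#' \deqn{V(r,R) = \tfrac12\omega_r^2 r^2 + \tfrac12\omega_R^2 R^2 + c\,r^2 R.}
#' The \eqn{r^2 R} form shifts the effective stretch curvature
#' (\eqn{\omega_r^2 + 2cR}) without moving the minimum, so increasing the
#' coupling red-shifts the stretch fundamental at fixed initial conditions —
#' the spectroscopic fingerprint of a strengthening hydrogen bond.
#'
#' @param omega_stretch stretch frequency (hartree); default 3450 cm\eqn{^{-1}},
#'   an NH-stretch scale.
#' @param omega_bath bath frequency (hartree); default 330 cm\eqn{^{-1}}, a
#'   typical intermolecular H-bond mode.
#' @param coupling cubic coupling constant \eqn{c} (hartree per mass-scaled
#'   bohr\eqn{^3} scale); 0 gives a separable pair of harmonic modes.
#' @return A [potential_surface()] of dimension 2 (coordinates: stretch,
#'   bath). If the effective stretch curvature can turn negative within the
#'   zero-point amplitude of the bath, a warning is raised and the surface is
#'   flagged `"curvature"`.
#' @export
make_hbond_mimic <- function(omega_stretch = wavenumber_to_au(3450),
                             omega_bath = wavenumber_to_au(330),
                             coupling = 0) {
  if (omega_stretch <= 0 || omega_bath <= 0)
    stop("frequencies must be positive")
  wr2 <- omega_stretch^2
  wR2 <- omega_bath^2
  c3 <- coupling
  flags <- character()
  if (c3 != 0) {
    # bath excursion at ZPE: free amplitude plus the coupling-induced mean shift
    A_r <- 1 / sqrt(omega_stretch)
    A_R <- 1 / sqrt(omega_bath) + abs(c3) * A_r^2 / wR2
    if (wr2 - 2 * abs(c3) * A_R <= 0) {
      warning("effective stretch curvature turns negative within zero-point amplitude; surface flagged")
      flags <- "curvature"
    }
  }
  potential_surface(
    energy = function(q) {
      0.5 * wr2 * q[1]^2 + 0.5 * wR2 * q[2]^2 + c3 * q[1]^2 * q[2]
    },
    gradient = function(q) {
      c(wr2 * q[1] + 2 * c3 * q[1] * q[2],
        wR2 * q[2] + c3 * q[1]^2)
    },
    hessian = function(q) {
      matrix(c(wr2 + 2 * c3 * q[2], 2 * c3 * q[1],
               2 * c3 * q[1], wR2), 2, 2)
    },
    dim = 2L, kind = "hbond-mimic",
    parameters = list(omega_stretch = omega_stretch, omega_bath = omega_bath,
                      coupling = coupling),
    flags = flags
  )
}
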