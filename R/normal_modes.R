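#' Molecular (or abstract model) system
#'
#' Couples a geometry to a [potential_surface()]. For Cartesian molecular
#' systems `coords` has length `3 * n_atoms` (bohr) and `masses` one entry
#' per atom; for abstract mass-scaled model systems the coordinate vector has
#' the surface's dimensionality and unit masses.
#'
#' @param surface a [potential_surface()].
#' @param coords coordinate vector (bohr for Cartesian, mass-scaled bohr for
#'   model systems). Defaults to the origin for model surfaces.
#' @param masses per-atom masses in electron-mass units (Cartesian only).
#' @param labels per-atom element labels (Cartesian only).
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(surface, coords = NULL, masses = NULL,
                             labels = NULL) {
  stopifnot(inherits(surface, "potential_surface"))
  cartesian <- surface$coords == "cartesian"
  if (is.null(coords)) {
    if (cartesian) stop("Cartesian systems need explicit coordinates")
    coords <- numeric(surface$dim)
  }
  if (length(coords) != surface$dim)
    stop("coordinate length must match the surface dimensionality")
  if (cartesian) {
    if (surface$dim %% 3L != 0L)
      stop("Cartesian systems need 3 coordinates per atom")
    n_atoms <- surface$dim %/% 3L
    if (is.null(masses)) masses <- surface$masses[3L * seq_len(n_atoms) - 2L]
    if (length(masses) != n_atoms) stop("need one mass per atom")
    if (any(masses <= 0)) stop("all masses must be positive")
  } else {
    n_atoms <- NA_integer_
    masses <- NULL
  }
  structure(list(surface = surface, coords = as.numeric(coords),
                 masses = masses, labels = labels,
                 cartesian = cartesian, n_atoms = n_atoms),
            class = "molecular_system")
}

# per-coordinate mass vector (unit for model systems)
.coord_masses <- function(system) {
  if (system$cartesian) rep(system$masses, each = 3L)
  else rep(1, system$surface$dim)
}

#' Mass-weighted Hessian of a system
#'
#' Uses the surface's analytic Hessian when present, otherwise central finite
#' differences of the gradient (step `step`, in mass-scaled bohr). The result
#' is symmetrized and, for Cartesian systems, mass-weighted as
#' \eqn{H_{ij}/\sqrt{m_i m_j}}. If the gradient norm at the input geometry
#' exceeds `grad_tol` a warning is raised and recorded in the
#' `"grad_norm_warning"` attribute.
#'
#' @param system a [molecular_system()].
#' @param step finite-difference step (mass-scaled bohr).
#' @param grad_tol gradient-norm threshold for the stationarity warning.
#' @return Symmetric mass-weighted Hessian (hartree, unit-mass coordinates),
#'   with attribute `grad_norm`.
#' @export
compute_hessian <- function(system, step = 1e-3, grad_tol = 1e-6) {
  surf <- system$surface
  q <- system$coords
  g <- surface_gradient(surf, q)
  gnorm <- sqrt(sum(g^2))
  m <- .coord_masses(system)
  if (!is.null(surf$hessian)) {
    H <- surf$hessian(q)
  } else {
    # central differences of the gradient, displacing mass-scaled coordinates
    d <- surf$dim
    H <- matrix(0, d, d)
    for (j in seq_len(d)) {
      e <- numeric(d)
      e[j] <- step / sqrt(m[j])   # step is in mass-scaled units
      H[, j] <- (surface_gradient(surf, q + e) - surface_gradient(surf, q - e)) /
        (2 * e[j])
    }
  }
  H <- (H + t(H)) / 2
  H <- H / sqrt(outer(m, m))
  attr(H, "grad_norm") <- gnorm
  if (gnorm > grad_tol) {
    warning(sprintf("gradient norm %.3g exceeds %.3g: geometry is not a stationary point",
                    gnorm, grad_tol))
    attr(H, "grad_norm_warning") <- TRUE
  }
  H
}

#' Harmonic normal-mode analysis
#'
#' Diagonalizes a mass-weighted Hessian after projecting out rigid-body
#' translations (and, for Cartesian systems, rotations about the center of
#' mass). Frequencies are the square roots of the retained eigenvalues;
#' negative eigenvalues beyond `zero_tol` are reported as imaginary modes,
#' never silently dropped.
#'
#' @param hessian mass-weighted symmetric Hessian, e.g. from
#'   [compute_hessian()].
#' @param system the [molecular_system()] the Hessian belongs to.
#' @param project_rotations project rotational modes (Cartesian systems only;
#'   default `TRUE` for Cartesian, ignored otherwise).
#' @param zero_tol eigenvalues within `(-zero_tol, zero_tol)` hartree\eqn{^2}
#'   are treated as zero modes.
#' @return An object of class `normal_mode_basis`: fields `q_eq` (equilibrium
#'   coordinates, surface units), `freq` (hartree), `modes` (orthonormal
#'   mass-weighted mode matrix, one column per retained mode), `n_modes`,
#'   `imaginary` (tibble of flagged modes), `masses` (per-coordinate).
#' @export
normal_mode_analysis <- function(hessian, system, project_rotations = NULL,
                                 zero_tol = 1e-8) {
  if (max(abs(hessian - t(hessian))) > 1e-10) stop("hessian must be symmetric")
  d <- nrow(hessian)
  m <- .coord_masses(system)
  if (is.null(project_rotations)) project_rotations <- system$cartesian

  P <- NULL
  n_project <- 0L
  if (system$cartesian) {
    vecs <- .rigid_body_vectors(system, rotations = project_rotations)
    n_project <- ncol(vecs)
    P <- diag(d) - vecs %*% t(vecs)
    hessian <- P %*% hessian %*% P
    hessian <- (hessian + t(hessian)) / 2
  }

  ee <- eigen(hessian, symmetric = TRUE)
  lam <- ee$values
  zero <- abs(lam) < zero_tol
  n_zero <- sum(zero)
  if (n_zero > n_project) {
    stop(sprintf("found %d near-zero Hessian eigenvalues but only %d rigid-body modes expected",
                 n_zero, n_project))
  }
  keep <- !zero
  lam_k <- lam[keep]
  L <- ee$vectors[, keep, drop = FALSE]
  imag_idx <- which(lam_k < 0)
  freq <- sqrt(abs(lam_k))
  ord <- order(freq)
  freq <- freq[ord]
  L <- L[, ord, drop = FALSE]
  imag_flag <- seq_along(lam_k)[ord] %in% imag_idx
  imaginary <- tibble::tibble(
    mode = which(imag_flag),
    frequency = freq[imag_flag]
  )
  structure(
    list(q_eq = system$coords, freq = freq, modes = L,
         n_modes = length(freq), imaginary = imaginary,
         masses = m, n_projected = n_zero, cartesian = system$cartesian),
    class = "normal_mode_basis"
  )
}

#' @export
print.normal_mode_basis <- function(x, ...) {
  cat("<normal_mode_basis>", x$n_modes, "modes;",
      x$n_projected, "projected\n")
  cat("  frequencies (cm^-1):",
      paste(sprintf("%.1f", au_to_wavenumber(x$freq)), collapse = ", "), "\n")
  if (nrow(x$imaginary))
    cat("  imaginary modes:", paste(x$imaginary$mode, collapse = ", "), "\n")
  invisible(x)
}

# orthonormal mass-weighted translation (+ rotation) vectors
.rigid_body_vectors <- function(system, rotations = TRUE) {
  n <- system$n_atoms
  m <- system$masses
  d <- 3L * n
  sm <- sqrt(rep(m, each = 3L))
  vecs <- matrix(0, d, 0)
  for (ax in 1:3) {
    v <- numeric(d)
    v[seq(ax, d, by = 3L)] <- 1
    vecs <- cbind(vecs, v * sm)
  }
  if (rotations) {
    X <- matrix(system$coords, ncol = 3L, byrow = TRUE)
    com <- colSums(X * m) / sum(m)
    Xc <- sweep(X, 2L, com)
    for (ax in 1:3) {
      e <- numeric(3); e[ax] <- 1
      rv <- t(vapply(seq_len(n), function(i) .cross3(e, Xc[i, ]), numeric(3)))
      v <- as.vector(t(rv)) * sm
      vecs <- cbind(vecs, v)
    }
  }
  # orthonormalize, dropping null vectors (linear molecules)
  qr_ <- qr(vecs)
  keep <- abs(diag(qr.R(qr_)))[seq_len(qr_$rank)] > 1e-10
  qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Cartesian/normal-mode coordinate transforms
#'
#' The transform uses the fixed equilibrium mode basis `L`:
#' \eqn{z = L^T M^{1/2}(q - q_{eq})}, \eqn{p_z = L^T M^{-1/2} p}. For model
#' systems the mass matrix is the identity. The round trip through the
#' retained modes is the identity for any displacement within their span.
#'
#' @param q_cart,p_cart coordinate and momentum vectors in the surface's
#'   native coordinates.
#' @param q_nm,p_nm normal-mode coordinates and momenta.
#' @param basis a [normal_mode_analysis()] result.
#' @return `cart_to_nm()` a list with `q_nm` and `p_nm`; `nm_to_cart()` a
#'   list with `q_cart` and `p_cart`.
#' @export
cart_to_nm <- function(q_cart, p_cart, basis) {
  d <- length(basis$q_eq)
  if (length(q_cart) != d || length(p_cart) != d)
    stop("dimension mismatch: expected length ", d)
  sm <- sqrt(basis$masses)
  L <- basis$modes
  list(q_nm = drop(crossprod(L, (q_cart - basis$q_eq) * sm)),
       p_nm = drop(crossprod(L, p_cart / sm)))
}

#' @rdname cart_to_nm
#' @export
nm_to_cart <- function(q_nm, p_nm, basis) {
  if (length(q_nm) != basis$n_modes || length(p_nm) != basis$n_modes)
    stop("dimension mismatch: expected ", basis$n_modes, " modes")
  sm <- sqrt(basis$masses)
  L <- basis$modes
  list(q_cart = basis$q_eq + drop(L %*% q_nm) / sm,
       p_cart = drop(L %*% p_nm) * sm)
}

#' Harmonic ("quasiclassical") initial conditions
#'
#' Places the system at equilibrium and gives each normal mode the momentum
#' of its quantized harmonic energy: in mass-scaled normal coordinates
#' \eqn{p_{0,j} = \sqrt{(2 n_j + 1)\hbar\omega_j}}, so the energy above the
#' minimum is \eqn{\sum_j (n_j + \tfrac12)\hbar\omega_j} on a harmonic
#' surface. `quanta = 0` everywhere gives zero-point-energy conditions.
#'
#' @param basis a [normal_mode_analysis()] result.
#' @param quanta non-negative integer vector of per-mode quanta (recycled
#'   scalar allowed).
#' @return List with `q_nm` (zeros), `p_nm`, the native-coordinate
#'   equivalents `q_cart`/`p_cart`, and `energy` (harmonic estimate,
#'   hartree).
#' @export
harmonic_initial_conditions <- function(basis, quanta = 0) {
  nq <- rep_len(as.numeric(quanta), basis$n_modes)
  if (any(nq < 0) || any(nq != round(nq))) stop("quanta must be non-negative integers")
  p_nm <- sqrt((2 * nq + 1) * basis$freq)
  q_nm <- numeric(basis$n_modes)
  native <- nm_to_cart(q_nm, p_nm, basis)
  list(q_nm = q_nm, p_nm = p_nm,
       q_cart = native$q_cart, p_cart = native$p_cart,
       energy = sum((nq + 0.5) * basis$freq))
}

#' Rotate a surface into its normal-mode frame
#'
#' Produces a unit-mass [potential_surface()] over normal-mode coordinates
#' \eqn{z}: \eqn{\tilde V(z) = V(q_{eq} + M^{-1/2} L z)}, with gradient
#' \eqn{L^T M^{-1/2} \nabla V} and Hessian \eqn{L^T M^{-1/2} H M^{-1/2} L}.
#' Propagating on this surface is equivalent to propagating in the native
#' coordinates and transforming to normal modes at every step (the transform
#' is linear and fixed).
#'
#' @param surface the native [potential_surface()].
#' @param basis a [normal_mode_analysis()] result for that surface.
#' @return A mass-scaled [potential_surface()] of dimension `basis$n_modes`.
#' @export
nm_surface <- function(surface, basis) {
  sm <- sqrt(basis$masses)
  L <- basis$modes
  q_eq <- basis$q_eq
  to_native <- function(z) q_eq + drop(L %*% z) / sm
  hess_fn <- if (!is.null(surface$hessian)) {
    function(z) {
      H <- surface$hessian(to_native(z))
      crossprod(L, (H / outer(sm, sm)) %*% L)
    }
  } else NULL
  potential_surface(
    energy = function(z) surface$energy(to_native(z)),
    gradient = function(z) drop(crossprod(L, surface$gradient(to_native(z)) / sm)),
    hessian = hess_fn,
    dim = basis$n_modes,
    kind = paste0(surface$kind, "/nm"),
    parameters = surface$parameters
  )
}
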