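#' Sinc-DVR quantum oracle for 1D and 2D surfaces
#'
#' Brute-force eigenvalues of \eqn{-\tfrac12 \nabla^2 + V} on a uniform grid
#' using the sinc (Colbert-Miller) kinetic-energy matrix, independent of the
#' trajectory machinery. Unit masses are assumed (mass-scaled coordinates).
#' The grid is refined by doubling the point count until the highest requested
#' level moves by less than `tol`.
#'
#' @param surface a 1- or 2-dimensional [potential_surface()] in mass-scaled
#'   coordinates.
#' @param n_states number of eigenvalues to converge (counted from the ground
#'   state).
#' @param range per-dimension coordinate range, a list of `c(lo, hi)` (a
#'   single `c(lo, hi)` is accepted for 1D). When `NULL`, an automatic range
#'   covering the classically allowed region of the requested states (plus a
#'   tunneling margin) is derived from the surface.
#' @param n0 initial points per dimension (doubled on refinement).
#' @param tol convergence tolerance on the top requested level (hartree).
#' @param max_refine maximum number of grid doublings before giving up.
#' @return A [quantum_levels()] object with provenance `"grid-oracle"` and
#'   attributes `n_grid` (final points per dimension) and `range`.
#' @examples
#' grid_oracle(make_harmonic(0.01), n_states = 3)
#' @export
grid_oracle <- function(surface, n_states = 5, range = NULL,
                        n0 = NULL, tol = 1e-8, max_refine = 6) {
  d <- surface$dim
  if (d > 2L) stop("grid_oracle supports only 1- or 2-dimensional surfaces")
  if (is.null(n0)) n0 <- if (d == 1L) 64L else 24L
  if (is.null(range)) {
    range <- oracle_auto_range(surface, n_states)
  } else if (is.numeric(range) && d == 1L) {
    range <- list(range)
  }
  stopifnot(length(range) == d)

  prev <- NULL
  n <- as.integer(n0)
  for (r in 0:max_refine) {
    ev <- .sinc_dvr_levels(surface, range, n, n_states)
    if (!is.null(prev) && abs(ev[n_states] - prev[n_states]) < tol) {
      vmin <- .oracle_vmin(surface, range)
      lv <- quantum_levels(ev, "grid-oracle", v_min = vmin - 1e-12)
      attr(lv, "n_grid") <- n
      attr(lv, "range") <- range
      return(lv)
    }
    prev <- ev
    n <- 2L * n
  }
  stop(sprintf(paste0("grid oracle did not converge after %d refinements; ",
                      "last two estimates of level %d: %.12g, %.12g hartree"),
               max_refine, n_states - 1L, prev[n_states], ev[n_states]))
}

# minimum of V over the grid box (model minima sit at the origin, but the
# hbond mimic's coupled well can dip slightly below 0)
.oracle_vmin <- function(surface, range) {
  if (surface$dim == 1L) {
    x <- seq(range[[1]][1], range[[1]][2], length.out = 201)
    min(vapply(x, function(xi) surface$energy(xi), numeric(1)))
  } else {
    x <- seq(range[[1]][1], range[[1]][2], length.out = 61)
    y <- seq(range[[2]][1], range[[2]][2], length.out = 61)
    min(outer(x, y, Vectorize(function(a, b) surface$energy(c(a, b)))))
  }
}

# Colbert-Miller sinc kinetic matrix on a uniform grid, unit mass
.sinc_kinetic <- function(n, dx) {
  i <- seq_len(n)
  M <- outer(i, i, "-")
  K <- ifelse(M == 0, pi^2 / 3, 2 * (-1)^M / M^2)
  K / (2 * dx^2)
}

.sinc_dvr_levels <- function(surface, range, n, n_states) {
  d <- surface$dim
  if (d == 1L) {
    x <- seq(range[[1]][1], range[[1]][2], length.out = n)
    dx <- x[2] - x[1]
    V <- vapply(x, function(xi) surface$energy(xi), numeric(1))
    H <- .sinc_kinetic(n, dx)
    diag(H) <- diag(H) + V
  } else {
    x <- seq(range[[1]][1], range[[1]][2], length.out = n)
    y <- seq(range[[2]][1], range[[2]][2], length.out = n)
    dx <- x[2] - x[1]; dy <- y[2] - y[1]
    Tx <- .sinc_kinetic(n, dx)
    Ty <- .sinc_kinetic(n, dy)
    In <- diag(n)
    # ordering: index = (iy - 1) * n + ix  (x fastest)
    H <- kronecker(In, Tx) + kronecker(Ty, In)
    V <- as.vector(outer(seq_len(n), seq_len(n),
                         Vectorize(function(ix, iy) surface$energy(c(x[ix], y[iy])))))
    diag(H) <- diag(H) + V
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  sort(ev)[seq_len(n_states)]
}

# Automatic range: classical turning points at an energy covering the
# requested states, extended 60% into the forbidden region per side.
oracle_auto_range <- function(surface, n_states) {
  d <- surface$dim
  q0 <- numeric(d)
  H0 <- surface_hessian(surface, q0)
  w <- sqrt(pmax(eigen(H0, symmetric = TRUE, only.values = TRUE)$values, 1e-12))
  E_target <- (n_states + 2.5) * max(w)
  v0 <- surface$energy(q0)
  lapply(seq_len(d), function(j) {
    f <- function(s) {
      q <- q0; q[j] <- s
      surface$energy(q) - v0 - E_target
    }
    lo <- .find_turning(f, -1, sqrt(2 * E_target) / w[min(j, length(w))])
    hi <- .find_turning(f, +1, sqrt(2 * E_target) / w[min(j, length(w))])
    c(lo * 1.6, hi * 1.6)
  })
}

.find_turning <- function(f, dir, s0) {
  s <- dir * s0
  for (k in 1:60) {
    if (f(s) > 0) {
      r <- stats::uniroot(f, sort(c(0, s)))$root
      return(r)
    }
    s <- s * 1.3
  }
  stop("could not bracket a classical turning point; supply `range` explicitly")
}
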