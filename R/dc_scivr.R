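#' Mode subspaces
#'
#' @param indices unique mode indices (1-based).
#' @param label optional label.
#' @return An object of class `mode_subspace`.
#' @export
mode_subspace <- function(indices, label = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("subspace indices must be unique")
  if (any(indices < 1L)) stop("subspace indices must be positive")
  if (is.null(label)) label <- paste(indices, collapse = ",")
  structure(list(indices = sort(indices), label = label),
            class = "mode_subspace")
}

#' Greedy coupling-based mode partition
#'
#' Groups normal modes by descending off-diagonal magnitude of the Hessian
#' expressed in the mode basis, \eqn{|(L^T H L)_{ij}|}: pairs are visited
#' from the strongest coupling down (ties broken by lowest mode index) and
#' their groups merged whenever the merged size stays within `max_size`.
#' Modes whose couplings all fall below `threshold` remain singletons. The
#' result is an exact partition of `1..n_modes`.
#'
#' Because the equilibrium-point Hessian is diagonal in its own normal-mode
#' basis, an optional `displacement` probes Hessians displaced by
#' \eqn{\pm\delta} along each mode and takes the maximum coupling magnitude
#' over the probe set; with `displacement = 0` the couplings are read at
#' equilibrium in whatever basis is supplied.
#'
#' @param basis a [normal_mode_analysis()] result.
#' @param surface the native [potential_surface()].
#' @param max_size maximum modes per subspace (\eqn{\ge 1}).
#' @param threshold coupling magnitude below which modes stay singletons.
#' @param displacement probe displacement \eqn{\delta} along each mode
#'   (mass-scaled bohr); 0 reads the equilibrium Hessian only.
#' @return List of [mode_subspace()]s, ordered by lowest contained index.
#' @export
partition_modes <- function(basis, surface, max_size = 2L,
                            threshold = 1e-10, displacement = 0) {
  if (max_size < 1L) stop("max_size must be at least 1")
  nm <- basis$n_modes
  nms <- nm_surface(surface, basis)
  geoms <- list(numeric(nm))
  if (displacement > 0) {
    for (j in seq_len(nm)) {
      e <- numeric(nm); e[j] <- displacement
      geoms <- c(geoms, list(e), list(-e))
    }
  }
  C <- matrix(0, nm, nm)
  for (z in geoms) {
    H <- surface_hessian(nms, z)
    C <- pmax(C, abs(H))
  }
  diag(C) <- 0

  # pairs sorted by descending coupling, ties by lowest indices
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  ord <- order(-C[pairs], pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]

  group <- seq_len(nm)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (C[i, j] < threshold) break
    gi <- group[i]; gj <- group[j]
    if (gi == gj) next
    if (sum(group == gi) + sum(group == gj) <= max_size) {
      group[group == max(gi, gj)] <- min(gi, gj)
    }
  }
  ids <- unique(group[order(match(group, group))])
  subs <- lapply(sort(unique(group)), function(g) mode_subspace(which(group == g)))
  subs[order(vapply(subs, function(s) min(s$indices), integer(1)))]
}

#' Divide-and-conquer SCIVR spectrum on a mode subspace
#'
#' Evaluates the time-averaged semiclassical spectrum with every ingredient
#' restricted to a subspace of normal modes while the trajectory remains
#' full-dimensional: subspace components of \eqn{(q_t, p_t)}, subspace
#' sub-blocks of the monodromy for the prefactor phase, and a projected
#' action \eqn{\tilde S_t} whose kinetic part keeps only subspace momenta
#' and whose potential part is, per `potential_mode`:
#' \describe{
#'   \item{`difference`}{\eqn{\tilde V(t) = V(q_t) - V(q_t\,\mathrm{with\
#'     subspace\ coordinates\ reset\ to\ equilibrium})}}
#'   \item{`clamped`}{\eqn{\tilde V(t) = V(\mathrm{subspace\ coordinates\
#'     from\ the\ trajectory,\ all\ others\ at\ equilibrium})}}
#' }
#' On separable surfaces both variants reduce exactly to the subspace's own
#' potential and the result equals the corresponding lower-dimensional
#' [ta_scivr_spectrum()]. The sub-block monodromy is extracted without
#' re-symplectification; its symplectic defect is logged per step and the
#' maximum reported in the spectrum metadata.
#'
#' @param trajectory a full-dimensional [propagate()] result (normal-mode
#'   coordinates, monodromy present).
#' @param subspace a [mode_subspace()] (or integer vector of mode indices).
#' @param reference a [reference_state()] of the subspace dimension.
#' @param grid energy grid in cm\eqn{^{-1}}.
#' @param potential_mode `"difference"` (default) or `"clamped"`.
#' @param gamma width vector on the subspace for the prefactor phase;
#'   defaults to the reference's.
#' @return An [new_spectrum()] tibble with method `"dc-scivr"` and metadata
#'   `max_symplectic_defect`.
#' @export
dc_spectrum <- function(trajectory, subspace, reference,
                        grid = seq(0, 4000, by = 1),
                        potential_mode = c("difference", "clamped"),
                        gamma = NULL) {
  potential_mode <- match.arg(potential_mode)
  if (!inherits(subspace, "mode_subspace")) subspace <- mode_subspace(subspace)
  idx <- subspace$indices
  if (any(idx > trajectory$dim)) stop("subspace indices exceed trajectory dimension")
  ds <- length(idx)
  if (reference$dim != ds)
    stop("reference dimension (", reference$dim,
         ") does not match the subspace size (", ds, ")")
  if (is.null(gamma)) gamma <- reference$gamma
  surface <- trajectory$surface
  if (is.null(surface)) stop("trajectory carries no surface (needed for the projected potential)")

  n <- length(trajectory$time)
  tt <- trajectory$time
  dt <- trajectory$dt
  Tt <- tt[n]

  # projected action
  Vt <- numeric(n)
  full_dim <- trajectory$dim
  for (i in seq_len(n)) {
    qi <- trajectory$q[i, ]
    if (potential_mode == "difference") {
      q_reset <- qi; q_reset[idx] <- 0
      Vt[i] <- surface$energy(qi) - surface$energy(q_reset)
    } else {
      q_cl <- numeric(full_dim); q_cl[idx] <- qi[idx]
      Vt[i] <- surface$energy(q_cl)
    }
  }
  kin <- 0.5 * rowSums(trajectory$p[, idx, drop = FALSE]^2)
  lag <- kin - Vt
  S_proj <- c(0, cumsum(0.5 * dt * (lag[-n] + lag[-1L])))

  # sub-block prefactor phase + symplectic defect log
  Gi <- 1 / gamma
  detv <- complex(n)
  defect <- numeric(n)
  Js <- rbind(cbind(matrix(0, ds, ds), diag(ds)),
              cbind(-diag(ds), matrix(0, ds, ds)))
  for (i in seq_len(n)) {
    A <- trajectory$Mqq[idx, idx, i, drop = FALSE][, , 1]
    B <- trajectory$Mqp[idx, idx, i, drop = FALSE][, , 1]
    Cm <- trajectory$Mpq[idx, idx, i, drop = FALSE][, , 1]
    D <- trajectory$Mpp[idx, idx, i, drop = FALSE][, , 1]
    dim(A) <- dim(B) <- dim(Cm) <- dim(D) <- c(ds, ds)
    M <- rbind(cbind(A, B), cbind(Cm, D))
    defect[i] <- sqrt(sum((t(M) %*% Js %*% M - Js)^2))
    Z <- A + Gi * D * rep(gamma, each = ds) -
      1i * B * rep(gamma, each = ds) + 1i * Gi * Cm
    detv[i] <- det_complex(0.5 * Z)
  }
  if (any(Mod(detv) < 1e-10))
    stop("subspace Herman-Kluk determinant passes through zero; reduce dt")
  darg <- diff(Arg(detv))
  darg <- darg - 2 * pi * round(darg / (2 * pi))
  phi <- 0.5 * c(0, cumsum(darg))

  # subspace overlap series
  sub_traj <- list(time = tt, q = trajectory$q[, idx, drop = FALSE],
                   p = trajectory$p[, idx, drop = FALSE])
  ov <- .reference_overlap_series(sub_traj, reference)

  f <- ov * exp(1i * (S_proj + phi))
  E <- wavenumber_to_au(grid)
  I <- ft_intensity(tt, f, E) / ((2 * pi)^ds * 2 * pi * Tt)
  new_spectrum(grid, I, method = "dc-scivr", mode = subspace$label,
               total_time = Tt,
               extra = list(potential_mode = potential_mode,
                            n_v = ds, dt = dt,
                            max_symplectic_defect = max(defect)))
}
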