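#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectrum
#'
#' @param object an `sc_spectrum`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot sc_spectrum
#' @export
autoplot.sc_spectrum <- function(object, ...) {
  m <- spectrum_meta(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavenumber, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(paste("wavenumber (", cm^-1, ")")),
      y = "intensity (arb. units)",
      title = sprintf("%s spectrum%s", toupper(m$method),
                      if (!is.na(m$mode[1])) paste0(" - mode ", m$mode[1]) else "")
    ) +
    ggplot2::theme_minimal()
}

#' Overlay several spectra
#'
#' @param spectra named list of `sc_spectrum` objects.
#' @param normalize rescale each spectrum to unit maximum.
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra, normalize = TRUE) {
  if (is.null(names(spectra)))
    names(spectra) <- vapply(spectra, function(s) spectrum_meta(s)$method, "")
  df <- dplyr::bind_rows(lapply(names(spectra), function(nm) {
    s <- spectra[[nm]]
    y <- s$intensity
    if (normalize && max(y) > 0) y <- y / max(y)
    tibble::tibble(wavenumber = s$wavenumber, intensity = y, spectrum = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$intensity,
                                   colour = .data$spectrum)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("wavenumber (", cm^-1, ")")),
                  y = if (normalize) "intensity (normalized)" else "intensity (arb.)") +
    ggplot2::theme_minimal()
}

#' @rdname qct_spectrum
#' @param x an `sc_spectrum`.
#' @param ... unused.
#' @method tidy sc_spectrum
#' @export
tidy.sc_spectrum <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("wavenumber", "intensity")])
}

#' @rdname propagate
#' @param x an `sc_trajectory`.
#' @param ... unused.
#' @method glance sc_trajectory
#' @export
glance.sc_trajectory <- function(x, ...) {
  tibble::tibble(
    n_modes = x$dim,
    n_steps = x$n_steps,
    dt = x$dt,
    total_time = x$metadata$total_time,
    energy_fluctuation = x$metadata$energy_fluctuation,
    energy_drift = x$metadata$energy_drift,
    max_symplectic_defect = max(symplectic_defect(x)),
    has_prefactor_phase = !is.null(x$phi)
  )
}

#' @rdname propagate
#' @method tidy sc_trajectory
#' @export
tidy.sc_trajectory <- function(x, ...) {
  d <- x$dim
  out <- tibble::tibble(time = x$time, S = x$S, E = x$E)
  for (j in seq_len(d)) {
    out[[paste0("q", j)]] <- x$q[, j]
    out[[paste0("p", j)]] <- x$p[, j]
  }
  if (!is.null(x$phi)) out$phi <- x$phi
  out
}
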