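#' Spectrum container
#'
#' Spectra are tibbles with columns `wavenumber` (cm\eqn{^{-1}}, strictly
#' increasing) and `intensity` (arbitrary units, non-negative), carrying the
#' method tag, mode/subspace id and total trajectory time as attributes.
#'
#' @param wavenumber strictly increasing grid (cm\eqn{^{-1}}).
#' @param intensity non-negative intensities.
#' @param method method tag (`"qct"`, `"ta-scivr"`, `"dc-scivr"`, ...).
#' @param mode mode or subspace identifier.
#' @param total_time total trajectory time T (au).
#' @param extra named list merged into the metadata.
#' @return A tibble of class `sc_spectrum`.
#' @export
new_spectrum <- function(wavenumber, intensity, method = "unknown",
                         mode = NA, total_time = NA_real_, extra = list()) {
  if (any(diff(wavenumber) <= 0)) stop("spectrum grid must be strictly increasing")
  if (any(intensity < -1e-12 * max(abs(intensity), 1)))
    stop("intensities must be non-negative")
  out <- tibble::tibble(wavenumber = as.numeric(wavenumber),
                        intensity = pmax(as.numeric(intensity), 0))
  attr(out, "sc_meta") <- c(list(method = method, mode = mode,
                                 total_time = total_time), extra)
  class(out) <- c("sc_spectrum", class(out))
  out
}

#' @export
print.sc_spectrum <- function(x, ...) {
  m <- attr(x, "sc_meta")
  cat("<sc_spectrum> method:", m$method,
      " mode:", paste(m$mode, collapse = ","),
      " T:", m$total_time, "au\n")
  NextMethod()
}

#' Metadata of a spectrum
#' @param spectrum an `sc_spectrum`.
#' @return Named list of metadata.
#' @export
spectrum_meta <- function(spectrum) attr(spectrum, "sc_meta")

# Finite-time Fourier intensity |integral_0^T f(t) e^{iEt} dt|^2 by
# trapezoidal quadrature on the stored uniform grid, evaluated at arbitrary
# energies (hartree). Chunked over the energy grid to bound memory.
ft_intensity <- function(times, f, energies, chunk = 512L) {
  dt <- times[2] - times[1]
  w <- rep(dt, length(times))
  w[1] <- w[length(w)] <- dt / 2
  fw <- f * w
  out <- numeric(length(energies))
  for (s in seq(1L, length(energies), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(energies))
    M <- exp(1i * outer(energies[idx], times))
    out[idx] <- Mod(M %*% fw)^2
  }
  out
}

# FFT route: same trapezoid-weighted sum evaluated on the DFT grid
# E_k = 2 pi k / (n_pad dt), k = 0 .. n_pad-1. Must agree with
# ft_intensity() at those energies to roundoff.
ft_intensity_fft <- function(times, f, n_pad = NULL) {
  n <- length(times)
  dt <- times[2] - times[1]
  if (is.null(n_pad)) n_pad <- 2^ceiling(log2(4L * n))
  if (n_pad < n) stop("n_pad must be at least the series length")
  w <- rep(dt, n)
  w[1] <- w[n] <- dt / 2
  padded <- c(f * w, rep(0 + 0i, n_pad - n))
  amp <- stats::fft(padded, inverse = TRUE)   # sum f_j e^{+2*pi*i jk/n_pad}
  E <- 2 * pi * (0:(n_pad - 1L)) / (n_pad * dt)
  list(energies = E, intensity = Mod(amp)^2)
}

#' Quasiclassical trajectory (QCT) power spectrum of one normal mode
#'
#' \deqn{I_j(E) = \frac{1}{2\pi\hbar T}\left|\int_0^T p_j(t)\,
#'   e^{iEt/\hbar}\,dt\right|^2,}
#' the Fourier transform of the normal-mode momentum over the finite
#' trajectory time \eqn{T}. Peaks sit at the classical oscillation
#' frequencies of the mode; the finite observation time imposes a
#' sinc\eqn{^2} line shape of FWHM \eqn{\approx 5.566/T} (about 49
#' cm\eqn{^{-1}} at \eqn{T = 25\,000} au). No apodization window is applied
#' by default, preserving that line shape; a Hann window is available for
#' side-lobe suppression.
#'
#' @param trajectory a [propagate()] result in normal-mode coordinates.
#' @param mode mode index \eqn{j}.
#' @param grid energy grid in cm\eqn{^{-1}} (default 0-4000 at 1
#'   cm\eqn{^{-1}}).
#' @param window `"none"` (default) or `"hann"`.
#' @return An [new_spectrum()] tibble with method `"qct"`.
#' @export
qct_spectrum <- function(trajectory, mode, grid = seq(0, 4000, by = 1),
                         window = c("none", "hann")) {
  window <- match.arg(window)
  if (length(trajectory$time) < 2L) stop("empty trajectory")
  if (mode < 1L || mode > trajectory$dim)
    stop("mode index out of range 1..", trajectory$dim)
  pj <- trajectory$p[, mode]
  tt <- trajectory$time
  Tt <- tt[length(tt)]
  f <- as.complex(pj)
  if (window == "hann") f <- f * 0.5 * (1 - cos(2 * pi * tt / Tt))
  E <- wavenumber_to_au(grid)
  I <- ft_intensity(tt, f, E) / (2 * pi * Tt)
  new_spectrum(grid, I, method = "qct", mode = mode, total_time = Tt,
               extra = list(window = window, dt = trajectory$dt))
}

#' Write / read spectra as two-column TSV
#'
#' Columns `wavenumber` (cm\eqn{^{-1}}) and `intensity`, preceded by
#' `#`-prefixed `key: value` metadata lines (method, mode, total time,
#' units). The shipped reader reproduces the in-memory object.
#'
#' @param spectrum an `sc_spectrum`.
#' @param path destination / source file.
#' @return The path (writer, invisibly) or the restored `sc_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  m <- spectrum_meta(spectrum)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(m)) {
    v <- m[[k]]
    if (is.null(v) || length(v) == 0L) next
    writeLines(sprintf("# %s: %s", k,
                       paste(format(v, digits = 17, trim = TRUE), collapse = ",")), con)
  }
  writeLines("# units: wavenumber_cm-1\tintensity_arb", con)
  utils::write.table(
    data.frame(wavenumber = format(spectrum$wavenumber, digits = 17, trim = TRUE),
               intensity = format(spectrum$intensity, digits = 17, trim = TRUE)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- list()
  for (h in hdr) {
    h2 <- sub("^# ", "", h)
    k <- sub(":.*$", "", h2)
    v <- sub("^[^:]*: ?", "", h2)
    if (k == "units") next
    num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    kv[[k]] <- if (anyNA(num)) v else num
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t")
  meta_names <- setdiff(names(kv), c("method", "mode", "total_time"))
  new_spectrum(df$wavenumber, df$intensity,
               method = if (!is.null(kv$method)) kv$method else "unknown",
               mode = if (!is.null(kv$mode)) kv$mode else NA,
               total_time = if (!is.null(kv$total_time)) kv$total_time else NA_real_,
               extra = kv[meta_names])
}
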