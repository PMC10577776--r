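#' Read and write XYZ geometry files
#'
#' Standard XYZ dialect: an atom-count line, a comment line, then one
#' `element x y z` line per atom with coordinates in angstrom (converted to
#' bohr internally). Parse errors name the offending line.
#'
#' @param path file path.
#' @return `read_xyz()`: a list with `labels`, `coords` (n x 3 matrix,
#'   bohr), `masses` (electron-mass units, from [element_masses()]) and
#'   `comment`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("XYZ parse error: file has fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ parse error at line 1: atom count is not an integer")
  if (length(lines) < 2L + n)
    stop(sprintf("XYZ parse error: count line says %d atoms but only %d atom lines found",
                 n, max(length(lines) - 2L, 0L)))
  labels <- character(n)
  coords <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    ln <- 2L + i
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(parts) < 4L)
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", ln))
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(xyz))
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln))
    labels[i] <- parts[1]
    coords[i, ] <- xyz
  }
  list(labels = labels, coords = angstrom_to_bohr(coords),
       masses = element_masses(labels), comment = lines[2])
}

#' @rdname read_xyz
#' @param labels element symbols.
#' @param coords n x 3 coordinate matrix in bohr.
#' @param comment comment line.
#' @export
write_xyz <- function(path, labels, coords, comment = "") {
  coords <- bohr_to_angstrom(as.matrix(coords))
  lines <- c(as.character(nrow(coords)), comment,
             sprintf("%-3s %18.10f %18.10f %18.10f",
                     labels, coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' External electronic-structure engine adapter (contract only)
#'
#' Wraps an external energy/gradient provider as a [potential_surface()].
#' The engine is either an R function `function(q)` returning
#' `list(energy = <hartree>, gradient = <hartree/bohr vector>)`, or the path
#' to an executable invoked as `engine <geometry-file>` where the geometry
#' file holds one coordinate per line (bohr) and the engine must print
#' `energy: <value>` followed by `gradient: <g1> <g2> ...`. Calls are cached
#' by geometry hash, the call count is tracked, and engines that omit the
#' gradient or fail to respond raise a contract-violation error carrying any
#' captured output. No engine ships with the package: this is the adapter
#' contract for on-the-fly ab initio surfaces.
#'
#' @param engine R function or executable path.
#' @param dim dimensionality of the geometry vector.
#' @param coords `"mass_scaled"` or `"cartesian"` (see
#'   [potential_surface()]).
#' @param masses per-coordinate masses for Cartesian engines.
#' @return A [potential_surface()] whose `parameters$calls()` reports the
#'   number of true engine invocations (cache misses).
#' @export
external_surface_adapter <- function(engine, dim,
                                     coords = c("mass_scaled", "cartesian"),
                                     masses = NULL) {
  coords <- match.arg(coords)
  cache <- new.env(parent = emptyenv())
  n_calls <- 0L

  call_engine <- function(q) {
    if (is.function(engine)) {
      res <- engine(q)
    } else {
      geom_file <- tempfile("geom", fileext = ".txt")
      on.exit(unlink(geom_file), add = TRUE)
      writeLines(format(q, digits = 17, trim = TRUE), geom_file)
      out <- tryCatch(
        suppressWarnings(system2(engine, geom_file, stdout = TRUE, stderr = TRUE)),
        error = function(e) stop("engine did not respond: ", conditionMessage(e))
      )
      status <- attr(out, "status")
      if (!is.null(status) && status != 0)
        stop("engine exited with status ", status, "; output:\n",
             paste(out, collapse = "\n"))
      e_line <- grep("^energy:", out, value = TRUE)
      g_line <- grep("^gradient:", out, value = TRUE)
      if (!length(e_line))
        stop("engine contract violation: no 'energy:' line in output:\n",
             paste(out, collapse = "\n"))
      res <- list(
        energy = as.numeric(sub("^energy:\\s*", "", e_line[1])),
        gradient = if (length(g_line))
          as.numeric(strsplit(trimws(sub("^gradient:\\s*", "", g_line[1])), "\\s+")[[1]])
        else NULL
      )
    }
    if (is.null(res$gradient))
      stop("engine contract violation: gradient missing from engine response")
    if (length(res$gradient) != dim || !is.finite(res$energy))
      stop("engine contract violation: malformed energy/gradient for dim ", dim)
    res
  }

  lookup <- function(q) {
    key <- paste(format(q, digits = 17), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_calls <<- n_calls + 1L
    res <- call_engine(q)
    cache[[key]] <- res
    res
  }

  potential_surface(
    energy = function(q) lookup(q)$energy,
    gradient = function(q) lookup(q)$gradient,
    hessian = NULL,
    dim = dim, kind = "external-adapter",
    parameters = list(calls = function() n_calls),
    coords = coords, masses = masses
  )
}

#' Read and validate a pipeline configuration
#'
#' Declarative YAML with sections `surface` (kind + parameters), `trajectory`
#' (`dt`, `n_steps`, drift bound), `spectrum` (grid bounds/spacing, window),
#' `reference` (target mode, parity), optional `subspaces` (e.g.
#' `"1 | 2"` or a list of index vectors), `assignment` (rule file) and
#' `output` directory. Validation happens before any compute.
#'
#' @param path YAML config file.
#' @return Validated config list with defaults filled in (class
#'   `scivr_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a config list.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$surface$kind)) stop("config: surface.kind is required")
  traj <- cfg$trajectory
  if (is.null(traj)) traj <- list()
  traj$dt <- traj$dt %||% 10
  traj$n_steps <- traj$n_steps %||% 2500L
  traj$drift_tol <- traj$drift_tol %||% 1e-6
  if (traj$dt <= 0) stop("config: trajectory.dt must be positive")
  if (traj$n_steps <= 0) stop("config: trajectory.n_steps must be positive")
  cfg$trajectory <- traj
  sp <- cfg$spectrum
  if (is.null(sp)) sp <- list()
  sp$grid_min <- sp$grid_min %||% 0
  sp$grid_max <- sp$grid_max %||% 4000
  sp$grid_step <- sp$grid_step %||% 1
  sp$window <- sp$window %||% "none"
  if (sp$grid_max <= sp$grid_min) stop("config: spectrum grid bounds are inverted")
  cfg$spectrum <- sp
  if (!is.null(cfg$assignment$rules) && !file.exists(cfg$assignment$rules))
    stop("config: assignment rule file not found: ", cfg$assignment$rules)
  structure(cfg, class = "scivr_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse "1,3-5 | 2 | 6" style subspace specs
parse_subspaces <- function(spec) {
  if (is.list(spec)) return(lapply(spec, mode_subspace))
  parts <- strsplit(spec, "\\|")[[1]]
  lapply(parts, function(p) {
    toks <- strsplit(trimws(p), ",")[[1]]
    idx <- unlist(lapply(toks, function(tk) {
      tk <- trimws(tk)
      if (grepl("-", tk)) {
        ab <- as.integer(strsplit(tk, "-")[[1]])
        ab[1]:ab[2]
      } else as.integer(tk)
    }))
    mode_subspace(idx)
  })
}

# stable content hash (djb2 over the deparsed object, mod 2^31-1) for
# provenance stamps
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full single-trajectory workflow from a config
#'
#' Mirrors the method's end-to-end chain: build the surface, harmonic normal
#' modes, quantized ("harmonic") initial conditions, symplectic propagation
#' with monodromy, Herman-Kluk prefactor phase, QCT spectra per mode, TA- or
#' DC-SCIVR spectra per subspace, peak picking, and (optionally) tautomer
#' signature classification. Deterministic given the config; every artifact
#' header carries the config hash. A per-stage log records timings.
#'
#' @param config a [read_config()] result, a config list, or a path.
#' @param outdir output directory (created if missing); overrides the
#'   config's `output.dir`.
#' @return List with the basis, trajectory, named spectra, peak tables, the
#'   assignment report (or `NULL`) and the paths written.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "scivr_config")) config <- validate_config(config)
  outdir <- outdir %||% config$output$dir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  logf <- file.path(outdir, "pipeline.log")
  log_lines <- c(sprintf("config hash: %s", hash),
                 sprintf("package: scivr %s", as.character(utils::packageVersion("scivr"))),
                 paste("defaults:", "dt", config$trajectory$dt,
                       "n_steps", config$trajectory$n_steps,
                       "grid", config$spectrum$grid_min, "-",
                       config$spectrum$grid_max, "by", config$spectrum$grid_step))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      log_lines <<- c(log_lines, sprintf("stage %s: FAILED (%s)", name,
                                         conditionMessage(e)))
      writeLines(log_lines, logf)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines,
                    sprintf("stage %s: %.2fs", name,
                            proc.time()[["elapsed"]] - t0))
    res
  }

  surface <- stage("surface", build_surface(config$surface))
  basis <- stage("modes", {
    sys <- molecular_system(surface)
    normal_mode_analysis(compute_hessian(sys), sys)
  })
  nms <- nm_surface(surface, basis)
  ic <- harmonic_initial_conditions(basis, quanta = config$quanta %||% 0)
  traj <- stage("trajectory", propagate(
    nms, p0 = ic$p_nm, q0 = ic$q_nm,
    dt = config$trajectory$dt, n_steps = config$trajectory$n_steps,
    drift_tol = config$trajectory$drift_tol))
  traj <- stage("prefactor", hk_prefactor_phase(traj, gamma = basis$freq))
  log_lines <- c(log_lines,
                 sprintf("invariants: energy fluctuation %.3g, drift %.3g, symplectic defect %.3g",
                         traj$metadata$energy_fluctuation,
                         traj$metadata$energy_drift,
                         max(symplectic_defect(traj))))

  grid <- seq(config$spectrum$grid_min, config$spectrum$grid_max,
              by = config$spectrum$grid_step)
  window <- config$spectrum$window
  spectra <- list()
  paths <- character()
  for (j in seq_len(basis$n_modes)) {
    spec <- stage(paste0("qct-mode", j),
                  qct_spectrum(traj, j, grid = grid, window = window))
    nmk <- sprintf("qct_mode%d", j)
    spectra[[nmk]] <- spec
    p <- file.path(outdir, paste0(nmk, ".tsv"))
    write_spectrum(spec, p)
    paths <- c(paths, p)
  }
  subs <- if (!is.null(config$subspaces)) parse_subspaces(config$subspaces)
  else lapply(seq_len(basis$n_modes), mode_subspace)
  parity <- config$reference$parity %||% -1
  for (s in subs) {
    ref <- .subspace_mc_reference(basis, s, parity)
    spec <- stage(paste0("dc-", s$label),
                  dc_spectrum(traj, s, ref, grid = grid,
                              potential_mode = config$potential_mode %||% "difference"))
    nmk <- sprintf("dc_scivr_%s", gsub("[^0-9]+", "_", s$label))
    spectra[[nmk]] <- spec
    p <- file.path(outdir, paste0(nmk, ".tsv"))
    write_spectrum(spec, p)
    paths <- c(paths, p)
  }

  peaks <- lapply(spectra, pick_peaks)
  assignment <- NULL
  if (!is.null(config$assignment)) {
    rules <- if (!is.null(config$assignment$rules))
      read_signature_rules(config$assignment$rules) else read_signature_rules()
    # QCT peaks carry transition-scale frequencies directly comparable to
    # line lists; threshold against the strongest line across all modes so
    # near-empty spectra contribute no spurious peaks
    qct_peaks <- dplyr::bind_rows(peaks[grep("^qct_", names(peaks))])
    if (nrow(qct_peaks))
      qct_peaks <- qct_peaks[qct_peaks$height >= 0.1 * max(qct_peaks$height), ]
    assignment <- assign_tautomer(qct_peaks, rules)
    rp <- file.path(outdir, "assignment.json")
    jsonlite::write_json(list(label = assignment$label,
                              report = assignment$report),
                         rp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, rp)
    log_lines <- c(log_lines, paste("assignment:", assignment$label))
  }
  writeLines(log_lines, logf)
  list(basis = basis, trajectory = traj, spectra = spectra, peaks = peaks,
       assignment = assignment, paths = paths, config_hash = hash,
       log = logf)
}

# MC reference restricted to a subspace: ZPE momenta on the subspace modes,
# sign of the target (first) mode flipped in the second term
.subspace_mc_reference <- function(basis, subspace, parity = -1) {
  idx <- subspace$indices
  w <- basis$freq[idx]
  p_eq <- sqrt(w)
  p_flip <- p_eq
  p_flip[1] <- -p_flip[1]
  q0 <- numeric(length(idx))
  reference_state(c(1, parity),
                  list(coherent_state(p_eq, q0, w),
                       coherent_state(p_flip, q0, w)))
}

# surface factory for configs
build_surface <- function(spec) {
  kind <- spec$kind
  switch(kind,
         harmonic = ,
         `coupled-harmonic` = {
           omega <- as.numeric(spec$omega)
           coupling <- if (!is.null(spec$coupling))
             matrix(unlist(spec$coupling), length(omega), length(omega)) else NULL
           make_harmonic(omega, coupling)
         },
         morse = make_morse(spec$D, spec$alpha, spec$mass),
         `hbond-mimic` = make_hbond_mimic(
           omega_stretch = spec$omega_stretch %||% wavenumber_to_au(3450),
           omega_bath = spec$omega_bath %||% wavenumber_to_au(330),
           coupling = spec$coupling %||% 0),
         stop("unknown surface kind: ", kind))
}
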