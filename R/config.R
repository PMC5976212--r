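# YAML run configuration: schema validation, Table-1-style defaults, and a
# deterministic executor binding circuit, stimulus and measure choices.

.default_circuit_config <- list(
  retinal = list(A = 1, a = 0.62, B = 0.85, b = 1.26,
                 tau_phase = 42.5, weight_second = 0.38),
  ff_excitation = list(weight = 1, a = 0.1, delay = 0, tau = 5),
  ff_inhibition = list(weight = -0.5, a = 0.3, delay = 3, tau = 5),
  feedback = list()
)

.known_keys <- list(
  top = c("grid", "circuit", "task", "measure", "stimulus", "seed"),
  grid = c("nx", "extent", "nt", "duration"),
  circuit = c("retinal", "ff_excitation", "ff_inhibition", "feedback"),
  retinal = c("A", "a", "B", "b", "tau_phase", "weight_second"),
  ff = c("weight", "a", "delay", "tau"),
  fb = c("weight", "a", "delay", "tau")
)

reject_unknown <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where, paste(extra, collapse = ", ")))
  invisible(NULL)
}

merge_defaults <- function(block, defaults) {
  if (is.null(block)) return(defaults)
  utils::modifyList(defaults, block)
}

#' Read and validate a YAML run configuration
#'
#' The configuration has blocks `grid`, `circuit`, `task`, `measure`,
#' optional `stimulus` and `seed`.  The circuit block gives per-connection
#' kernel parameters (weight, Gaussian width `a`, delay, time constant) and
#' is merged over the stock cat parameter set, so an empty circuit block
#' reproduces the defaults exactly.  `feedback` is either a list of kernel
#' maps or one of the shorthand strings `"none"`, `"excitatory"`,
#' `"inhibitory"`, `"mixed"`.  Unknown keys anywhere are rejected; sign
#' rules are enforced (feedforward inhibition must carry negative weight,
#' feedforward excitation positive).
#'
#' @param path path to a YAML file.
#' @return A validated `run_config` list.
#' @seealso [run_config()] to execute it; example configurations ship under
#'   `system.file("configs", package = "edogsim")`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  reject_unknown(cfg, .known_keys$top, "configuration")
  task <- cfg$task
  if (is.null(task) || !task %in% c("irf", "area_response", "spatial_tuning",
                                    "temporal_tuning", "respond", "autocorr"))
    stop("`task` must be one of: irf, area_response, spatial_tuning, temporal_tuning, respond, autocorr")
  cfg$grid <- merge_defaults(cfg$grid,
                             list(nx = 128, extent = 10, nt = 512, duration = 1000))
  reject_unknown(cfg$grid, .known_keys$grid, "grid")

  circ <- cfg$circuit
  if (!is.null(circ)) reject_unknown(circ, .known_keys$circuit, "circuit")
  fb <- circ$feedback
  if (is.character(fb)) {
    fb <- switch(fb,
      none = list(),
      excitatory = list(list(weight = 0.5, a = 0.83, delay = 5, tau = 5)),
      inhibitory = list(list(weight = -0.5, a = 0.83, delay = 30, tau = 5)),
      mixed = list(list(weight = 0.3, a = 0.1, delay = 5, tau = 5),
                   list(weight = -0.6, a = 0.9, delay = 30, tau = 5)),
      stop("unknown feedback shorthand: ", fb))
  }
  circ$feedback <- NULL
  circ <- merge_defaults(circ, .default_circuit_config[c("retinal", "ff_excitation", "ff_inhibition")])
  reject_unknown(circ$retinal, .known_keys$retinal, "circuit$retinal")
  reject_unknown(circ$ff_excitation, .known_keys$ff, "circuit$ff_excitation")
  if (!is.null(circ$ff_inhibition)) {
    reject_unknown(circ$ff_inhibition, .known_keys$ff, "circuit$ff_inhibition")
    if (circ$ff_inhibition$weight >= 0)
      stop("circuit$ff_inhibition$weight must be negative (inhibitory connection)")
  }
  if (circ$ff_excitation$weight <= 0)
    stop("circuit$ff_excitation$weight must be positive (excitatory connection)")
  if (is.null(fb)) fb <- list()
  for (i in seq_along(fb)) {
    fb[[i]] <- merge_defaults(fb[[i]], list(tau = 5, delay = 5))
    reject_unknown(fb[[i]], .known_keys$fb, sprintf("circuit$feedback[[%d]]", i))
    if (is.null(fb[[i]]$weight) || is.null(fb[[i]]$a))
      stop("each feedback term needs `weight` and `a`")
  }
  circ$feedback <- fb
  cfg$circuit <- circ
  cfg$measure <- if (is.null(cfg$measure)) list() else cfg$measure
  structure(cfg, class = "run_config")
}

config_to_circuit <- function(cfg) {
  circ <- cfg$circuit
  retinal <- coupling_kernel(1,
    spatial_dog(circ$retinal$A, circ$retinal$a, circ$retinal$B, circ$retinal$b),
    temporal_biphasic(circ$retinal$tau_phase, circ$retinal$weight_second))
  mk <- function(p) coupling_kernel(p$weight, spatial_gaussian(p$a),
                                    temporal_exp_delay(p$delay, p$tau))
  edog_circuit(retinal, mk(circ$ff_excitation),
               if (!is.null(circ$ff_inhibition)) mk(circ$ff_inhibition),
               lapply(circ$feedback, mk))
}

config_to_grid <- function(cfg) {
  g <- cfg$grid
  stgrid(g$nx, g$extent, g$nt, g$duration)
}

#' Execute a run configuration
#'
#' Runs the requested computation deterministically and writes its outputs
#' under `out_dir`: curves as CSV (one row per sweep point), scalar
#' measures as a JSON summary keyed by measure name, and a plain-text log
#' recording the normalized configuration, grid and package version.
#'
#' Tasks: `irf` (spatiotemporal impulse response; center trace CSV plus
#' biphasic index and peak latency), `area_response` (size-tuning CSV plus
#' suppression index and optimal size), `spatial_tuning` and
#' `temporal_tuning` (tuning CSVs), `respond` (response to the configured
#' stimulus; center trace CSV), `autocorr` (seeded synthetic movie;
#' stimulus and response autocorrelation CSVs).
#'
#' @param cfg a `run_config` (from [read_run_config()]) or a path to one.
#' @param out_dir output directory, created if missing.
#' @param seed optional integer overriding the configured seed.
#' @param grid optional numeric vector `c(nx, extent, nt, duration)`
#'   overriding the configured grid.
#' @return Named list of the scalar measures written to the JSON summary,
#'   invisibly.
#' @export
run_config <- function(cfg, out_dir, seed = NULL, grid = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.null(grid)) {
    stopifnot(length(grid) == 4)
    cfg$grid <- list(nx = grid[1], extent = grid[2], nt = grid[3], duration = grid[4])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  circuit <- config_to_circuit(cfg)
  g <- config_to_grid(cfg)
  m <- cfg$measure
  scalars <- list()

  if (cfg$task == "irf") {
    fld <- spatiotemporal_irf(circuit, g)
    tr <- center_trace(fld)
    write_trace_csv(tr, file.path(out_dir, "center_trace.csv"), time = g$t)
    tm <- temporal_irf_measures(tr, g$dt)
    scalars <- list(i_bp = tm$i_bp, t_peak = tm$t_peak)
  } else if (cfg$task == "area_response") {
    diam <- sweep_values(m$diameters, default = seq(0.2, g$extent / 2, by = 0.2))
    curve <- area_response_curve(circuit, diam, g,
      kind = if (is.null(m$kind)) "spot" else m$kind,
      k_mag = if (is.null(m$k_mag)) 0 else m$k_mag)
    utils::write.csv(as.data.frame(curve), file.path(out_dir, "area_response.csv"),
                     row.names = FALSE)
    scalars <- list(suppression_index = suppression_index(curve),
                    optimal_size = optimal_size(curve))
  } else if (cfg$task == "spatial_tuning") {
    ks <- sweep_values(m$k_mag, default = seq(0, 4, by = 0.1))
    d_pg <- if (is.null(m$diameter)) 10 else m$diameter
    tune <- spatial_frequency_tuning(circuit, d_pg, ks, g)
    utils::write.csv(tune, file.path(out_dir, "spatial_tuning.csv"), row.names = FALSE)
    scalars <- list(peak_k = tune$k_mag[which.max(tune$response)],
                    peak_response = max(tune$response))
  } else if (cfg$task == "temporal_tuning") {
    ws <- sweep_values(m$omega, default = seq(0, 1, by = 0.01))
    k_mag <- if (is.null(m$k_mag)) 1 else m$k_mag
    tune <- temporal_frequency_tuning(circuit, k_mag, ws)
    utils::write.csv(tune, file.path(out_dir, "temporal_tuning.csv"), row.names = FALSE)
    scalars <- list(peak_omega = tune$omega[which.max(tune$response)],
                    peak_response = max(tune$response))
  } else if (cfg$task == "respond") {
    stim <- config_to_stimulus(cfg, g)
    fld <- compute_response(circuit, stim, g)
    if (fld$static) {
      ic <- g$nx / 2 + 1
      utils::write.csv(data.frame(x = g$x, response = fld$values[, ic]),
                       file.path(out_dir, "response_profile.csv"), row.names = FALSE)
      scalars <- list(center_response = fld$values[ic, ic])
    } else {
      tr <- center_trace(fld)
      write_trace_csv(tr, file.path(out_dir, "center_trace.csv"), time = g$t)
      scalars <- list(peak_response = max(abs(tr)))
    }
  } else if (cfg$task == "autocorr") {
    movie <- generate_synthetic_movie(g, seed = cfg$seed,
      spatial_exponent = if (is.null(m$spatial_exponent)) 2 else m$spatial_exponent,
      temporal_correlation = if (is.null(m$temporal_correlation)) 0.9
                             else m$temporal_correlation)
    max_lag <- if (is.null(m$max_lag)) 50 else m$max_lag
    window <- if (is.null(m$window)) min(40, g$nx) else m$window
    fld <- compute_response(circuit, movie, g)
    acf_s <- temporal_autocorrelation(movie, window, max_lag)
    acf_r <- temporal_autocorrelation(fld, window, max_lag)
    utils::write.csv(acf_s, file.path(out_dir, "stimulus_acf.csv"), row.names = FALSE)
    utils::write.csv(acf_r, file.path(out_dir, "response_acf.csv"), row.names = FALSE)
    scalars <- list(stimulus_acf_lag1 = acf_s$acf_mean[2],
                    response_acf_lag1 = acf_r$acf_mean[2])
  }

  jsonlite::write_json(scalars, file.path(out_dir, "measures.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("edogsim %s", as.character(utils::packageVersion("edogsim"))),
    sprintf("task: %s", cfg$task),
    sprintf("seed: %d", cfg$seed),
    sprintf("grid: nx=%d extent=%g nt=%d duration=%g", g$nx, g$extent, g$nt, g$duration),
    "config:",
    strsplit(yaml::as.yaml(unclass(cfg)), "\n")[[1]]
  ), file.path(out_dir, "run.log"))
  invisible(scalars)
}

# sweep lists come either as explicit vectors or as {from, to, by} maps
sweep_values <- function(spec, default) {
  if (is.null(spec)) return(default)
  if (is.list(spec) && all(c("from", "to") %in% names(spec)))
    return(seq(spec$from, spec$to, by = if (is.null(spec$by)) 1 else spec$by))
  as.numeric(unlist(spec))
}

config_to_stimulus <- function(cfg, grid) {
  s <- cfg$stimulus
  if (is.null(s) || is.null(s$type))
    stop("task `respond` requires a stimulus block with a `type`")
  contrast <- if (is.null(s$contrast)) 1 else s$contrast
  switch(s$type,
    grating = fullfield_grating(s$kx, if (is.null(s$ky)) 0 else s$ky,
                                if (is.null(s$omega)) 0 else s$omega, contrast),
    patch_grating = patch_grating(s$diameter, if (is.null(s$kx)) 0 else s$kx,
                                  if (is.null(s$ky)) 0 else s$ky,
                                  if (is.null(s$omega)) 0 else s$omega, contrast),
    spot = static_spot(s$diameter, contrast),
    flashing_spot = flashing_spot(s$diameter, s$onset, s$on_duration, contrast),
    stop("unknown stimulus type: ", s$type))
}
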