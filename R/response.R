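#' Relay-cell response fields
#'
#' `compute_response()` evaluates the firing-rate deviation of the
#' relay-cell layer, \eqn{R(\mathbf r, t) = \mathcal F^{-1}\{\tilde W_R
#' \tilde S\}}, by multiplying the circuit transfer function with the
#' stimulus Fourier transform on the grid and inverse-transforming.  Static
#' stimuli (non-drifting patch gratings, single-frame rasters, plain
#' matrices) route through the 2-D static path
#' \eqn{\tilde W_R^{sp}(k)\,\tilde H(0)\,\tilde S(k)}, which keeps the
#' constant retinal temporal factor \eqn{\tilde H(0)} explicitly so static
#' and dynamic paths agree numerically at omega = 0.
#'
#' Responses inherit periodic boundary conditions from the FFT: stimuli and
#' kernel supports should decay well inside the domain (a warning fires when
#' the widest kernel exceeds a quarter of the extent).  Units are arbitrary
#' — the model fixes no firing-rate scale — so downstream measures are
#' ratios or argmax positions.
#'
#' @param circuit an [edog_circuit()].
#' @param stimulus an `edog_stimulus`, or a plain `nx x nx` matrix treated
#'   as a static image of luminance deviations.
#' @param grid an [stgrid()].
#' @return A `response_field`: list with `values` (real array, 3-D over
#'   (x, y, t) or 2-D for the static path, centered spatial order), `grid`,
#'   `static` flag, and provenance (`circuit`, `stimulus` description).
#' @export
compute_response <- function(circuit, stimulus, grid) {
  stopifnot(inherits(circuit, "edog_circuit"), inherits(grid, "stgrid"))
  check_grid_resolution(circuit, grid)
  if (is_static_stimulus(stimulus)) {
    S <- stimulus_ft_spatial(stimulus, grid)
    W <- static_transfer(circuit, kmag_grid(grid)) * retinal_H0(circuit)
    vals <- take_real(ift_xy(W * S, grid), tol = 1e-8)
    return(new_response_field(vals, grid, circuit, stimulus, static = TRUE))
  }
  if (!inherits(stimulus, "edog_stimulus"))
    stop("`stimulus` must be an edog_stimulus or a static image matrix")
  S <- stimulus_ft(stimulus, grid)
  K <- kmag_grid(grid)
  for (j in seq_len(grid$nt))
    S[, , j] <- S[, , j] * transfer_function(circuit, K, grid$omega[j])
  vals <- take_real(ift_xyt(hermitize(S), grid), tol = 1e-8)
  new_response_field(vals, grid, circuit, stimulus)
}

new_response_field <- function(values, grid, circuit, stimulus, static = FALSE) {
  structure(list(values = values, grid = grid, static = static,
                 circuit = circuit,
                 stimulus = if (is.character(stimulus)) stimulus
                            else class(stimulus)[1]),
            class = "response_field")
}

#' @export
print.response_field <- function(x, ...) {
  cat(sprintf("Relay-cell response field (%s, stimulus: %s)\n",
              if (x$static) "static 2-D" else "spatiotemporal 3-D", x$stimulus))
  cat(sprintf("  grid: %d x %d px over %g deg", x$grid$nx, x$grid$nx, x$grid$extent))
  if (!x$static) cat(sprintf(", %d steps over %g ms", x$grid$nt, x$grid$duration))
  cat(sprintf("\n  range: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Response amplitude to a full-field drifting grating
#'
#' For a grating aligned with the grid, the response of every neuron is a
#' pure sinusoid at \eqn{(\mathbf k_g, \omega_g)} whose amplitude is
#' \eqn{C\,|\tilde W_R(\mathbf k_g, \omega_g)|}; this shortcut evaluates the
#' transfer function directly instead of simulating the full field.
#'
#' @param circuit an [edog_circuit()].
#' @param k_mag grating wavenumber magnitude, rad/deg.
#' @param omega grating drift frequency, rad/ms.
#' @param contrast grating contrast.
#' @return Non-negative scalar amplitude (arbitrary units).
#' @export
fullfield_amplitude <- function(circuit, k_mag, omega = 0, contrast = 1) {
  abs(contrast) * abs(transfer_function(circuit, k_mag, omega))
}

#' Time series of the center neuron
#'
#' Extracts the trace of the neuron at the grid center (1-based index
#' `nx/2 + 1` on each spatial axis) from a spatiotemporal response field.
#'
#' @param field a 3-D `response_field`.
#' @return Numeric vector of length `nt` (the field's time axis).
#' @export
center_trace <- function(field) {
  stopifnot(inherits(field, "response_field"))
  if (field$static || length(dim(field$values)) != 3L)
    stop("`center_trace()` requires a spatiotemporal (3-D) response field")
  ic <- field$grid$nx / 2 + 1
  field$values[ic, ic, ]
}

#' Write a center trace or curve to CSV
#'
#' @param x a data frame (e.g. an area-response curve) or a numeric vector.
#' @param path output file.
#' @param time optional time axis for vector input.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path, time = NULL) {
  if (is.numeric(x) && is.null(dim(x)))
    x <- data.frame(time = if (is.null(time)) seq_along(x) - 1 else time,
                    response = x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
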