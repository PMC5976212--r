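#' Assemble an eDOG relay-cell circuit
#'
#' A circuit bundles the descriptive retinal impulse response `W_G` with the
#' mechanistic coupling kernels of the dLGN loop: direct feedforward
#' excitation `K_RG` (retina to relay cell), optional indirect feedforward
#' inhibition `K_RIG` (retina to relay cell via intrageniculate
#' interneurons), and any number of thalamo-cortico-thalamic feedback loop
#' terms `K_RCR` (relay to cortex to relay; excitatory terms carry positive
#' weight, inhibitory terms negative; mixed feedback is two terms).  The
#' relay-cell transfer function in Fourier space is
#'
#' \deqn{\tilde W_R(k, \omega) =
#'  \frac{w_{RG}\tilde f_{RG}\tilde h_{RG} + w_{RIG}\tilde f_{RIG}\tilde h_{RIG}}
#'       {1 - \sum_j w_j \tilde f_j \tilde h_j}\;
#'  \tilde F(k) \tilde H(\omega),}
#'
#' where the numerator sums the feedforward arms, the denominator the
#' feedback loop terms, and \eqn{\tilde F \tilde H} is the retinal input.
#' The half-wave rectification of the cortical populations drops out of this
#' expression analytically, so relay responses are linear (and may be
#' negative; no rectification is applied at the geniculate level).
#'
#' @param retinal retinal impulse response: a [coupling_kernel()] with DOG
#'   spatial and biphasic temporal parts; its weight must be 1.
#' @param ff_excitation feedforward excitation `K_RG`: a kernel with
#'   positive weight.
#' @param ff_inhibition optional feedforward inhibition `K_RIG`: a kernel
#'   with negative weight, or `NULL` for none.
#' @param feedback list of feedback-loop kernels (possibly empty).
#' @return An object of class `edog_circuit`.
#' @seealso [edog_circuit_table1()] for the stock cat-dLGN parameterization.
#' @export
edog_circuit <- function(retinal, ff_excitation, ff_inhibition = NULL,
                         feedback = list()) {
  stopifnot(inherits(retinal, "coupling_kernel"),
            inherits(ff_excitation, "coupling_kernel"))
  if (!inherits(retinal$spatial, "spatial_dog") ||
      !inherits(retinal$temporal, "temporal_biphasic"))
    stop("`retinal` must combine a DOG spatial profile with a biphasic temporal profile")
  if (retinal$weight != 1)
    stop("the retinal impulse response has fixed weight 1")
  if (ff_excitation$weight <= 0)
    stop("feedforward excitation weight must be positive")
  if (!is.null(ff_inhibition)) {
    stopifnot(inherits(ff_inhibition, "coupling_kernel"))
    if (ff_inhibition$weight >= 0)
      stop("feedforward inhibition weight must be negative")
  }
  stopifnot(is.list(feedback),
            all(vapply(feedback, inherits, logical(1), "coupling_kernel")))
  structure(list(retinal = retinal,
                 ff_excitation = ff_excitation,
                 ff_inhibition = ff_inhibition,
                 feedback = feedback),
            class = "edog_circuit")
}

#' Stock circuit configurations for cat dLGN
#'
#' Builds an [edog_circuit()] from the standard cat parameter set: retinal
#' DOG with center strength 1 and width 0.62 deg, surround strength 0.85 and
#' width 1.26 deg; biphasic retinal time course with 42.5 ms phases and
#' second-phase weight 0.38; feedforward excitation of weight 1, width
#' 0.1 deg, instantaneous exponential coupling with 5 ms time constant;
#' feedforward inhibition of weight -0.5, width 0.3 deg, 3 ms delay.
#' Feedback configurations: `"excitatory"` (weight 0.5, width 0.83 deg),
#' `"inhibitory"` (weight -0.5, width 0.83 deg), `"mixed"` (narrow
#' excitatory arm, weight 0.3, width 0.1 deg, plus broad inhibitory arm,
#' weight -0.6, width 0.9 deg), or `"none"`.  All feedback loops use a 5 ms
#' decay time constant; corticothalamic delays default to a fast excitatory
#' (5 ms) and slow inhibitory (30 ms) loop, the configuration that best
#' matches feedback phenomenology, and can be set anywhere in the studied
#' 5-30 ms range.
#'
#' @param feedback which feedback configuration to build.
#' @param feedback_factor scalar multiplying the default feedback weight(s);
#'   0 reproduces `"none"` exactly.
#' @param delta_ex,delta_in corticothalamic loop delays (ms) for the
#'   excitatory and inhibitory feedback arms.
#' @param ff_inhibition include the feedforward inhibition arm `K_RIG`?
#' @return An [edog_circuit()].
#' @examples
#' circ <- edog_circuit_table1("mixed")
#' static_transfer(circ, k_mag = 0)
#' @export
edog_circuit_table1 <- function(feedback = c("none", "excitatory", "inhibitory", "mixed"),
                                feedback_factor = 1,
                                delta_ex = 5, delta_in = 30,
                                ff_inhibition = TRUE) {
  feedback <- match.arg(feedback)
  stopifnot(is.numeric(feedback_factor), feedback_factor >= 0)
  retinal <- coupling_kernel(1, spatial_dog(A = 1, a = 0.62, B = 0.85, b = 1.26),
                             temporal_biphasic(tau_phase = 42.5, weight_second = 0.38))
  ffe <- coupling_kernel(1, spatial_gaussian(0.1), temporal_exp_delay(0, 5))
  ffi <- if (ff_inhibition)
    coupling_kernel(-0.5, spatial_gaussian(0.3), temporal_exp_delay(3, 5))
  fb <- switch(feedback,
    none = list(),
    excitatory = list(
      coupling_kernel(0.5 * feedback_factor, spatial_gaussian(0.83),
                      temporal_exp_delay(delta_ex, 5))),
    inhibitory = list(
      coupling_kernel(-0.5 * feedback_factor, spatial_gaussian(0.83),
                      temporal_exp_delay(delta_in, 5))),
    mixed = list(
      coupling_kernel(0.3 * feedback_factor, spatial_gaussian(0.1),
                      temporal_exp_delay(delta_ex, 5)),
      coupling_kernel(-0.6 * feedback_factor, spatial_gaussian(0.9),
                      temporal_exp_delay(delta_in, 5))))
  if (feedback_factor == 0) fb <- list()
  edog_circuit(retinal, ffe, ffi, fb)
}

#' Remove the cortical feedback from a circuit
#'
#' @param circuit an [edog_circuit()].
#' @return The same circuit with an empty feedback list.
#' @export
strip_feedback <- function(circuit) {
  stopifnot(inherits(circuit, "edog_circuit"))
  circuit$feedback <- list()
  circuit
}

#' @export
print.edog_circuit <- function(x, ...) {
  cat("eDOG relay-cell circuit\n")
  cat(sprintf("  retinal DOG (A = %g, a = %g, B = %g, b = %g), biphasic (tau = %g ms, B = %g)\n",
              x$retinal$spatial$A, x$retinal$spatial$a,
              x$retinal$spatial$B, x$retinal$spatial$b,
              x$retinal$temporal$tau_phase, x$retinal$temporal$weight_second))
  cat(sprintf("  feedforward excitation: w = %+g\n", x$ff_excitation$weight))
  if (!is.null(x$ff_inhibition))
    cat(sprintf("  feedforward inhibition: w = %+g\n", x$ff_inhibition$weight))
  if (length(x$feedback))
    cat(sprintf("  feedback loop terms: %s\n",
                paste(sprintf("%+g", vapply(x$feedback, `[[`, numeric(1), "weight")),
                      collapse = ", ")))
  else cat("  no cortical feedback\n")
  invisible(x)
}

## ---- transfer function ------------------------------------------------

# instability policy: error below `tol_error`, warn below `tol_warn`
.instability_tol <- c(error = 1e-6, warn = 0.05)

# feedback loop denominator 1 - sum w f~ h~ at (|k|, omega)
loop_denominator <- function(circuit, k_mag, omega) {
  den <- 1 + 0i
  for (kern in circuit$feedback)
    den <- den - kernel_ft(kern, k_mag, omega)
  den
}

check_denominator <- function(den, k_mag, omega, static = FALSE) {
  mag <- abs(den)
  i <- which.min(mag)
  if (mag[i] < .instability_tol[["error"]]) {
    stop(sprintf(
      "feedback loop gain is unstable: |denominator| = %.3g at |k| = %.4g rad/deg%s",
      mag[i], k_mag[[min(i, length(k_mag))]],
      if (static) "" else sprintf(", omega = %.4g rad/ms", omega[[min(i, length(omega))]])))
  }
  if (mag[i] < .instability_tol[["warn"]])
    warning(sprintf("feedback loop gain close to instability: min |denominator| = %.3g", mag[i]))
  invisible(NULL)
}

#' Relay-cell transfer function
#'
#' Evaluates the closed-form Fourier-space relay-cell impulse-response
#' function of the circuit at spatial frequency magnitude `k_mag` and
#' temporal angular frequency `omega` (see [edog_circuit()] for the
#' formula).  `static_transfer()` evaluates the static (omega = 0) reduction
#'
#' \deqn{\tilde W_R^{sp}(k) = \frac{w_{RG}\tilde f_{RG} + w_{RIG}\tilde f_{RIG}}
#'       {1 - \sum_j w_j \tilde f_j}\, \tilde F(k),}
#'
#' which uses \eqn{\tilde h(0) = 1} for all exponential couplings and drops
#' the constant retinal temporal factor \eqn{\tilde H(0)}; hence
#' `static_transfer(c, k) * retinal_H0(c) == transfer_function(c, k, 0)`.
#'
#' @param circuit an [edog_circuit()].
#' @param k_mag spatial angular frequency magnitude, rad/deg (vectorized).
#' @param omega temporal angular frequency, rad/ms (recycled against `k_mag`).
#' @return Complex response gain (real for `static_transfer`).  An error is
#'   raised when the feedback loop denominator magnitude falls below 1e-6
#'   (instability), and a warning between 1e-6 and 0.05.
#' @export
transfer_function <- function(circuit, k_mag, omega) {
  stopifnot(inherits(circuit, "edog_circuit"))
  num <- kernel_ft(circuit$ff_excitation, k_mag, omega)
  if (!is.null(circuit$ff_inhibition))
    num <- num + kernel_ft(circuit$ff_inhibition, k_mag, omega)
  den <- loop_denominator(circuit, k_mag, omega)
  check_denominator(den, k_mag, omega)
  num / den *
    ft_spatial(circuit$retinal$spatial, k_mag) *
    ft_temporal(circuit$retinal$temporal, omega)
}

#' @rdname transfer_function
#' @export
static_transfer <- function(circuit, k_mag) {
  stopifnot(inherits(circuit, "edog_circuit"))
  num <- circuit$ff_excitation$weight * ft_spatial(circuit$ff_excitation$spatial, k_mag)
  if (!is.null(circuit$ff_inhibition))
    num <- num + circuit$ff_inhibition$weight * ft_spatial(circuit$ff_inhibition$spatial, k_mag)
  den <- rep(1, length(k_mag))
  for (kern in circuit$feedback)
    den <- den - kern$weight * ft_spatial(kern$spatial, k_mag)
  check_denominator(den, k_mag, 0, static = TRUE)
  num / den * ft_spatial(circuit$retinal$spatial, k_mag)
}

#' Zero-frequency retinal temporal factor
#'
#' The constant \eqn{\tilde H(0) = (2\tau/\pi)(1 - B)} of the retinal
#' biphasic time course, the proportionality factor between the static and
#' dynamic transfer paths at omega = 0.
#'
#' @param circuit an [edog_circuit()].
#' @return A real scalar, ms.
#' @export
retinal_H0 <- function(circuit) {
  Re(ft_temporal(circuit$retinal$temporal, 0))
}

## ---- grid checks ------------------------------------------------------

circuit_kernels <- function(circuit) {
  c(list(circuit$retinal, circuit$ff_excitation),
    if (!is.null(circuit$ff_inhibition)) list(circuit$ff_inhibition),
    circuit$feedback)
}

min_spatial_width <- function(circuit) {
  min(vapply(circuit_kernels(circuit), function(kern) {
    sp <- kern$spatial
    if (inherits(sp, "spatial_dog")) min(sp$a, sp$b) else sp$a
  }, numeric(1)))
}

max_spatial_width <- function(circuit) {
  max(vapply(circuit_kernels(circuit), function(kern) {
    sp <- kern$spatial
    if (inherits(sp, "spatial_dog")) max(sp$a, sp$b) else sp$a
  }, numeric(1)))
}

# total temporal support estimate: biphasic support + sum of (delay + 5 tau)
# over exponential couplings along the slowest path
temporal_support <- function(circuit) {
  biph <- 2 * circuit$retinal$temporal$tau_phase
  arms <- vapply(circuit_kernels(circuit)[-1], function(kern) {
    tp <- kern$temporal
    if (inherits(tp, "temporal_exp_delay")) tp$delay + 5 * tp$tau else 2 * tp$tau_phase
  }, numeric(1))
  biph + max(arms, 0)
}

check_grid_resolution <- function(circuit, grid) {
  amin <- min_spatial_width(circuit)
  if (grid$dx > amin)
    warning(sprintf(
      "grid spacing dx = %.4g deg does not resolve the narrowest kernel width (%.4g deg); use a finer grid",
      grid$dx, amin))
  if (4 * max_spatial_width(circuit) > grid$extent)
    warning("kernel spatial support exceeds a quarter of the grid extent; periodic wrap-around may bias responses")
  invisible(NULL)
}

## ---- impulse-response fields ------------------------------------------

#' Spatial impulse-response field of the relay cell
#'
#' Inverse 2-D Fourier transform of [static_transfer()] sampled on the grid:
#' the relay cell's spatial receptive field (static path; the constant
#' retinal temporal factor is omitted, so values are in deg^-2 up to that
#' constant).  The field is real and circularly symmetric; the analyzed
#' neuron sits at index `nx/2 + 1` on each axis.
#'
#' @param circuit an [edog_circuit()].
#' @param grid an [stgrid()] fine enough to resolve all kernels (a warning
#'   is emitted otherwise).
#' @return A `spatial_field` object: list with `values` (nx x nx matrix in
#'   centered order), `x` (axis coordinates, deg) and `grid`.
#' @export
spatial_irf <- function(circuit, grid) {
  stopifnot(inherits(grid, "stgrid"))
  check_grid_resolution(circuit, grid)
  W <- static_transfer(circuit, kmag_grid(grid))
  vals <- take_real(ift_xy(W, grid), tol = 1e-10)
  structure(list(values = vals, x = grid$x, grid = grid,
                 circuit = circuit),
            class = "spatial_field")
}

#' Spatiotemporal impulse-response field of the relay cell
#'
#' Inverse 3-D Fourier transform of the full transfer function on the grid:
#' the response of the relay-cell layer to a point flash at the grid center
#' at t = 0.  Causality demands the field decays to zero well before the end
#' of the time window; a warning is emitted when the late-time magnitude
#' exceeds 1e-3 of the peak (enlarge `duration` in that case).  The residue
#' floor is set by spectral truncation of the biphasic retinal kernel, whose
#' transform decays only algebraically in omega.
#'
#' @inheritParams spatial_irf
#' @return A `response_field` object (see [compute_response()]) with a 3-D
#'   `values` array over (x, y, t).
#' @export
spatiotemporal_irf <- function(circuit, grid) {
  stopifnot(inherits(grid, "stgrid"))
  check_grid_resolution(circuit, grid)
  if (grid$duration < 2 * temporal_support(circuit))
    warning("grid duration is below twice the total kernel temporal support; wrap-around risk")
  K <- kmag_grid(grid)
  W <- array(0i, dim = c(grid$nx, grid$nx, grid$nt))
  for (j in seq_len(grid$nt))
    W[, , j] <- transfer_function(circuit, K, grid$omega[j])
  vals <- take_real(ift_xyt(hermitize(W), grid), tol = 1e-8)
  late <- vals[, , grid$nt - seq_len(max(2L, grid$nt %/% 32L)) + 1L]
  if (max(abs(late)) > 1e-3 * max(abs(vals)))
    warning("impulse response has not decayed by the end of the time window; enlarge `duration`")
  new_response_field(vals, grid, circuit, stimulus = "impulse")
}

#' Scan the feedback loop gain for instability
#'
#' Evaluates the loop denominator \eqn{1 - \sum_j w_j \tilde f_j \tilde h_j}
#' over the discrete (k, omega) grid and reports the minimum magnitude and
#' the frequency where it occurs.  A no-feedback circuit returns exactly 1.
#'
#' @inheritParams spatial_irf
#' @return List with `min_denominator`, `k` (rad/deg) and `omega` (rad/ms).
#' @export
stability_check <- function(circuit, grid) {
  stopifnot(inherits(circuit, "edog_circuit"), inherits(grid, "stgrid"))
  K <- kmag_grid(grid)
  best <- list(min_denominator = Inf, k = NA_real_, omega = NA_real_)
  for (j in seq_len(grid$nt)) {
    den <- abs(loop_denominator(circuit, K, grid$omega[j]))
    i <- which.min(den)
    if (den[i] < best$min_denominator)
      best <- list(min_denominator = den[i], k = K[i], omega = grid$omega[j])
  }
  best
}
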