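#' Spatial profile functions
#'
#' Circularly symmetric, normalized spatial profiles used for receptive fields
#' and coupling kernels.  `spatial_gaussian()` is the unit-mass Gaussian
#'
#' \deqn{f(r; a) = \frac{1}{\pi a^2} e^{-r^2/a^2},}
#'
#' where `a` is the width parameter in degrees of visual angle.
#' `spatial_dog()` is the difference-of-Gaussians (DOG) profile
#'
#' \deqn{F(r) = \frac{A}{\pi a^2} e^{-r^2/a^2} - \frac{B}{\pi b^2} e^{-r^2/b^2},}
#'
#' whose first term is the receptive-field center and second term the
#' antagonistic surround.  Its integral over the plane is `A - B`.
#'
#' @param a center (or only) Gaussian width, degrees; must be positive.
#' @param A,B center and surround strengths, both positive.
#' @param b surround width, degrees; must be positive.
#' @return An object of class `spatial_gaussian` or `spatial_dog`, both
#'   inheriting from `spatial_profile`.
#' @seealso [eval_spatial()], [ft_spatial()]
#' @examples
#' f <- spatial_gaussian(a = 0.62)
#' eval_spatial(f, 0)        # 1 / (pi * 0.62^2)
#' ft_spatial(f, 0)          # 1: the profile is normalized
#' @export
spatial_gaussian <- function(a) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  structure(list(a = a), class = c("spatial_gaussian", "spatial_profile"))
}

#' @rdname spatial_gaussian
#' @export
spatial_dog <- function(A, a, B, b) {
  vals <- c(A = A, a = a, B = B, b = b)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals > 0))
  structure(list(A = A, a = a, B = B, b = b),
            class = c("spatial_dog", "spatial_profile"))
}

#' Temporal profile functions
#'
#' Normalized (or near-normalized) temporal profiles.  `temporal_biphasic()`
#' is the biphasic retinal impulse response
#'
#' \deqn{H(t; \tau, B) = \begin{cases}
#'   \sin(\pi t/\tau)   & 0 \le t \le \tau \\
#'   B \sin(\pi t/\tau) & \tau < t \le 2\tau \\
#'   0 & \text{otherwise},
#' \end{cases}}
#'
#' with phase duration `tau_phase` (ms) and second-phase weight
#' `weight_second`; note \eqn{\sin} is negative on the second phase, so the
#' rebound is negative for positive weights.  `temporal_exp_delay()` is the
#' delayed exponential decay used for synaptic coupling,
#'
#' \deqn{h(t; \Delta, \tau) = \frac{1}{\tau}
#'   e^{-(t-\Delta)/\tau}\,\theta(t-\Delta),}
#'
#' where `delay` \eqn{\Delta} (ms) lumps axonal and synaptic latency and
#' `tau` (ms) is the decay time constant.  The delayed exponential integrates
#' to one exactly.
#'
#' @param tau_phase duration of each of the two phases, ms.
#' @param weight_second weight of the second (rebound) phase, dimensionless.
#' @param delay onset delay \eqn{\Delta \ge 0}, ms.
#' @param tau decay time constant, ms; must be positive.
#' @return An object of class `temporal_biphasic` or `temporal_exp_delay`,
#'   both inheriting from `temporal_profile`.
#' @seealso [eval_temporal()], [ft_temporal()]
#' @export
temporal_biphasic <- function(tau_phase, weight_second) {
  stopifnot(is.numeric(tau_phase), length(tau_phase) == 1L, tau_phase > 0,
            is.numeric(weight_second), length(weight_second) == 1L,
            is.finite(weight_second))
  structure(list(tau_phase = tau_phase, weight_second = weight_second),
            class = c("temporal_biphasic", "temporal_profile"))
}

#' @rdname temporal_biphasic
#' @export
temporal_exp_delay <- function(delay, tau) {
  stopifnot(is.numeric(delay), length(delay) == 1L, delay >= 0,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(delay = delay, tau = tau),
            class = c("temporal_exp_delay", "temporal_profile"))
}

#' Evaluate a spatial profile in real space
#'
#' @param profile a [spatial_gaussian()] or [spatial_dog()] object.
#' @param r radial distance from the profile center, degrees; vectorized,
#'   all values must be finite and non-negative.
#' @return Profile amplitude at radius `r`, in deg^-2.
#' @export
eval_spatial <- function(profile, r) {
  if (!all(is.finite(r))) stop("`r` must be finite")
  if (any(r < 0)) stop("`r` must be non-negative")
  UseMethod("eval_spatial")
}

#' @export
eval_spatial.spatial_gaussian <- function(profile, r) {
  exp(-r^2 / profile$a^2) / (pi * profile$a^2)
}

#' @export
eval_spatial.spatial_dog <- function(profile, r) {
  # DOG = A * gaussian(a) - B * gaussian(b), pointwise
  profile$A * exp(-r^2 / profile$a^2) / (pi * profile$a^2) -
    profile$B * exp(-r^2 / profile$b^2) / (pi * profile$b^2)
}

#' Evaluate a temporal profile in real time
#'
#' Exactly zero before the support starts (t < 0 for the biphasic profile,
#' t < delay for the delayed exponential) and, for the biphasic profile,
#' after `2 * tau_phase`.
#'
#' @param profile a [temporal_biphasic()] or [temporal_exp_delay()] object.
#' @param t time, ms; vectorized.
#' @return Profile amplitude at time `t`, in ms^-1.
#' @export
eval_temporal <- function(profile, t) UseMethod("eval_temporal")

#' @export
eval_temporal.temporal_biphasic <- function(profile, t) {
  tau <- profile$tau_phase
  B <- profile$weight_second
  out <- numeric(length(t))
  first <- t >= 0 & t <= tau
  second <- t > tau & t <= 2 * tau
  out[first] <- sin(pi * t[first] / tau)
  out[second] <- B * sin(pi * t[second] / tau)
  out
}

#' @export
eval_temporal.temporal_exp_delay <- function(profile, t) {
  out <- numeric(length(t))
  on <- t >= profile$delay
  out[on] <- exp(-(t[on] - profile$delay) / profile$tau) / profile$tau
  out
}

#' Closed-form Fourier transforms of profiles
#'
#' The package-wide Fourier convention is
#' \deqn{\tilde W(k, \omega) = \int\!\!\int W(\mathbf r, t)\,
#'   e^{-i(\mathbf k \cdot \mathbf r - \omega t)}\, d^2 r\, dt,}
#' so that a drifting plane wave \eqn{\cos(\mathbf k_g \cdot \mathbf r -
#' \omega_g t)} probes the transfer function exactly at
#' \eqn{(\mathbf k_g, \omega_g)}.  Under this convention the 2-D spatial
#' transform of the unit Gaussian is \eqn{e^{-a^2 k^2/4}} (real, since the
#' profile is even), the DOG transform is
#' \eqn{A e^{-a^2k^2/4} - B e^{-b^2k^2/4}} (equal to `A - B` at `k = 0`), and
#' the delayed exponential transforms to
#' \eqn{e^{i\omega\Delta} / (1 - i\omega\tau)} with
#' \eqn{\tilde h(0) = 1} exactly and \eqn{|\tilde h| \le 1}.
#' The biphasic transform is
#' \deqn{\tilde H(\omega) = \frac{\pi/\tau\,(e^{i\omega\tau} + 1)
#'   (1 - B e^{i\omega\tau})}{(\pi/\tau)^2 - \omega^2},}
#' with the removable singularities at \eqn{\omega = \pm\pi/\tau} evaluated
#' by their analytic limits.  All four forms are verified against dense
#' discrete-Fourier-transform oracles in the test suite.
#'
#' @param profile a spatial or temporal profile object.
#' @param k_mag spatial angular frequency magnitude, rad/deg; vectorized,
#'   non-negative.
#' @param omega temporal angular frequency, rad/ms; vectorized.
#' @return `ft_spatial()`: a real vector (dimensionless); `ft_temporal()`: a
#'   complex vector (dimensionless).
#' @export
ft_spatial <- function(profile, k_mag) {
  if (any(k_mag < 0)) stop("`k_mag` must be non-negative")
  UseMethod("ft_spatial")
}

#' @export
ft_spatial.spatial_gaussian <- function(profile, k_mag) {
  exp(-profile$a^2 * k_mag^2 / 4)
}

#' @export
ft_spatial.spatial_dog <- function(profile, k_mag) {
  profile$A * exp(-profile$a^2 * k_mag^2 / 4) -
    profile$B * exp(-profile$b^2 * k_mag^2 / 4)
}

#' @rdname ft_spatial
#' @export
ft_temporal <- function(profile, omega) UseMethod("ft_temporal")

#' @export
ft_temporal.temporal_biphasic <- function(profile, omega) {
  tau <- profile$tau_phase
  B <- profile$weight_second
  a <- pi / tau
  den <- a^2 - omega^2
  eiwt <- exp(1i * omega * tau)
  out <- a * (eiwt + 1) * (1 - B * eiwt) / den
  # removable singularity at omega = +/- pi/tau: l'Hopital on
  # (e^{i w tau} + 1) / (a^2 - w^2) -> i tau e^{i w tau} / (-2 w)
  bad <- abs(den) < 1e-8 * a^2
  if (any(bad)) {
    wb <- omega[bad]
    out[bad] <- a * (1i * tau * exp(1i * wb * tau)) / (-2 * wb) *
      (1 - B * exp(1i * wb * tau))
  }
  out
}

#' @export
ft_temporal.temporal_exp_delay <- function(profile, omega) {
  exp(1i * omega * profile$delay) / (1 - 1i * omega * profile$tau)
}

#' Weighted separable coupling kernel
#'
#' A space-time separable kernel \eqn{K(\mathbf r, t) = w f(r) h(t)} made of
#' a signed scalar weight, a normalized spatial profile and a normalized
#' temporal profile.  Positive weights encode excitatory connections,
#' negative weights inhibitory ones.
#'
#' @param weight signed coupling strength, dimensionless.
#' @param spatial a `spatial_profile` object.
#' @param temporal a `temporal_profile` object.
#' @return An object of class `coupling_kernel`.
#' @examples
#' k_rg <- coupling_kernel(1, spatial_gaussian(0.1), temporal_exp_delay(0, 5))
#' kernel_ft(k_rg, k_mag = 0, omega = 0)  # weight * 1 * 1
#' @export
coupling_kernel <- function(weight, spatial, temporal) {
  stopifnot(is.numeric(weight), length(weight) == 1L, is.finite(weight),
            inherits(spatial, "spatial_profile"),
            inherits(temporal, "temporal_profile"))
  structure(list(weight = weight, spatial = spatial, temporal = temporal),
            class = "coupling_kernel")
}

#' Fourier transform of a separable kernel
#'
#' @param kernel a [coupling_kernel()].
#' @param k_mag spatial angular frequency magnitude, rad/deg.
#' @param omega temporal angular frequency, rad/ms.
#' @return Complex value \eqn{w \tilde f(k) \tilde h(\omega)}; `k_mag` and
#'   `omega` are recycled against each other.
#' @export
kernel_ft <- function(kernel, k_mag, omega) {
  kernel$weight * ft_spatial(kernel$spatial, k_mag) *
    ft_temporal(kernel$temporal, omega)
}

#' @export
print.spatial_gaussian <- function(x, ...) {
  cat(sprintf("Gaussian spatial profile (a = %g deg)\n", x$a))
  invisible(x)
}

#' @export
print.spatial_dog <- function(x, ...) {
  cat(sprintf("DOG spatial profile (A = %g, a = %g deg, B = %g, b = %g deg)\n",
              x$A, x$a, x$B, x$b))
  invisible(x)
}

#' @export
print.temporal_biphasic <- function(x, ...) {
  cat(sprintf("Biphasic temporal profile (tau = %g ms, second-phase weight = %g)\n",
              x$tau_phase, x$weight_second))
  invisible(x)
}

#' @export
print.temporal_exp_delay <- function(x, ...) {
  cat(sprintf("Delayed exponential temporal profile (delay = %g ms, tau = %g ms)\n",
              x$delay, x$tau))
  invisible(x)
}

#' @export
print.coupling_kernel <- function(x, ...) {
  cat(sprintf("Coupling kernel, weight %+g\n", x$weight))
  cat("  spatial:  "); print(x$spatial)
  cat("  temporal: "); print(x$temporal)
  invisible(x)
}
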