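# Quantitative response measures: receptive-field geometry, area summation,
# suppression index, frequency tuning, temporal IRF shape, autocorrelation,
# natural-image response maps.

# 3-point quadratic refinement of an argmax/argmin; returns fractional
# offset in [-0.5, 0.5] and the interpolated extremum value
quad_refine <- function(y3) {
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (denom == 0) return(list(offset = 0, value = y3[2]))
  off <- 0.5 * (y3[1] - y3[3]) / denom
  list(offset = off, value = y3[2] - 0.25 * (y3[1] - y3[3]) * off)
}

#' Receptive-field characteristics of a spatial field
#'
#' Summarizes a center-surround spatial impulse-response field by three
#' measures: `center_excitation` (the field maximum), `surround_inhibition`
#' (the field minimum), and `rf_size`, the radius of the first sign change
#' of the radial profile taken along the +x axis from the center, linearly
#' interpolated between the two bracketing samples.  When the profile never
#' changes sign inside the domain, `rf_size` is `NA` and `rf_size_defined`
#' is `FALSE`.
#'
#' @param field a `spatial_field` from [spatial_irf()], or a plain matrix
#'   (then `x` must give the axis coordinates).
#' @param x axis coordinates for matrix input, deg.
#' @return List with `rf_size` (deg), `center_excitation`,
#'   `surround_inhibition`, `rf_size_defined`.
#' @export
rf_characteristics <- function(field, x = NULL) {
  if (inherits(field, "spatial_field")) {
    x <- field$x
    vals <- field$values
  } else {
    vals <- field
    stopifnot(is.matrix(vals), !is.null(x), length(x) == nrow(vals))
  }
  n <- nrow(vals)
  ic <- n / 2 + 1
  if (vals[ic, ic] <= 0)
    stop("field has no positive center; receptive-field measures undefined")
  prof <- vals[ic:n, ic]
  r <- x[ic:n] - x[ic]
  s <- sign(prof)
  flip <- which(s[-1] != s[-length(s)] & s[-1] != 0)
  if (length(flip) == 0) {
    rf <- NA_real_; defined <- FALSE
  } else {
    i <- flip[1]
    # linear interpolation of the zero between samples i and i+1
    rf <- r[i] + (r[i + 1] - r[i]) * prof[i] / (prof[i] - prof[i + 1])
    defined <- TRUE
  }
  list(rf_size = rf,
       center_excitation = max(vals),
       surround_inhibition = min(vals),
       rf_size_defined = defined)
}

# scalar center-neuron response to one static spot / patch grating via the
# static path; W2 is the precomputed static transfer field (incl. H~(0))
center_response_static <- function(W2, stimulus, grid) {
  S <- stimulus_ft_spatial(stimulus, grid)
  ic <- grid$nx / 2 + 1
  vals <- take_real(ift_xy(W2 * S, grid), tol = 1e-8)
  vals[ic, ic]
}

#' Area-response (size tuning) curve
#'
#' Response of the center neuron to concentric circular stimuli as a
#' function of diameter.  Static spots and patch gratings use the static
#' analysis path (also for slowly drifting patch gratings, the fast-loop
#' limit, taking the response at cosine phase zero); flashing spots run the
#' full spatiotemporal response and summarize the center trace, by default
#' with its peak absolute value.
#'
#' `R_plateau` is estimated as the mean response over the largest 10% of
#' diameters; a warning fires when the response varies by more than 1%
#' across that window ("plateau not reached").  When the curve maximum
#' itself falls inside the plateau window the curve never descends to a
#' distinct plateau and `R_plateau` is set to `R_max` (suppression index 0).
#'
#' @param circuit an [edog_circuit()].
#' @param diameters strictly increasing spot/patch diameters, deg; at most
#'   `extent / 2`.
#' @param grid an [stgrid()].
#' @param kind stimulus type sweeping the diameter.
#' @param k_mag patch-grating wavenumber magnitude (along x), rad/deg.
#' @param omega_pg patch-grating drift frequency, rad/ms; nonzero values use
#'   the fast-loop (static) limit and are recorded, not simulated.
#' @param contrast stimulus contrast.
#' @param onset,on_duration flashing-spot timing, ms.
#' @param summary scalar summary of the flashing-spot center trace.
#' @return An `area_response_curve`: data frame with columns `diameter` and
#'   `response`, plus attributes `kind`, `R_max`, `R_plateau`.
#' @export
area_response_curve <- function(circuit, diameters, grid,
                                kind = c("spot", "patch_grating", "flashing_spot"),
                                k_mag = 0, omega_pg = 0, contrast = 1,
                                onset = 100, on_duration = 250,
                                summary = c("peak", "mean", "sustained")) {
  kind <- match.arg(kind)
  summary <- match.arg(summary)
  stopifnot(length(diameters) >= 1, all(diff(diameters) > 0), all(diameters > 0))
  if (max(diameters) > grid$extent / 2)
    stop("largest diameter exceeds half the grid extent")
  if (kind %in% c("spot", "patch_grating")) {
    W2 <- static_transfer(circuit, kmag_grid(grid)) * retinal_H0(circuit)
    kx <- if (kind == "spot") 0 else k_mag
    resp <- vapply(diameters, function(d)
      center_response_static(W2, patch_grating(d, kx = kx, contrast = contrast), grid),
      numeric(1))
  } else {
    resp <- vapply(diameters, function(d) {
      fld <- compute_response(circuit,
                              flashing_spot(d, onset, on_duration, contrast), grid)
      tr <- center_trace(fld)
      switch(summary,
             peak = max(abs(tr)),
             mean = mean(tr),
             sustained = tr[max(which(fld$grid$t < onset + on_duration))])
    }, numeric(1))
  }
  finalize_area_curve(diameters, resp, kind = kind, k_mag = k_mag,
                      omega_pg = omega_pg)
}

# attach R_max / R_plateau estimates to a (diameter, response) sweep
finalize_area_curve <- function(diameters, resp, kind = "spot", k_mag = 0,
                                omega_pg = 0) {
  out <- data.frame(diameter = diameters, response = resp)
  n_pl <- max(1L, ceiling(0.1 * length(diameters)))
  pl_win <- resp[seq(length(resp) - n_pl + 1, length(resp))]
  plateau <- mean(pl_win)
  if (diff(range(pl_win)) > 0.01 * max(abs(plateau), .Machine$double.eps))
    warning("plateau not reached: response varies by more than 1% over the largest diameters")
  r_max <- max(resp)
  if (which.max(resp) > length(resp) - n_pl) plateau <- r_max
  structure(out, class = c("area_response_curve", "data.frame"),
            kind = kind, k_mag = k_mag, omega_pg = omega_pg,
            R_max = r_max, R_plateau = plateau)
}

#' Surround-suppression index of an area-response curve
#'
#' \eqn{\alpha_s = (R_{max} - R_{plateau}) / R_{max}}, bounded in
#' \[0, 1\] for curves that rise to a peak and settle to a non-negative
#' plateau; invariant under uniform rescaling of the curve.
#'
#' @param curve an [area_response_curve()], or any object with `R_max` and
#'   `R_plateau` attributes.
#' @return Scalar suppression index.
#' @export
suppression_index <- function(curve) {
  r_max <- attr(curve, "R_max")
  plateau <- attr(curve, "R_plateau")
  if (is.null(r_max) || is.null(plateau))
    stop("`curve` must carry R_max and R_plateau attributes (see area_response_curve)")
  if (r_max <= 0) stop("non-positive maximum response; suppression index undefined")
  (r_max - plateau) / r_max
}

#' Optimal stimulus size of an area-response curve
#'
#' Diameter of the maximum response, refined by 3-point quadratic
#' interpolation around the argmax (ties break toward the smaller
#' diameter); boundary maxima are returned unrefined.
#'
#' @param curve an [area_response_curve()].
#' @return Optimal diameter, deg.
#' @export
optimal_size <- function(curve) {
  d <- curve$diameter
  y <- curve$response
  stopifnot(length(d) >= 1)
  i <- which.max(y)          # which.max returns the first (smallest) tie
  if (i == 1L || i == length(y)) return(d[i])
  qr <- quad_refine(y[(i - 1):(i + 1)])
  d[i] + qr$offset * (d[i + 1] - d[i - 1]) / 2
}

#' Spatial frequency tuning of the center neuron
#'
#' Static-path response magnitude to concentric patch gratings of fixed
#' diameter swept over wavenumber.  Small patches (within the receptive
#' field center) give low-pass profiles; large patches covering the
#' surround give band-pass profiles.
#'
#' @param circuit an [edog_circuit()].
#' @param d_pg patch diameter, deg.
#' @param k_list wavenumbers to probe, rad/deg (within the grid Nyquist).
#' @param grid an [stgrid()].
#' @return Data frame with columns `k_mag` and `response` (magnitude).
#' @export
spatial_frequency_tuning <- function(circuit, d_pg, k_list, grid) {
  stopifnot(all(k_list >= 0))
  if (max(k_list) > nyquist(grid)[["k"]])
    stop("wavenumber beyond the grid Nyquist frequency")
  if (d_pg > grid$extent / 2)
    stop("patch diameter exceeds half the grid extent")
  W2 <- static_transfer(circuit, kmag_grid(grid)) * retinal_H0(circuit)
  resp <- vapply(k_list, function(k)
    abs(center_response_static(W2, patch_grating(d_pg, kx = k), grid)),
    numeric(1))
  data.frame(k_mag = k_list, response = resp)
}

#' Center/surround response reduction
#'
#' Percentage reduction of the center-neuron response when a large patch
#' grating stimulating center plus surround replaces a small patch
#' stimulating the center only:
#' \eqn{100\,(R(d_{center}) - R(d_{full})) / R(d_{center})}, evaluated at a
#' fixed wavenumber via the static path.
#'
#' @param circuit an [edog_circuit()].
#' @param k_mag probe wavenumber, rad/deg.
#' @param d_center,d_full small and large patch diameters, deg (defaults
#'   1.5 and 10, the standard center-only / center-plus-surround pair).
#' @param grid an [stgrid()] whose extent holds the large patch.
#' @return Reduction in percent.
#' @export
response_reduction <- function(circuit, k_mag, d_center = 1.5, d_full = 10, grid) {
  if (d_center > d_full) stop("`d_center` must not exceed `d_full`")
  W2 <- static_transfer(circuit, kmag_grid(grid)) * retinal_H0(circuit)
  r_c <- center_response_static(W2, patch_grating(d_center, kx = k_mag), grid)
  r_f <- center_response_static(W2, patch_grating(d_full, kx = k_mag), grid)
  if (r_c <= 0) stop("center-only response is non-positive; reduction undefined")
  100 * (r_c - r_f) / r_c
}

#' Temporal impulse-response measures
#'
#' Characterizes a temporal impulse-response trace by its peak response
#' latency `t_peak` — the time of the first positive local maximum,
#' quadratically interpolated — and biphasic index `i_bp`, the ratio of the
#' magnitude of the most negative value after the first peak (the rebound;
#' for multiphasic traces the global post-peak minimum, not the first local
#' one) to the first-peak magnitude.  A perfectly biphasic trace has index
#' 1, a monophasic positive trace index 0.
#'
#' @param trace numeric time series, sampled at `dt`, starting at t = 0.
#' @param dt sample interval, ms.
#' @return List with `i_bp`, `t_peak` (ms), `first_peak`, `rebound`.
#' @export
temporal_irf_measures <- function(trace, dt) {
  stopifnot(is.numeric(trace), length(trace) >= 3, dt > 0)
  if (all(trace <= 0)) stop("trace has no positive phase; measures undefined")
  n <- length(trace)
  # first positive local maximum (interior); fall back to the global max
  interior <- 2:(n - 1)
  is_peak <- trace[interior] > 0 &
    trace[interior] >= trace[interior - 1] & trace[interior] > trace[interior + 1]
  ip <- if (any(is_peak)) interior[which(is_peak)[1]] else which.max(trace)
  if (ip > 1L && ip < n) {
    qr <- quad_refine(trace[(ip - 1):(ip + 1)])
    t_peak <- (ip - 1 + qr$offset) * dt
    peak <- qr$value
  } else {
    t_peak <- (ip - 1) * dt
    peak <- trace[ip]
  }
  reb <- 0
  if (ip < n) {
    post <- trace[(ip + 1):n]
    ir <- which.min(post)
    if (post[ir] < 0) {
      j <- ip + ir
      reb <- if (j > 1L && j < n) quad_refine(trace[(j - 1):(j + 1)])$value
             else trace[j]
    }
  }
  list(i_bp = max(0, -reb) / peak, t_peak = t_peak,
       first_peak = peak, rebound = min(reb, 0))
}

#' Temporal frequency tuning of relay cells
#'
#' Response magnitude \eqn{|\tilde W_R(k_g, \omega)|} to full-field drifting
#' gratings at fixed wavenumber over a sweep of drift frequencies.
#'
#' @param circuit an [edog_circuit()].
#' @param k_mag grating wavenumber, rad/deg (the standard probe is about
#'   1 deg^-1).
#' @param omega_list drift angular frequencies, rad/ms.
#' @return Data frame with columns `omega` and `response`.
#' @export
temporal_frequency_tuning <- function(circuit, k_mag, omega_list) {
  resp <- vapply(omega_list, function(w)
    abs(transfer_function(circuit, k_mag, w)), numeric(1))
  data.frame(omega = omega_list, response = resp)
}

#' Temporal autocorrelation across a window of neurons
#'
#' Per-neuron, mean-subtracted, lag-zero-normalized autocorrelation of the
#' response time series, averaged over a centered `window x window` block
#' of neurons; the spread across neurons is reported as a standard
#' deviation.  Zero-variance neurons are excluded with a warning.
#'
#' @param field a 3-D `response_field` (or a [raster_stimulus()], whose
#'   frames are analyzed the same way).
#' @param window side length of the centered neuron block (default 40).
#' @param max_lag largest lag, in samples.
#' @return Data frame with columns `lag` (ms), `acf_mean`, `acf_sd`.
#' @export
temporal_autocorrelation <- function(field, window = 40, max_lag = 50) {
  if (inherits(field, "response_field")) {
    if (field$static) stop("autocorrelation requires a spatiotemporal field")
    vals <- field$values; grid <- field$grid; dt <- grid$dt; nx <- grid$nx
  } else if (inherits(field, "raster_stimulus")) {
    vals <- field$frames; dt <- field$frame_interval; nx <- dim(vals)[1]
  } else stop("`field` must be a response_field or raster_stimulus")
  nt <- dim(vals)[3]
  stopifnot(window >= 1, window <= nx, max_lag < nt)
  i0 <- floor((nx - window) / 2)
  idx <- i0 + seq_len(window)
  block <- vals[idx, idx, , drop = FALSE]
  m <- matrix(block, nrow = window^2, ncol = nt)
  m <- m - rowMeans(m)
  v <- rowSums(m^2)
  keep <- v > 0
  if (!all(keep)) {
    warning(sprintf("%d zero-variance neurons excluded from autocorrelation", sum(!keep)))
    m <- m[keep, , drop = FALSE]; v <- v[keep]
  }
  lags <- 0:max_lag
  acf_mat <- vapply(lags, function(L) {
    if (L == 0) rep(1, nrow(m))
    else rowSums(m[, 1:(nt - L), drop = FALSE] * m[, (L + 1):nt, drop = FALSE]) / v
  }, numeric(nrow(m)))
  data.frame(lag = lags * dt,
             acf_mean = colMeans(acf_mat),
             acf_sd = apply(acf_mat, 2, stats::sd))
}

#' Normalized response map to a static image
#'
#' Static-path response field of the circuit to a grayscale image, divided
#' by the peak absolute response of the same image through the no-feedback
#' variant of the circuit — the normalization that makes feedback-induced
#' enhancement (> 1) and suppression (< 1) directly readable.
#'
#' @param circuit an [edog_circuit()].
#' @param image a static image: `nx x nx` matrix of luminance deviations or
#'   a single-frame [raster_stimulus()].
#' @param grid an [stgrid()].
#' @return A `spatial_field` whose `values` are the normalized map.
#' @export
response_map <- function(circuit, image, grid) {
  base <- compute_response(strip_feedback(circuit), image, grid)
  peak <- max(abs(base$values))
  if (peak == 0) stop("no-feedback response is identically zero; map undefined")
  fld <- compute_response(circuit, image, grid)
  structure(list(values = fld$values / peak, x = grid$x, grid = grid,
                 circuit = circuit),
            class = "spatial_field")
}
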