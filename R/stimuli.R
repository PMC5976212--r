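#' Visual stimuli
#'
#' Constructors for the stimulus types understood by [compute_response()]:
#'
#' * `fullfield_grating()` — drifting full-field grating
#'   \eqn{C \cos(\mathbf k_g \cdot \mathbf r - \omega_g t)}.  For exact
#'   spectral representation the wave vector and frequency must coincide
#'   with DFT grid frequencies; they are snapped with [align_wavevector()]
#'   when the Fourier transform is taken.
#' * `patch_grating()` — circular patch of drifting grating: the same cosine
#'   windowed by a sharp-edged disc of diameter `diameter` (deg).  The
#'   cosine has phase 0 (its maximum) at the patch center and the patch is
#'   centered on the analyzed neuron, the concentric configuration used for
#'   area-summation experiments.  A static spot is the special case
#'   `kx = ky = omega = 0`.
#' * `flashing_spot()` — a spot whose luminance steps to `contrast` at
#'   `onset` (ms) and back to zero after `on_duration` ms.
#' * `raster_stimulus()` — an arbitrary grayscale movie given as a numeric
#'   (x, y, t) array of luminance deviations on the grid raster.
#'
#' A pixel belongs to a disc iff its center lies within the radius
#' (deterministic sharp edge, no anti-aliasing).
#'
#' @param kx,ky wave vector components, rad/deg.
#' @param omega drift angular frequency, rad/ms.
#' @param contrast stimulus contrast (dimensionless); default 1.
#' @param diameter spot/patch diameter, deg.
#' @param onset,on_duration flash onset time and duration, ms.
#' @param frames numeric 3-D array (x, y, t) of luminance deviations.
#' @param pixel_size pixel size of `frames`, deg.
#' @param frame_interval frame interval of `frames`, ms.
#' @return A stimulus object inheriting from `edog_stimulus`.
#' @export
fullfield_grating <- function(kx, ky = 0, omega = 0, contrast = 1) {
  stopifnot(is.finite(kx), is.finite(ky), is.finite(omega), is.finite(contrast))
  structure(list(kx = kx, ky = ky, omega = omega, contrast = contrast),
            class = c("fullfield_grating", "edog_stimulus"))
}

#' @rdname fullfield_grating
#' @export
patch_grating <- function(diameter, kx = 0, ky = 0, omega = 0, contrast = 1) {
  stopifnot(is.finite(diameter), diameter > 0,
            is.finite(kx), is.finite(ky), is.finite(omega), is.finite(contrast))
  structure(list(diameter = diameter, kx = kx, ky = ky, omega = omega,
                 contrast = contrast),
            class = c("patch_grating", "edog_stimulus"))
}

#' @rdname fullfield_grating
#' @export
static_spot <- function(diameter, contrast = 1) {
  patch_grating(diameter, 0, 0, 0, contrast)
}

#' @rdname fullfield_grating
#' @export
flashing_spot <- function(diameter, onset, on_duration, contrast = 1) {
  stopifnot(diameter > 0, onset >= 0, on_duration > 0, is.finite(contrast))
  structure(list(diameter = diameter, onset = onset,
                 on_duration = on_duration, contrast = contrast),
            class = c("flashing_spot", "edog_stimulus"))
}

#' @rdname fullfield_grating
#' @export
raster_stimulus <- function(frames, pixel_size, frame_interval) {
  stopifnot(is.numeric(frames), length(dim(frames)) == 3L,
            pixel_size > 0, frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = c("raster_stimulus", "edog_stimulus"))
}

#' @export
print.edog_stimulus <- function(x, ...) {
  cat("Stimulus:", class(x)[1], "\n")
  str(unclass(x), give.attr = FALSE, max.level = 1)
  invisible(x)
}

#' Snap a wave vector and frequency to the DFT grid
#'
#' Returns the exactly representable grid frequencies nearest to the
#' requested `(kx, ky, omega)`.  Ties break toward the lower magnitude.
#'
#' @param kx,ky requested wave vector components, rad/deg.
#' @param omega requested angular frequency, rad/ms.
#' @param grid an [stgrid()].
#' @return List with `kx, ky, omega` (snapped values) and `rel_error`, the
#'   relative Euclidean snap distance.  Requests beyond the grid Nyquist
#'   frequencies are an error.
#' @export
align_wavevector <- function(kx, ky = 0, omega = 0, grid) {
  ny <- nyquist(grid)
  if (abs(kx) > ny[["k"]] || abs(ky) > ny[["k"]])
    stop("requested wave vector exceeds the spatial Nyquist frequency")
  if (abs(omega) > ny[["omega"]])
    stop("requested frequency exceeds the temporal Nyquist frequency")
  snap1 <- function(v, delta) {
    m <- v / delta
    lo <- floor(m); hi <- ceiling(m)
    # tie (half-integer m) resolves toward the smaller magnitude
    cand <- if (abs(m - lo) < abs(hi - m)) lo
            else if (abs(m - lo) > abs(hi - m)) hi
            else if (abs(lo) <= abs(hi)) lo else hi
    cand * delta
  }
  dk <- 2 * pi / grid$extent
  dw <- 2 * pi / grid$duration
  out <- list(kx = snap1(kx, dk), ky = snap1(ky, dk), omega = snap1(omega, dw))
  req <- c(kx, ky, omega)
  out$rel_error <- sqrt(sum((unlist(out[1:3]) - req)^2)) /
    max(sqrt(sum(req^2)), .Machine$double.eps)
  out
}

## ---- real-space sampling ----------------------------------------------

disc_mask <- function(grid, diameter) {
  r <- sqrt(outer(grid$x^2, grid$x^2, "+"))
  (r <= diameter / 2) * 1
}

#' Sample a stimulus on the real-space grid
#'
#' Returns the (x, y, t) luminance array of a stimulus on the grid raster
#' (centered spatial order).  Gratings are snapped to grid frequencies first.
#'
#' @param stimulus an `edog_stimulus`.
#' @param grid an [stgrid()].
#' @return Numeric array `nx x nx x nt`.
#' @export
stimulus_raster <- function(stimulus, grid) UseMethod("stimulus_raster")

#' @export
stimulus_raster.fullfield_grating <- function(stimulus, grid) {
  al <- align_wavevector(stimulus$kx, stimulus$ky, stimulus$omega, grid)
  phase <- outer(al$kx * grid$x, rep(1, grid$nx)) +
    outer(rep(1, grid$nx), al$ky * grid$x)
  arr <- array(0, c(grid$nx, grid$nx, grid$nt))
  for (j in seq_len(grid$nt))
    arr[, , j] <- stimulus$contrast * cos(phase - al$omega * grid$t[j])
  arr
}

#' @export
stimulus_raster.patch_grating <- function(stimulus, grid) {
  sp <- patch_spatial(stimulus, grid)
  arr <- array(0, c(grid$nx, grid$nx, grid$nt))
  if (stimulus$omega == 0) {
    for (j in seq_len(grid$nt)) arr[, , j] <- sp
  } else {
    mask <- disc_mask(grid, stimulus$diameter)
    phase <- outer(stimulus$kx * grid$x, rep(1, grid$nx)) +
      outer(rep(1, grid$nx), stimulus$ky * grid$x)
    for (j in seq_len(grid$nt))
      arr[, , j] <- stimulus$contrast * cos(phase - stimulus$omega * grid$t[j]) * mask
  }
  arr
}

# spatial (single-frame) section of a patch grating at temporal phase zero
patch_spatial <- function(stimulus, grid) {
  phase <- outer(stimulus$kx * grid$x, rep(1, grid$nx)) +
    outer(rep(1, grid$nx), stimulus$ky * grid$x)
  stimulus$contrast * cos(phase) * disc_mask(grid, stimulus$diameter)
}

#' @export
stimulus_raster.flashing_spot <- function(stimulus, grid) {
  sp <- stimulus$contrast * disc_mask(grid, stimulus$diameter)
  on <- grid$t >= stimulus$onset & grid$t < stimulus$onset + stimulus$on_duration
  arr <- array(0, c(grid$nx, grid$nx, grid$nt))
  for (j in which(on)) arr[, , j] <- sp
  arr
}

#' @export
stimulus_raster.raster_stimulus <- function(stimulus, grid) {
  d <- dim(stimulus$frames)
  if (!identical(d, c(grid$nx, grid$nx, grid$nt)))
    stop(sprintf("raster stimulus shape (%s) does not match the grid (%d x %d x %d)",
                 paste(d, collapse = " x "), grid$nx, grid$nx, grid$nt))
  if (abs(stimulus$pixel_size - grid$dx) > 1e-9 * grid$dx ||
      abs(stimulus$frame_interval - grid$dt) > 1e-9 * grid$dt)
    stop("raster stimulus pixel size / frame interval do not match the grid")
  stimulus$frames
}

## ---- Fourier transforms -----------------------------------------------

#' Fourier transform of a stimulus on a grid
#'
#' Full-field gratings transform analytically to a conjugate pair of
#' Kronecker deltas at the (snapped) \eqn{\pm(\mathbf k_g, \omega_g)} bins;
#' all other stimuli are sampled in real space and transformed numerically.
#' The inverse FFT of the result reproduces the sampled stimulus to machine
#' precision.
#'
#' @param stimulus an `edog_stimulus`.
#' @param grid an [stgrid()].
#' @return Complex `nx x nx x nt` array in DFT frequency order.
#' @export
stimulus_ft <- function(stimulus, grid) UseMethod("stimulus_ft")

#' @export
stimulus_ft.fullfield_grating <- function(stimulus, grid) {
  al <- align_wavevector(stimulus$kx, stimulus$ky, stimulus$omega, grid)
  arr <- array(0i, c(grid$nx, grid$nx, grid$nt))
  amp <- stimulus$contrast / 2 * grid$nx^2 * grid$nt * grid$dx^2 * grid$dt
  # modular bin lookup; +Nyquist and -Nyquist share a bin
  bin <- function(v, delta, n) (round(v / delta) %% n) + 1L
  dk <- 2 * pi / grid$extent
  dw <- 2 * pi / grid$duration
  # DFT bins hold one period each; the +/- pair makes the cosine real
  i1 <- c(bin(al$kx, dk, grid$nx), bin(al$ky, dk, grid$nx),
          bin(al$omega, dw, grid$nt))
  i2 <- c(bin(-al$kx, dk, grid$nx), bin(-al$ky, dk, grid$nx),
          bin(-al$omega, dw, grid$nt))
  arr[i1[1], i1[2], i1[3]] <- arr[i1[1], i1[2], i1[3]] + amp
  arr[i2[1], i2[2], i2[3]] <- arr[i2[1], i2[2], i2[3]] + amp
  arr
}

#' @export
stimulus_ft.edog_stimulus <- function(stimulus, grid) {
  ft_xyt(stimulus_raster(stimulus, grid), grid)
}

# 2-D spatial transform of a static stimulus (static analysis path)
stimulus_ft_spatial <- function(stimulus, grid) {
  if (inherits(stimulus, "patch_grating")) {
    if (stimulus$omega != 0)
      stop("static path requires a non-drifting stimulus")
    return(ft_xy(patch_spatial(stimulus, grid), grid))
  }
  if (inherits(stimulus, "raster_stimulus") && dim(stimulus$frames)[3] == 1L) {
    if (!identical(dim(stimulus$frames)[1:2], c(grid$nx, grid$nx)))
      stop("raster stimulus shape does not match the grid")
    return(ft_xy(stimulus$frames[, , 1], grid))
  }
  if (is.matrix(stimulus)) {
    if (!identical(dim(stimulus), c(grid$nx, grid$nx)))
      stop("image shape does not match the grid")
    return(ft_xy(stimulus, grid))
  }
  stop("no static spatial transform for this stimulus type")
}

is_static_stimulus <- function(stimulus) {
  (inherits(stimulus, "patch_grating") && stimulus$omega == 0) ||
    (inherits(stimulus, "raster_stimulus") && dim(stimulus$frames)[3] == 1L) ||
    is.matrix(stimulus)
}

## ---- synthetic naturalistic movies ------------------------------------

#' Generate a synthetic naturalistic movie
#'
#' Seeded grayscale movie emulating the statistics of natural head-camera
#' footage: spatial power spectrum following a power law
#' \eqn{P(k) \propto |k|^{-\beta}} (natural scenes have \eqn{\beta \approx
#' 2}) and first-order autoregressive (AR(1)) temporal correlation with
#' lag-one coefficient `temporal_correlation` per frame.  Frames have zero
#' mean; the marginal pixel standard deviation is stationary in time.
#'
#' What this generator does not emulate: occlusions, global motion flow,
#' non-Gaussian luminance statistics, or the fixed photographic content of
#' real footage — it captures only second-order spatio-temporal structure.
#'
#' @param grid an [stgrid()]; the movie fills the grid raster.
#' @param seed integer seed; the same seed yields an identical movie.
#' @param spatial_exponent power-law exponent \eqn{\beta \ge 0} of the
#'   spatial power spectrum.
#' @param temporal_correlation AR(1) lag-one coefficient, `|rho| < 1`.
#' @param sd marginal pixel standard deviation.
#' @return A [raster_stimulus()] matching the grid.
#' @export
generate_synthetic_movie <- function(grid, seed, spatial_exponent = 2,
                                     temporal_correlation = 0.9, sd = 1) {
  stopifnot(inherits(grid, "stgrid"), grid$nt >= 2)
  if (!is.finite(spatial_exponent) || spatial_exponent < 0)
    stop("`spatial_exponent` must be a non-negative number")
  if (!is.finite(temporal_correlation) || abs(temporal_correlation) >= 1)
    stop("`temporal_correlation` must satisfy |rho| < 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nx <- grid$nx; nt <- grid$nt
  K <- kmag_grid(grid)
  amp <- K^(-spatial_exponent / 2)  # power ~ |k|^-beta => amplitude ~ |k|^-beta/2
  amp[1, 1] <- 0                    # zero mean
  spatial_innov <- function() {
    z <- stats::fft(matrix(stats::rnorm(nx * nx), nx, nx))
    f <- Re(stats::fft(z * amp, inverse = TRUE)) / (nx * nx)
    f / stats::sd(f)
  }
  rho <- temporal_correlation
  frames <- array(0, c(nx, nx, nt))
  frames[, , 1] <- spatial_innov()
  fac <- sqrt(1 - rho^2)
  for (j in 2:nt)
    frames[, , j] <- rho * frames[, , j - 1] + fac * spatial_innov()
  raster_stimulus(frames * sd, pixel_size = grid$dx, frame_interval = grid$dt)
}
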