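#' Space-time sampling grid
#'
#' Discrete (x, y, t) grid and its conjugate (k_x, k_y, omega) frequencies,
#' owning all FFT conventions of the package.  Spatial axes are centered:
#' `x` runs from `-extent/2` to `extent/2 - dx` and the analyzed ("center")
#' neuron sits at 1-based index `nx/2 + 1` on each axis.  Time runs from 0 to
#' `duration - dt`.  Frequencies are stored in standard DFT order
#' (non-negative first, then negative).
#'
#' The spatial forward transform uses the \eqn{e^{-i k \cdot r}} sign and the
#' temporal forward transform the \eqn{e^{+i\omega t}} sign, matching the
#' closed-form kernel transforms (see [ft_spatial()]).
#'
#' @param nx points per spatial axis; a power of two.
#' @param extent spatial side length, degrees.
#' @param nt temporal points; a power of two.
#' @param duration total simulated time, ms.
#' @return An object of class `stgrid` with fields `nx, extent, nt, duration,
#'   dx, dt, x, t, k, omega`.
#' @examples
#' g <- stgrid(nx = 64, extent = 10, nt = 128, duration = 500)
#' g$dx; g$dt
#' @export
stgrid <- function(nx = 128, extent = 10, nt = 512, duration = 1000) {
  stopifnot(nx >= 2, nt >= 2, extent > 0, duration > 0)
  if (bitwAnd(nx, nx - 1L) != 0L || bitwAnd(nt, nt - 1L) != 0L)
    stop("`nx` and `nt` must be powers of two")
  dx <- extent / nx
  dt <- duration / nt
  structure(list(
    nx = as.integer(nx), extent = extent,
    nt = as.integer(nt), duration = duration,
    dx = dx, dt = dt,
    x = (seq_len(nx) - 1 - nx / 2) * dx,
    t = (seq_len(nt) - 1) * dt,
    k = 2 * pi * c(0:(nx / 2 - 1), -(nx / 2):-1) / extent,
    omega = 2 * pi * c(0:(nt / 2 - 1), -(nt / 2):-1) / duration
  ), class = "stgrid")
}

#' @export
print.stgrid <- function(x, ...) {
  cat(sprintf(
    "Space-time grid: %d x %d pixels over %g deg (dx = %.4g deg), %d steps over %g ms (dt = %.4g ms)\n",
    x$nx, x$nx, x$extent, x$dx, x$nt, x$duration, x$dt))
  cat(sprintf("  Nyquist: |k| = %.4g rad/deg, |omega| = %.4g rad/ms\n",
              pi / x$dx, pi / x$dt))
  invisible(x)
}

#' Nyquist frequencies of a grid
#'
#' @param grid an [stgrid()].
#' @return Named vector with elements `k` (rad/deg) and `omega` (rad/ms).
#' @export
nyquist <- function(grid) {
  c(k = pi / grid$dx, omega = pi / grid$dt)
}

## ---- internal FFT plumbing --------------------------------------------

# |k| on the (kx, ky) DFT-ordered grid
kmag_grid <- function(grid) {
  sqrt(outer(grid$k^2, grid$k^2, "+"))
}

# circular shift moving real-space origin between centered order
# (origin at nx/2 + 1) and DFT order (origin at 1), spatial dims only.
shift_spatial <- function(arr, grid, to = c("dft", "centered")) {
  to <- match.arg(to)
  n <- grid$nx
  idx <- if (to == "dft") c((n / 2 + 1):n, 1:(n / 2)) else c((n / 2 + 1):n, 1:(n / 2))
  # for even n the two shifts coincide
  if (length(dim(arr)) == 3L) arr[idx, idx, , drop = FALSE] else arr[idx, idx, drop = FALSE]
}

# reflect the temporal frequency axis (omega -> -omega), used to realize the
# e^{+i omega t} forward sign with R's single-sign fft()
flip_omega <- function(arr, grid) {
  nt <- grid$nt
  idx <- c(1L, nt:2L)
  if (length(dim(arr)) == 3L) arr[, , idx, drop = FALSE] else arr[idx]
}

# forward transform of a real-space (x, y, t) array in centered spatial
# order: returns S~(k, omega) in DFT order, approximating the continuous FT
ft_xyt <- function(arr, grid) {
  a <- shift_spatial(arr, grid, "dft")
  flip_omega(stats::fft(a), grid) * grid$dx^2 * grid$dt
}

# inverse of ft_xyt: complex (k, omega) array in DFT order -> real-space
# (x, y, t) array in centered spatial order
ift_xyt <- function(arr, grid) {
  a <- stats::fft(flip_omega(arr, grid), inverse = TRUE) /
    (grid$nx^2 * grid$nt * grid$dx^2 * grid$dt)
  shift_spatial(a, grid, "centered")
}

# 2-D (static) versions; no temporal axis, spatial sign convention only
ft_xy <- function(mat, grid) {
  stats::fft(shift_spatial(mat, grid, "dft")) * grid$dx^2
}

ift_xy <- function(mat, grid) {
  shift_spatial(stats::fft(mat, inverse = TRUE) / (grid$nx^2 * grid$dx^2),
                grid, "centered")
}

# enforce the DFT Hermitian symmetry W(-k, -omega) = conj(W(k, omega)) on a
# sampled transfer field: continuous closed forms sampled at the unpaired
# Nyquist bins are not exactly symmetric, which would leak a spurious
# imaginary part into real-space fields
hermitize <- function(arr) {
  d <- dim(arr)
  neg <- lapply(d, function(n) c(1L, n:2L))
  rev_arr <- if (length(d) == 3L) arr[neg[[1]], neg[[2]], neg[[3]], drop = FALSE]
             else arr[neg[[1]], neg[[2]], drop = FALSE]
  (arr + Conj(rev_arr)) / 2
}

# drop numerically negligible imaginary parts, warn if they are not
take_real <- function(arr, tol = 1e-8) {
  mx <- max(abs(Re(arr)), .Machine$double.eps)
  if (max(abs(Im(arr))) > tol * mx)
    warning("imaginary residue exceeds tolerance; result may not be a valid real field")
  Re(arr)
}
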