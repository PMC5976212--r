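# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the package's FFT plumbing: spatial/temporal
# transforms are checked against dense discrete Fourier sums of real-space
# samples, and inverse transforms against direct DFT summation via explicit
# transform matrices.

# dense 2-D DFT oracle for a circularly symmetric spatial profile: returns
# the numeric transform at the grid frequencies closest to each |k|
# requested, together with those frequencies (closed forms must be compared
# at the snapped k)
oracle_ft_spatial <- function(profile, k_req, nx = 256, extent = 16) {
  dx <- extent / nx
  x <- (seq_len(nx) - 1 - nx / 2) * dx
  r <- sqrt(outer(x^2, x^2, "+"))
  f <- eval_spatial(profile, r)
  idx <- c((nx / 2 + 1):nx, 1:(nx / 2))
  F <- Re(stats::fft(f[idx, idx])) * dx^2
  kv <- 2 * pi * c(0:(nx / 2 - 1), -(nx / 2):-1) / extent
  i <- vapply(k_req, function(k) which.min(abs(kv - k)), integer(1))
  list(k = kv[i], value = F[cbind(i, 1L)])  # sampled along the kx axis
}

# dense trapezoid quadrature oracle for a temporal transform at arbitrary
# omega (forward sign e^{+i omega t}, the package convention); integrates
# exactly over the profile support
oracle_ft_temporal <- function(profile, omega, n = 2e5) {
  if (inherits(profile, "temporal_exp_delay")) {
    t0 <- profile$delay; t1 <- profile$delay + 45 * profile$tau
  } else {
    t0 <- 0; t1 <- 2 * profile$tau_phase
  }
  tt <- seq(t0, t1, length.out = n + 1)
  dt <- tt[2] - tt[1]
  h <- eval_temporal(profile, tt)
  w_trap <- c(0.5, rep(1, n - 1), 0.5)
  vapply(omega, function(w) sum(w_trap * h * exp(1i * w * tt)) * dt, complex(1))
}

# direct (non-FFT) inverse transform of a (k, omega) array via explicit DFT
# matrices, mixed-sign convention: e^{+i k r}, e^{-i omega t}
oracle_ift_xyt <- function(W, grid) {
  nx <- grid$nx; nt <- grid$nt
  Ex <- exp(2i * pi * outer(0:(nx - 1), 0:(nx - 1)) / nx)   # spatial, + sign
  Et <- exp(-2i * pi * outer(0:(nt - 1), 0:(nt - 1)) / nt)  # temporal, - sign
  out <- array(0i, dim(W))
  for (l in seq_len(nt)) {                                  # spatial axes
    out[, , l] <- Ex %*% W[, , l] %*% t(Ex)
  }
  m <- matrix(out, nx * nx, nt) %*% t(Et)                   # temporal axis
  out <- array(m, c(nx, nx, nt))
  out <- out / (nx^2 * nt * grid$dx^2 * grid$dt)
  idx <- c((nx / 2 + 1):nx, 1:(nx / 2))
  out[idx, idx, , drop = FALSE]
}

oracle_ift_xy <- function(W, grid) {
  nx <- grid$nx
  Ex <- exp(2i * pi * outer(0:(nx - 1), 0:(nx - 1)) / nx)
  out <- (Ex %*% W %*% t(Ex)) / (nx^2 * grid$dx^2)
  idx <- c((nx / 2 + 1):nx, 1:(nx / 2))
  out[idx, idx]
}

# direct circular space-time convolution of kernel field W (centered spatial
# order, t from 0) with stimulus S, times the grid measure: the real-space
# definition of the response
oracle_convolve <- function(W, S, grid) {
  nx <- grid$nx; nt <- grid$nt
  # recenter W so its spatial origin is at index 1 for wrap arithmetic
  idx <- c((nx / 2 + 1):nx, 1:(nx / 2))
  W0 <- W[idx, idx, , drop = FALSE]
  out <- array(0, c(nx, nx, nt))
  for (i in 1:nx) for (j in 1:nx) for (l in 1:nt) {
    wi <- ((i - 1) - (0:(nx - 1))) %% nx + 1
    wj <- ((j - 1) - (0:(nx - 1))) %% nx + 1
    wl <- ((l - 1) - (0:(nt - 1))) %% nt + 1
    out[i, j, l] <- sum(W0[wi, wj, wl] * S) * grid$dx^2 * grid$dt
  }
  # indexing by displacement keeps the output in the same (centered spatial)
  # order as the stimulus
  out
}

table1_circuit <- function(feedback = "none", ...) {
  edog_circuit_table1(feedback, ...)
}

ffonly_circuit <- function() {
  edog_circuit_table1("none", ff_inhibition = FALSE)
}

small_grid <- function(nx = 16, extent = 8, nt = 32, duration = 400) {
  stgrid(nx, extent, nt, duration)
}

# grid used for static-path (area summation / tuning) analyses in tests:
# coarse enough to be fast, fine enough for the widest stimuli
static_grid <- function(nx = 256, extent = 20) {
  stgrid(nx, extent, nt = 4, duration = 8)
}
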