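test_that("transfer function reduces to the pure feedforward product", {
  circ <- ffonly_circuit()
  k <- c(0, 0.5, 1.3, 4)
  w <- c(0, 0.1, -0.2, 0.8)
  got <- transfer_function(circ, k, w)
  expected <- kernel_ft(circ$ff_excitation, k, w) *
    ft_spatial(circ$retinal$spatial, k) * ft_temporal(circ$retinal$temporal, w)
  expect_equal(got, expected, tolerance = 1e-14)
  # zero-weight feedback terms are bit-for-bit equivalent to no feedback
  circ0 <- circ
  circ0$feedback <- list(coupling_kernel(0, spatial_gaussian(0.83),
                                         temporal_exp_delay(5, 5)))
  expect_identical(transfer_function(circ0, k, w), got)
})

test_that("the full transfer function matches term-by-term assembly", {
  circ <- table1_circuit("mixed")
  k <- c(1, 0, 0.7, 2.5)
  w <- c(0, 0.2, -0.4, 0.05)
  # independent re-assembly from the raw closed forms
  g <- function(k, a) exp(-a^2 * k^2 / 4)
  h <- function(w, d, tau) exp(1i * w * d) / (1 - 1i * w * tau)
  num <- 1 * g(k, 0.1) * h(w, 0, 5) + (-0.5) * g(k, 0.3) * h(w, 3, 5)
  den <- 1 - 0.3 * g(k, 0.1) * h(w, 5, 5) - (-0.6) * g(k, 0.9) * h(w, 30, 5)
  FH <- (g(k, 0.62) - 0.85 * g(k, 1.26)) *
    ft_temporal(temporal_biphasic(42.5, 0.38), w)
  expect_equal(transfer_function(circ, k, w), num / den * FH, tolerance = 1e-14)
})

test_that("static transfer is the omega = 0 reduction up to the retinal constant", {
  for (fb in c("none", "excitatory", "inhibitory", "mixed")) {
    circ <- table1_circuit(fb)
    k <- seq(0, 4, by = 0.25)
    expect_equal(static_transfer(circ, k) * retinal_H0(circ),
                 Re(transfer_function(circ, k, 0)), tolerance = 1e-12)
  }
  # zero-frequency value of the bare feedforward circuit: DOG integral A - B
  expect_equal(static_transfer(ffonly_circuit(), 0), 0.15)
})

test_that("impulse-response fields match the direct DFT-summation oracle", {
  g <- small_grid()
  circ <- table1_circuit("mixed")
  # spatial (static) field
  W2 <- static_transfer(circ, edogsim:::kmag_grid(g))
  fld <- suppressWarnings(spatial_irf(circ, g))
  direct <- oracle_ift_xy(W2, g)
  expect_lt(max(abs(Im(direct))), 1e-10)
  expect_equal(fld$values, Re(direct), tolerance = 1e-8)
  # spatiotemporal field
  K <- edogsim:::kmag_grid(g)
  W3 <- array(0i, c(g$nx, g$nx, g$nt))
  for (j in seq_len(g$nt)) W3[, , j] <- transfer_function(circ, K, g$omega[j])
  fld3 <- suppressWarnings(spatiotemporal_irf(circ, g))
  direct3 <- oracle_ift_xyt(W3, g)
  expect_equal(fld3$values, Re(direct3), tolerance = 1e-8)
})

test_that("spatial impulse response keeps center-surround structure", {
  g <- stgrid(128, 10, 4, 8)
  none <- spatial_irf(table1_circuit("none"), g)
  ic <- g$nx / 2 + 1
  prof <- none$values[ic:g$nx, ic]
  expect_gt(prof[1], 0)                       # positive center
  expect_lt(min(prof), 0)                     # negative surround ring
  expect_lt(max(abs(prof[(length(prof) - 5):length(prof)])), 1e-4 * prof[1])
  # circular symmetry: x-profile equals y-profile
  expect_equal(none$values[, ic], none$values[ic, ],
               tolerance = 1e-10)
  # excitatory feedback raises the center peak
  exc <- spatial_irf(table1_circuit("excitatory"), g)
  expect_gt(max(exc$values), max(none$values))
})

test_that("spatiotemporal impulse response is causal and biphasic", {
  g <- stgrid(32, 8, 512, 1000)
  fld <- suppressWarnings(spatiotemporal_irf(ffonly_circuit(), g))
  tr <- center_trace(fld)
  ip <- which.max(tr)
  expect_gt(tr[ip], 0)
  expect_lt(min(tr[(ip + 1):length(tr)]), 0)  # negative rebound after the peak
  # the first-phase-peak time slice has the bright-excitatory-center
  # sign structure of the static field
  ic <- g$nx / 2 + 1
  sl <- fld$values[, , ip]
  expect_gt(sl[ic, ic], 0)
  expect_lt(min(sl[ic:g$nx, ic]), 0)
  # causality: the field has decayed at the end of the window (wrapped t < 0)
  expect_lt(max(abs(fld$values[, , g$nt])), 1e-3 * max(fld$values))
})

test_that("stability check scans the loop-gain denominator", {
  g <- small_grid()
  expect_identical(stability_check(table1_circuit("none"), g)$min_denominator, 1)
  res <- stability_check(table1_circuit("mixed"), stgrid(64, 10, 64, 500))
  expect_gt(res$min_denominator, 0.05)
  # contrived marginal circuit: unit-gain instantaneous feedback loop
  bad <- table1_circuit("none")
  bad$feedback <- list(coupling_kernel(1, spatial_gaussian(0.05),
                                       temporal_exp_delay(0, 5)))
  res_bad <- stability_check(bad, g)
  expect_lt(res_bad$min_denominator, 1e-6)
  expect_equal(res_bad$k, 0)
  expect_equal(res_bad$omega, 0)
  expect_error(transfer_function(bad, 0, 0), "unstable")
})

test_that("circuit constructors enforce kernel roles", {
  ret <- coupling_kernel(1, spatial_dog(1, 0.62, 0.85, 1.26),
                         temporal_biphasic(42.5, 0.38))
  ffe <- coupling_kernel(1, spatial_gaussian(0.1), temporal_exp_delay(0, 5))
  expect_error(edog_circuit(ret, coupling_kernel(-1, spatial_gaussian(0.1),
                                                 temporal_exp_delay(0, 5))),
               "positive")
  expect_error(edog_circuit(ret, ffe,
                            coupling_kernel(0.5, spatial_gaussian(0.3),
                                            temporal_exp_delay(3, 5))),
               "negative")
  expect_error(edog_circuit(ffe, ffe), "DOG")
  # weight-zero feedback factor collapses to the no-feedback configuration
  expect_identical(edog_circuit_table1("mixed", feedback_factor = 0)$feedback,
                   list())
})
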