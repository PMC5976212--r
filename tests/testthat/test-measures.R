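test_that("receptive-field size is the first radial zero crossing", {
  # pure DOG field: the zero crossing has a closed form checked by a 1-D
  # root-finding oracle
  dog <- spatial_dog(1, 0.62, 0.85, 1.26)
  nx <- 256; extent <- 8
  x <- (seq_len(nx) - 1 - nx / 2) * extent / nx
  fld <- eval_spatial(dog, sqrt(outer(x^2, x^2, "+")))
  root <- stats::uniroot(function(r) eval_spatial(dog, r), c(0.3, 3),
                         tol = 1e-12)$root
  rc <- rf_characteristics(fld, x)
  expect_true(rc$rf_size_defined)
  expect_lt(abs(rc$rf_size - root), 1e-3)
  expect_equal(rc$center_excitation, eval_spatial(dog, 0), tolerance = 1e-12)
  expect_lt(rc$surround_inhibition, 0)
  # an all-positive Gaussian has no zero crossing
  gauss <- eval_spatial(spatial_gaussian(1), sqrt(outer(x^2, x^2, "+")))
  expect_false(rf_characteristics(gauss, x)$rf_size_defined)
  expect_error(rf_characteristics(-gauss, x), "positive center")
})

test_that("feedback shifts center excitation in opposite directions", {
  g <- stgrid(128, 10, 4, 8)
  ce <- function(fb) rf_characteristics(spatial_irf(table1_circuit(fb), g))$center_excitation
  base <- ce("none")
  expect_gt(ce("excitatory"), base)
  expect_lt(ce("inhibitory"), base)
})

test_that("area-response curves rise, peak and settle to a plateau", {
  g <- static_grid()
  circ <- table1_circuit("none")
  d <- seq(0.2, 10, by = 0.2)
  curve <- area_response_curve(circ, d, g, kind = "spot")
  i_max <- which.max(curve$response)
  expect_gt(i_max, 1)                          # rises to an interior peak
  expect_lt(i_max, length(d) / 2)
  expect_true(all(diff(curve$response[1:i_max]) > 0))
  expect_lt(curve$response[length(d)], curve$response[i_max])  # declines
  expect_lt(curve$response[1], 0.1 * curve$response[i_max])    # d -> 0
  # largest diameters agree with the uniform full-field value within 2%
  ff <- static_transfer(circ, 0) * retinal_H0(circ)
  expect_lt(abs(curve$response[length(d)] - ff) / ff, 0.02)
  expect_error(area_response_curve(circ, c(1, 11), g), "extent")
})

test_that("suppression index is the normalized drop from peak to plateau", {
  mk <- function(resp) edogsim:::finalize_area_curve(seq_along(resp), resp)
  expect_equal(suppression_index(
    structure(list(), R_max = 10, R_plateau = 4)), 0.6)
  # monotonically increasing curve: the plateau is the maximum
  expect_equal(suppression_index(mk(1 - exp(-(1:50) / 10))), 0)
  # bounded and invariant under uniform rescaling
  set.seed(2)
  for (i in 1:20) {
    resp <- abs(stats::rnorm(30)) + 0.1
    resp <- stats::filter(resp, rep(1 / 5, 5), circular = TRUE)
    a1 <- suppression_index(suppressWarnings(mk(as.numeric(resp))))
    a2 <- suppression_index(suppressWarnings(mk(as.numeric(resp) * 7.3)))
    expect_equal(a1, a2, tolerance = 1e-12)
    expect_lte(a1, 1)
  }
  expect_error(suppression_index(structure(list(), R_max = -1, R_plateau = 0)),
               "non-positive")
})

test_that("optimal size interpolates the argmax and tracks feedback sign", {
  # analytic parabola: vertex recovered within one diameter step
  d <- seq(0.5, 6, by = 0.5)
  vertex <- 2.62
  curve <- suppressWarnings(edogsim:::finalize_area_curve(d, 10 - (d - vertex)^2))
  expect_lt(abs(optimal_size(curve) - vertex), 0.5)
  # tie breaks toward the smaller diameter: argmax is the first tied point,
  # and the parabola through (1, 2, 2) peaks midway between the tied pair
  flat <- suppressWarnings(edogsim:::finalize_area_curve(1:5, c(1, 2, 2, 2, 1)))
  expect_equal(optimal_size(flat), 2.5)
  g <- static_grid()
  dd <- seq(0.2, 10, by = 0.2)
  opt <- function(fb, f) optimal_size(suppressWarnings(
    area_response_curve(table1_circuit(fb, feedback_factor = f), dd, g)))
  base <- opt("none", 1)
  expect_lt(opt("inhibitory", 1.5), base)   # inhibition shrinks the optimum
  expect_gt(opt("excitatory", 1.5), base)   # excitation grows it
})

test_that("patch size switches spatial tuning between low-pass and band-pass", {
  g <- static_grid()
  ks <- seq(0, 3, by = 0.15)
  for (fb in c("none", "mixed")) {
    circ <- table1_circuit(fb)
    small <- spatial_frequency_tuning(circ, 1.5, ks, g)
    expect_equal(which.max(small$response), 1L)           # low-pass
    expect_true(all(diff(small$response) < 0))
    large <- spatial_frequency_tuning(circ, 10, ks, g)
    i <- which.max(large$response)
    expect_gt(i, 1L)                                      # band-pass
    expect_lt(i, length(ks))
    expect_lt(large$response[1], 0.6 * large$response[i])
  }
})

test_that("surround stimulation cuts the low-frequency response", {
  g <- static_grid()
  expect_equal(response_reduction(table1_circuit("mixed"), 0.25,
                                  d_center = 2, d_full = 2, grid = g), 0)
  r_mixed <- response_reduction(table1_circuit("mixed"), 0.25, grid = g)
  r_none <- response_reduction(table1_circuit("none"), 0.25, grid = g)
  expect_gt(r_mixed, r_none)     # feedback deepens the suppression
  expect_error(response_reduction(table1_circuit("none"), 0.25,
                                  d_center = 3, d_full = 2, grid = g),
               "exceed")
})

test_that("temporal impulse measures recover constructed trace shapes", {
  # the biphasic retinal time course itself: index = second-phase weight,
  # latency = half the phase duration
  dt <- 0.05
  tt <- seq(0, 120, by = dt)
  tm <- temporal_irf_measures(eval_temporal(temporal_biphasic(42.5, 0.38), tt), dt)
  expect_equal(tm$i_bp, 0.38, tolerance = 1e-4)
  expect_equal(tm$t_peak, 21.25, tolerance = 1e-3)
  # monophasic positive bump
  bump <- exp(-(tt - 30)^2 / 50)
  expect_equal(temporal_irf_measures(bump, dt)$i_bp, 0)
  expect_error(temporal_irf_measures(-bump, dt), "positive")
  # two-lobe traces with random amplitudes recover the constructed ratio
  set.seed(9)
  half <- sin(pi * seq(0, 1, length.out = 201))
  for (i in 1:100) {
    a <- stats::runif(2, 0.2, 3)
    trace <- c(a[1] * half, -a[2] * half[-1])
    tm <- temporal_irf_measures(trace, dt)
    expect_equal(tm$i_bp, a[2] / a[1], tolerance = 1e-4)
  }
})

test_that("temporal tuning reflects feedback delay structure", {
  circ <- table1_circuit("none")
  ws <- seq(0, 0.8, by = 0.01)
  tf <- temporal_frequency_tuning(circ, 1, ws)
  expect_equal(tf$response[1],
               abs(static_transfer(circ, 1) * retinal_H0(circ)),
               tolerance = 1e-12)
  # long-delay inhibition + short-delay excitation sharpens the resonance
  delayed_inh <- temporal_frequency_tuning(
    table1_circuit("mixed", delta_ex = 5, delta_in = 30), 1, ws)
  expect_gt(max(delayed_inh$response) / mean(delayed_inh$response),
            max(tf$response) / mean(tf$response))
  # synchronized feedback barely moves the curve, unlike delayed inhibition
  sync <- temporal_frequency_tuning(
    table1_circuit("mixed", delta_ex = 15, delta_in = 15), 1, ws)
  dev <- function(x) max(abs(x$response - tf$response)) / max(tf$response)
  expect_lt(dev(sync), 0.25 * dev(delayed_inh))
})

test_that("autocorrelation is unit at lag zero and flat for white noise", {
  g <- stgrid(16, 8, 512, 1024)
  set.seed(21)
  white <- raster_stimulus(array(stats::rnorm(16 * 16 * 512), c(16, 16, 512)),
                           g$dx, g$dt)
  ac <- temporal_autocorrelation(white, window = 8, max_lag = 10)
  expect_equal(ac$acf_mean[1], 1)
  expect_equal(ac$acf_sd[1], 0)
  expect_lt(max(abs(ac$acf_mean[-1])), 0.02)
  # zero-variance neurons are excluded with a warning
  frames <- white$frames; frames[8, 8, ] <- 0
  expect_warning(temporal_autocorrelation(
    raster_stimulus(frames, g$dx, g$dt), window = 8, max_lag = 2),
    "zero-variance")
})

test_that("response maps normalize by the no-feedback peak", {
  g <- stgrid(64, 10, 4, 8)
  set.seed(4)
  img <- matrix(stats::rnorm(64 * 64), 64, 64)
  circ0 <- table1_circuit("none")
  mp0 <- suppressWarnings(response_map(circ0, img, g))
  expect_equal(max(abs(mp0$values)), 1)
  # uniform image: spatially constant response
  mp_u <- suppressWarnings(response_map(table1_circuit("mixed"),
                                        matrix(1, 64, 64), g))
  expect_lt(diff(range(mp_u$values)), 1e-8 * max(abs(mp_u$values)))
  # a luminance edge: mixed feedback enhances the edge response and
  # suppresses the flat regions relative to no feedback
  gf <- stgrid(128, 10, 4, 8)
  edge <- matrix(rep(c(-0.5, 0.5), each = 64), 128, 128, byrow = TRUE)
  m_mix <- response_map(table1_circuit("mixed", feedback_factor = 1.8), edge, gf)
  m_non <- response_map(table1_circuit("none"), edge, gf)
  band <- 60:70; flat <- c(20:40, 90:110)  # columns: across / away from the edge
  expect_gt(max(abs(m_mix$values[, band])), max(abs(m_non$values[, band])))
  expect_lt(max(abs(m_mix$values[, flat])), max(abs(m_non$values[, flat])))
})
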