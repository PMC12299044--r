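test_that("pulse-echo traces are linear with summed start times", {
  g <- time_grid(16e6, 0, 64)
  pT <- us_waveform(sin(2 * pi * 3e6 * grid_times(g)) * exp(-(1:64) / 20), 16e6, 2e-6)
  pR <- us_waveform(cos(2 * pi * 3e6 * grid_times(g)) * exp(-(1:64) / 10), 16e6, 3e-6)
  tr0 <- pulse_echo_trace(pT, pR, 0, tissue)
  expect_true(all(tr0$samples == 0))
  tr1 <- pulse_echo_trace(pT, pR, 1, tissue)
  tr2 <- pulse_echo_trace(pT, pR, 2, tissue)
  expect_equal(tr2$samples, 2 * tr1$samples)
  expect_equal(tr1$t0, 5e-6)
  expect_length(tr1$samples, 2 * 64 - 1)
  bad <- us_waveform(pR$samples, 20e6, 0)
  expect_error(pulse_echo_trace(pT, bad, 1, tissue), "mismatched")
})

test_that("the compiled kernel matches the R waveform path", {
  a <- imaging_array(4)
  sc <- us_scatterers(rbind(c(2e-3, 1e-3, 30e-3), c(-1e-3, 0, 33e-3)),
                      c(1.5, -0.7))
  q <- element_quadrature(a, 6, 2)
  tau <- as.numeric(plane_wave_delays(a, 6, tissue))
  rx <- 1:4
  ref <- echosim:::rf_event_r(a, sc, rx, tau, rep(1, 4), rx, rep(0, 4),
                              pulse3, pulse3, tissue, 16e6, q, "analytic")
  g <- time_grid(16e6, ref$t0, nrow(ref$data))
  raw <- echosim:::rf_event_raw(a, sc, rx, tau, rep(1, 4), rx, rep(0, 4),
                                pulse3, pulse3, tissue, g, q)
  got <- echosim:::time_derivative(raw, 16e6)
  expect_lt(max(abs(got - ref$data)) / max(abs(ref$data)), 1e-10)
})

test_that("monostatic echoes arrive at the two-way time of flight", {
  a <- linear_array(1, 0.3e-3, 0.3e-3, 0)
  z <- 30e-3
  rf <- simulate_synthetic_aperture(a, point_target(z), pulse3, tissue, 100e6)
  tpk <- envelope_peak_time(rf$events[[1]]$data[, 1], rf$fs, rf$t0)
  # the received pulse v = w1 * w2 spans two single-cycle durations, so the
  # envelope peaks within half that of the two-way flight time
  expect_lt(abs(tpk - 2 * z / 1540), pulse3$duration + 2 / rf$fs)

  # moving the scatterer by dz shifts the echo by 2 dz / c
  dz <- 1.5e-3
  rf2 <- simulate_synthetic_aperture(a, point_target(z + dz), pulse3, tissue,
                                     100e6, grid = time_grid(1e8, rf$t0, 700))
  tpk2 <- envelope_peak_time(rf2$events[[1]]$data[, 1], rf2$fs, rf2$t0)
  expect_equal(tpk2 - tpk, 2 * dz / 1540, tolerance = 0.02)
})

test_that("single-pair traces are reciprocal and scatterers superpose", {
  a <- imaging_array(4)
  sc <- point_target(28e-3, x = 1.2e-3)
  q <- element_quadrature(a, 6, 1)
  g <- echosim:::auto_rf_grid(a, sc$pos, 0, pulse3, pulse3, tissue, 16e6)
  tr_ij <- echosim:::rf_event_raw(a, sc, 1, 0, 1, 4, 0, pulse3, pulse3,
                                  tissue, g, q)
  tr_ji <- echosim:::rf_event_raw(a, sc, 4, 0, 1, 1, 0, pulse3, pulse3,
                                  tissue, g, q)
  expect_lt(max(abs(tr_ij - tr_ji)) / max(abs(tr_ij)), 1e-12)

  s1 <- point_target(30e-3, x = -2e-3, amp = 1.3)
  s2 <- point_target(34e-3, x = 2e-3, amp = -0.4)
  both <- us_scatterers(rbind(s1$pos, s2$pos), c(s1$amp, s2$amp))
  g2 <- echosim:::auto_rf_grid(a, both$pos, 0, pulse3, pulse3, tissue, 16e6)
  t1 <- echosim:::rf_event_raw(a, s1, 1, 0, 1, 1:4, rep(0, 4), pulse3, pulse3, tissue, g2, q)
  t2 <- echosim:::rf_event_raw(a, s2, 1, 0, 1, 1:4, rep(0, 4), pulse3, pulse3, tissue, g2, q)
  tb <- echosim:::rf_event_raw(a, both, 1, 0, 1, 1:4, rep(0, 4), pulse3, pulse3, tissue, g2, q)
  expect_equal(tb, t1 + t2, tolerance = 1e-12)
})

test_that("far-field two-way amplitude falls as one over r squared", {
  a <- linear_array(1, 0.3e-3, 0.3e-3, 0)
  peak_at <- function(z) {
    rf <- simulate_synthetic_aperture(a, point_target(z), pulse3, tissue, 100e6)
    max(Mod(analytic_signal(rf$events[[1]]$data[, 1])))
  }
  r1 <- 60e-3
  ratio <- peak_at(r1) / peak_at(2 * r1)
  expect_equal(ratio, 4, tolerance = 0.05)
})

test_that("a one-element plane wave reduces to its synthetic aperture event", {
  a <- linear_array(1, 0.3e-3, 7e-3, 0.05e-3)
  sc <- point_target(25e-3)
  g <- echosim:::auto_rf_grid(a, sc$pos, 0, pulse3, pulse3, tissue, 16e6)
  sa <- simulate_synthetic_aperture(a, sc, pulse3, tissue, 16e6, grid = g)
  pw <- simulate_plane_wave(a, sc, pulse3, tissue, 16e6, 0, grid = g)
  expect_equal(pw$events[[1]]$data, sa$events[[1]]$data, tolerance = 1e-12)
})

test_that("zero-degree plane wave echoes are laterally symmetric", {
  a <- imaging_array(8)
  rf <- simulate_plane_wave(a, point_target(30e-3), pulse3, tissue, 64e6, 0)
  tp <- vapply(1:8, function(j)
    envelope_peak_time(rf$events[[1]]$data[, j], rf$fs, rf$t0), 0)
  expect_equal(tp, rev(tp), tolerance = 1e-8)
  # outer channels never arrive earlier (ties allowed: sub-sample geometry)
  expect_true(all(diff(tp[1:4]) <= 1e-9))
})

test_that("B-mode transmit focusing peaks on the centered A-line", {
  a <- imaging_array(16)
  sc <- point_target(30e-3)
  alx <- aline_positions(a)
  alx <- alx[seq(1, length(alx), by = 4)]
  rf <- simulate_bmode(a, sc, pulse3, tissue, 16e6, n_sub = 8,
                       focus_depth = 30e-3, aline_x = alx)
  amp <- vapply(rf$events, function(ev) max(abs(ev$data)), 0)
  expect_equal(alx[which.max(amp)], alx[which.min(abs(alx))])
  # Hanning apodization: ends ~0, center 1 for odd counts
  h <- as.numeric(signal::hanning(9))
  expect_equal(h[c(1, 9)], c(0, 0))
  expect_equal(h[5], 1)
  expect_error(simulate_bmode(a, sc, pulse3, tissue, 16e6, n_sub = 17),
               "exceeds")
})

test_that("simulators reject empty scatterer fields", {
  a <- imaging_array(2)
  empty <- structure(list(pos = matrix(0, 0, 3), amp = numeric(0)),
                     class = "us_scatterers")
  expect_error(simulate_plane_wave(a, empty, pulse3, tissue, 16e6, 0), "empty")
  expect_error(simulate_synthetic_aperture(a, empty, pulse3, tissue, 16e6), "empty")
})

test_that("a one-element B-mode sub-aperture degenerates to its element pair", {
  a <- imaging_array(8)
  sc <- point_target(30e-3, x = a$x[4])
  g <- echosim:::auto_rf_grid(a, sc$pos, 0, pulse3, pulse3, tissue, 16e6)
  bm <- simulate_bmode(a, sc, pulse3, tissue, 16e6, n_sub = 1,
                       focus_depth = 30e-3, aline_x = a$x[4], grid = g)
  sa <- simulate_synthetic_aperture(a, sc, pulse3, tissue, 16e6,
                                    tx_elements = 4, grid = g)
  # the focused single-element delay is a pure time reference shift of zero
  # for an element on its own A-line
  expect_equal(bm$events[[1]]$data, sa$events[[1]]$data, tolerance = 1e-10)
})
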