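#' Point-scatterer field
#'
#' Container for point scatterers: positions and (dimensionless) amplitudes.
#'
#' @param positions N x 3 matrix of positions (m).
#' @param amplitudes numeric vector of scatterer amplitudes.
#' @param seed optional seed recorded for provenance.
#' @return an object of class \code{us_scatterers}.
#' @export
us_scatterers <- function(positions, amplitudes, seed = NULL) {
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 3)
  if (ncol(positions) != 3) stopf("positions must be N x 3")
  if (nrow(positions) != length(amplitudes))
    stopf("positions and amplitudes disagree in length")
  if (any(!is.finite(amplitudes))) stopf("amplitudes must be finite")
  structure(list(pos = positions, amp = as.numeric(amplitudes), seed = seed),
            class = "us_scatterers")
}

#' @export
print.us_scatterers <- function(x, ...) {
  cat(sprintf("Scatterer field: %d scatterers, z in [%.1f, %.1f] mm, amplitude sd %.3g\n",
              nrow(x$pos), 1e3 * min(x$pos[, 3]), 1e3 * max(x$pos[, 3]),
              sd(x$amp)))
  invisible(x)
}

#' Single pulse-echo trace
#'
#' Received trace for one transmit/receive intermediate pair and one
#' scatterer: the time derivative of the (full linear, continuous-time
#' approximated) convolution of the transmit and receive intermediate
#' pressures, scaled by \code{a_s / (2 rho0 c^2)}. The result's start time
#' is the sum of the input start times.
#'
#' @param pT,pR transmit/receive intermediate waveforms
#'   (\code{us_waveform}) on grids with the same sampling frequency.
#' @param amplitude scatterer amplitude \code{a_s}.
#' @param medium a \code{us_medium}.
#' @return a \code{us_waveform} of length \code{length(pT) + length(pR) - 1}.
#' @export
pulse_echo_trace <- function(pT, pR, amplitude, medium) {
  if (pT$fs != pR$fs) stopf("mismatched sampling frequencies")
  y <- convolve(pT$samples, rev(pR$samples), type = "open") / pT$fs
  y <- y * amplitude / (2 * medium$rho * medium$c^2)
  us_waveform(time_derivative(y, pT$fs), pT$fs, pT$t0 + pR$t0)
}

# Shared RF time grid sized from the scatterer cloud: two-way propagation
# span plus pulse durations, delays, the element half-diagonal, and a 10%
# margin.  t0 is an exact multiple of 1/fs so cached and analytic paths stay
# sample-aligned.
auto_rf_grid <- function(array, positions, tau_all, pulse_tx, pulse_rx,
                         medium, fs) {
  dmin <- Inf; dmax <- -Inf
  for (i in seq_len(array$n)) {
    d <- sqrt((positions[, 1] - array$x[i])^2 + positions[, 2]^2 + positions[, 3]^2)
    dmin <- min(dmin, min(d)); dmax <- max(dmax, max(d))
  }
  hd <- sqrt((array$width / 2)^2 + (array$height / 2)^2)
  dmin <- max(dmin - hd, 1e-6); dmax <- dmax + hd
  tlo <- 2 * dmin / medium$c + min(0, tau_all)
  thi <- 2 * dmax / medium$c + max(0, tau_all) + pulse_tx$duration + pulse_rx$duration
  span <- thi - tlo
  k0 <- floor(tlo * fs) - 8L
  n <- ceiling(span * fs * 1.1) + 16L
  time_grid(fs, k0 / fs, n)
}

# Synthesize one transmit event with the compiled kernel.  Returns the
# pre-derivative nt x n_rx trace matrix; callers sum contributions
# (e.g. moving + static scatterers) before differentiating.
rf_event_raw <- function(array, scat, tx_elements, tau_tx, apod_tx,
                         rx_elements, tau_rx, pulse_tx, pulse_rx, medium,
                         grid, quad) {
  k0 <- round(grid$t0 * grid$fs)
  rf_event_cpp(scat$pos, scat$amp,
               element_centers(array, tx_elements), tau_tx, apod_tx,
               element_centers(array, rx_elements), tau_rx,
               quad_matrix(quad),
               pulse_tx$f0, pulse_tx$duration,
               pulse_rx$f0, pulse_rx$duration,
               grid$fs, as.integer(k0), grid$n,
               medium$c, medium$rho)
}

new_us_rf <- function(mode, events, grid, array, medium, pulse_tx, pulse_rx) {
  structure(list(mode = mode, events = events, fs = grid$fs, t0 = grid$t0,
                 array = array, medium = medium,
                 pulse_tx = pulse_tx, pulse_rx = pulse_rx),
            class = "us_rf")
}

#' @export
print.us_rf <- function(x, ...) {
  cat(sprintf("RF data set (%s): %d events, %d channels x %d samples, fs %.3g MHz, t0 %.2f us\n",
              x$mode, length(x$events), ncol(x$events[[1]]$data),
              nrow(x$events[[1]]$data), x$fs / 1e6, x$t0 * 1e6))
  invisible(x)
}

#' Synthetic aperture RF simulation
#'
#' One transmit event per element: each element is excited individually and
#' the backscattered echoes are recorded on all elements, giving the full
#' set of transmit/receive element pairs.
#'
#' @param array a \code{us_array}.
#' @param scatterers a \code{us_scatterers}.
#' @param pulse transmit excitation (\code{us_pulse}); also used on receive
#'   unless \code{pulse_rx} is given.
#' @param medium a \code{us_medium}.
#' @param fs RF sampling frequency (Hz).
#' @param pulse_rx receive-side excitation (defaults to \code{pulse}).
#' @param tx_elements transmit element indices (default: all).
#' @param quad element-face quadrature.
#' @param grid optional \code{us_grid}; auto-sized when NULL.
#' @return an object of class \code{us_rf} whose events carry an
#'   \code{nt x M} trace matrix each.
#' @export
simulate_synthetic_aperture <- function(array, scatterers, pulse, medium, fs,
                                        pulse_rx = pulse,
                                        tx_elements = seq_len(array$n),
                                        quad = element_quadrature(array),
                                        grid = NULL) {
  if (nrow(scatterers$pos) < 1) stopf("empty scatterer field")
  if (is.null(grid))
    grid <- auto_rf_grid(array, scatterers$pos, 0, pulse, pulse_rx, medium, fs)
  rx <- seq_len(array$n)
  events <- lapply(tx_elements, function(i) {
    raw <- rf_event_raw(array, scatterers, i, 0, 1, rx, rep(0, array$n),
                        pulse, pulse_rx, medium, grid, quad)
    list(data = time_derivative(raw, fs), label = sprintf("tx%03d", i),
         tx_element = i, tau_tx = 0, apod = 1)
  })
  new_us_rf("sa", events, grid, array, medium, pulse, pulse_rx)
}

#' Plane wave RF simulation
#'
#' One transmit event per steering angle: all elements fire with linear
#' plane-wave delays and the transmit intermediates are summed before
#' convolution; echoes are recorded element-wise on all receivers.
#'
#' @inheritParams simulate_synthetic_aperture
#' @param angles_deg steering angles in degrees.
#' @param apod transmit apodization (length M, in [0, 1]; default uniform).
#' @return a \code{us_rf}; each event records its angle.
#' @examples
#' seq(-6, 6, length.out = 5)   # the five-angle set used throughout
#' @export
simulate_plane_wave <- function(array, scatterers, pulse, medium, fs,
                                angles_deg, pulse_rx = pulse,
                                apod = rep(1, array$n),
                                quad = element_quadrature(array),
                                grid = NULL) {
  if (length(angles_deg) < 1) stopf("at least one steering angle is required")
  if (nrow(scatterers$pos) < 1) stopf("empty scatterer field")
  taus <- lapply(angles_deg, function(a) plane_wave_delays(array, a, medium))
  if (is.null(grid))
    grid <- auto_rf_grid(array, scatterers$pos, unlist(taus), pulse, pulse_rx,
                         medium, fs)
  rx <- seq_len(array$n)
  events <- mapply(function(angle, tau) {
    raw <- rf_event_raw(array, scatterers, rx, tau, apod, rx, rep(0, array$n),
                        pulse, pulse_rx, medium, grid, quad)
    list(data = time_derivative(raw, fs), label = sprintf("pw%+.1fdeg", angle),
         angle = angle, tau_tx = tau, apod = apod,
         offset = attr(tau, "offset"))
  }, angles_deg, taus, SIMPLIFY = FALSE)
  new_us_rf("pw", events, grid, array, medium, pulse, pulse_rx)
}

#' Focused B-mode RF simulation
#'
#' One transmit event per A-line: a sub-aperture of \code{n_sub} elements,
#' apodized with a Hanning window and focused at \code{focus_depth} on the
#' line, walks across the array. The sub-aperture is centered at the nearest
#' achievable element block and clamped at the array edges. All M receive
#' channels are recorded for every event (receive focusing is a beamforming
#' concern).
#'
#' @inheritParams simulate_synthetic_aperture
#' @param n_sub sub-aperture size in elements (<= M).
#' @param focus_depth transmit focal depth (m).
#' @param aline_x A-line lateral positions (default
#'   \code{\link{aline_positions}}).
#' @return a \code{us_rf}; each event records its A-line position and
#'   active elements.
#' @export
simulate_bmode <- function(array, scatterers, pulse, medium, fs,
                           n_sub = min(64L, array$n), focus_depth = 60e-3,
                           aline_x = NULL, pulse_rx = pulse,
                           quad = element_quadrature(array), grid = NULL) {
  if (n_sub > array$n) stopf("sub-aperture size exceeds the array")
  if (nrow(scatterers$pos) < 1) stopf("empty scatterer field")
  if (is.null(aline_x)) aline_x <- aline_positions(array)
  apod <- as.numeric(signal::hanning(n_sub))
  events_spec <- lapply(aline_x, function(x0) {
    s <- round((x0 - array$x[1]) / array$pitch - (n_sub - 1) / 2) + 1
    s <- min(max(s, 1), array$n - n_sub + 1)           # clamp at edges
    idx <- s:(s + n_sub - 1)
    tau <- focus_delays(element_centers(array, idx), c(x0, 0, focus_depth),
                        medium)
    list(x0 = x0, idx = idx, tau = tau)
  })
  if (is.null(grid))
    grid <- auto_rf_grid(array, scatterers$pos,
                         unlist(lapply(events_spec, `[[`, "tau")),
                         pulse, pulse_rx, medium, fs)
  rx <- seq_len(array$n)
  events <- lapply(events_spec, function(ev) {
    raw <- rf_event_raw(array, scatterers, ev$idx, ev$tau, apod, rx,
                        rep(0, array$n), pulse, pulse_rx, medium, grid, quad)
    list(data = time_derivative(raw, fs),
         label = sprintf("aline x=%+.2fmm", ev$x0 * 1e3),
         aline_x = ev$x0, tx_elements = ev$idx, tau_tx = ev$tau, apod = apod,
         focus_depth = focus_depth)
  })
  new_us_rf("bmode", events, grid, array, medium, pulse, pulse_rx)
}

# Reference R implementation of one transmit event through the waveform
# path: intermediates on a one-way time grid, per-event delays applied by
# the requested delay-handling mode, transmit intermediates summed before
# convolution (full linear convolution, step 1/fs), then the outer time
# derivative.  Used by the convergence harness and as the oracle for the
# compiled kernel.  Returns list(data = nt x n_rx, fs, t0).
rf_event_r <- function(array, scat, tx_elements, tau_tx, apod_tx,
                       rx_elements, tau_rx, pulse_tx, pulse_rx, medium, fs,
                       quad, mode = c("analytic", "cached_linear",
                                      "cached_upsampled")) {
  mode <- match.arg(mode)
  pos <- scat$pos
  els <- union(tx_elements, rx_elements)
  dmin <- Inf; dmax <- -Inf
  for (i in els) {
    d <- sqrt((pos[, 1] - array$x[i])^2 + pos[, 2]^2 + pos[, 3]^2)
    dmin <- min(dmin, min(d)); dmax <- max(dmax, max(d))
  }
  hd <- sqrt((array$width / 2)^2 + (array$height / 2)^2)
  taus <- c(tau_tx, tau_rx, 0)
  tlo <- max(dmin - hd, 1e-6) / medium$c + min(taus)
  thi <- (dmax + hd) / medium$c + max(taus) +
    max(pulse_tx$duration, pulse_rx$duration)
  k0 <- floor(tlo * fs) - 4
  ni <- ceiling((thi - tlo) * fs) + 12
  gi <- time_grid(fs, k0 / fs, ni)
  upsample <- if (mode == "cached_upsampled") 4 else 1

  get_tx <- get_rx <- NULL
  if (mode == "analytic") {
    get_tx <- function(i, n, dly)
      transient_pressure(array, i, pos[n, ], pulse_tx, medium, gi, quad, dly)
    get_rx <- function(j, n, dly)
      transient_pressure(array, j, pos[n, ], pulse_rx, medium, gi, quad, dly)
  } else {
    ctx <- intermediate_cache(array, pos, pulse_tx, medium, gi, quad,
                              upsample, elements = tx_elements)
    crx <- intermediate_cache(array, pos, pulse_rx, medium, gi, quad,
                              upsample, elements = rx_elements)
    get_tx <- function(i, n, dly) cache_waveform(ctx, i, n, dly, mode)
    get_rx <- function(j, n, dly) cache_waveform(crx, j, n, dly, mode)
  }

  nt <- 2L * ni - 1L
  acc <- matrix(0, nt, length(rx_elements))
  scale <- 1 / (2 * medium$rho * medium$c^2) / fs
  for (n in seq_len(nrow(pos))) {
    if (scat$amp[n] == 0) next
    tsum <- numeric(ni)
    for (k in seq_along(tx_elements)) {
      if (apod_tx[k] == 0) next
      tsum <- tsum + apod_tx[k] * get_tx(tx_elements[k], n, tau_tx[k])$samples
    }
    for (k in seq_along(rx_elements)) {
      pr <- get_rx(rx_elements[k], n, tau_rx[k])$samples
      acc[, k] <- acc[, k] +
        (scale * scat$amp[n]) * convolve(tsum, rev(pr), type = "open")
    }
  }
  list(data = time_derivative(acc, fs), fs = fs, t0 = 2 * k0 / fs)
}
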