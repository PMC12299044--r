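#' Acoustic medium
#'
#' Homogeneous, isotropic, non-dissipative propagation medium.
#'
#' @param c sound speed in m/s.
#' @param rho density in kg/m^3.
#' @return an object of class \code{us_medium}.
#' @examples
#' us_medium()          # soft tissue: 1540 m/s, 1000 kg/m^3
#' @export
us_medium <- function(c = 1540, rho = 1000) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0) stopf("sound speed must be a positive scalar")
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0) stopf("density must be a positive scalar")
  structure(list(c = c, rho = rho), class = "us_medium")
}

#' Excitation pulse
#'
#' A sinusoidal burst used as the time-varying normal velocity of the
#' transducer face: \code{sin(2 pi f0 t)} on \code{[0, n_cycles/f0)} and zero
#' elsewhere. The pulse is stored analytically and can be evaluated (and
#' differentiated) at arbitrary continuous times, so time delays can be
#' applied without interpolation error.
#'
#' @param f0 center frequency in Hz.
#' @param n_cycles number of cycles (real, > 0); duration is
#'   \code{n_cycles/f0}.
#' @return an object of class \code{us_pulse} with fields \code{f0},
#'   \code{n_cycles}, \code{duration}.
#' @examples
#' p <- us_pulse(3e6, 1)
#' pulse_eval(p, 1 / (4 * 3e6))   # quarter period: sin peak = 1
#' @export
us_pulse <- function(f0, n_cycles = 1) {
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0) stopf("f0 must be a positive scalar")
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles <= 0)
    stopf("n_cycles must be a positive scalar")
  structure(list(f0 = f0, n_cycles = n_cycles, duration = n_cycles / f0),
            class = "us_pulse")
}

#' @rdname us_pulse
#' @param pulse a \code{us_pulse}.
#' @param t times in seconds (vector OK).
#' @export
pulse_eval <- function(pulse, t) {
  ifelse(t >= 0 & t < pulse$duration, sin(2 * pi * pulse$f0 * t), 0)
}

#' @rdname us_pulse
#' @export
pulse_rate <- function(pulse, t) {
  w <- 2 * pi * pulse$f0
  ifelse(t >= 0 & t < pulse$duration, w * cos(w * t), 0)
}

#' Linear array of rectangular elements
#'
#' Builds a 1-D linear array of identical rectangular piston elements in the
#' plane z = 0, centered at the origin, with the element normals along +z.
#' Element centers are at \code{x_i = (i - (M-1)/2) * pitch}, i = 0..M-1,
#' with \code{pitch = width + kerf}.
#'
#' @param n_elements number of elements (>= 1).
#' @param width element width (lateral x) in m.
#' @param height element height (elevation y) in m.
#' @param kerf gap between elements in m (>= 0).
#' @return an object of class \code{us_array} with fields \code{n},
#'   \code{width}, \code{height}, \code{kerf}, \code{pitch} and element
#'   center abscissas \code{x}.
#' @examples
#' a <- linear_array(128, 0.3e-3, 7e-3, 0.05e-3)
#' a$pitch                  # 0.35 mm
#' a$x[1]                   # -22.225 mm
#' @export
linear_array <- function(n_elements, width, height, kerf) {
  if (!is.numeric(n_elements) || length(n_elements) != 1 || n_elements < 1 ||
      n_elements != round(n_elements))
    stopf("invalid geometry: n_elements must be a positive integer")
  if (width <= 0 || height <= 0) stopf("invalid geometry: element width and height must be positive")
  if (kerf < 0) stopf("invalid geometry: kerf must be non-negative")
  m <- as.integer(n_elements)
  pitch <- width + kerf
  x <- (seq_len(m) - 1 - (m - 1) / 2) * pitch
  structure(list(n = m, width = width, height = height, kerf = kerf,
                 pitch = pitch, x = x), class = "us_array")
}

#' @export
print.us_array <- function(x, ...) {
  cat(sprintf("Linear array: %d elements, width %.3g mm, height %.3g mm, kerf %.3g mm (pitch %.3g mm)\n",
              x$n, x$width * 1e3, x$height * 1e3, x$kerf * 1e3, x$pitch * 1e3))
  cat(sprintf("  aperture: %.3g mm, centered at x = 0, normal +z\n",
              1e3 * ((x$n - 1) * x$pitch + x$width)))
  invisible(x)
}

# Element centers as an M x 3 matrix (y = z = 0).
element_centers <- function(array, idx = seq_len(array$n)) {
  cbind(array$x[idx], 0, 0)
}

#' A-line lateral positions
#'
#' Lateral scan-line positions at both the element centers and the midpoints
#' between adjacent elements: \code{2M - 1} sorted positions spaced at half
#' the pitch. With a single element the element center is returned.
#'
#' @param array a \code{us_array}.
#' @return numeric vector of lateral positions in m.
#' @export
aline_positions <- function(array) {
  if (array$n < 2) return(array$x)
  mids <- (array$x[-1] + array$x[-array$n]) / 2
  sort(c(array$x, mids))
}

#' Plane wave transmit delays
#'
#' Per-element firing delays steering an unfocused plane wave:
#' \code{tau_i = x_i sin(angle) / c}. Negative delays are allowed (the RF
#' start time accounts for them); with \code{offset = "nonneg"} the delays
#' are shifted so the earliest is zero and the shift is recorded in the
#' \code{"offset"} attribute, so downstream bookkeeping stays consistent.
#'
#' @param array a \code{us_array}.
#' @param angle_deg steering angle in degrees, |angle| < 90.
#' @param medium a \code{us_medium}.
#' @param offset \code{"none"} (default) or \code{"nonneg"}.
#' @return numeric delay vector (s) with attribute \code{"offset"} (s), the
#'   amount added to the raw delays.
#' @export
plane_wave_delays <- function(array, angle_deg, medium, offset = c("none", "nonneg")) {
  offset <- match.arg(offset)
  if (abs(angle_deg) >= 90) stopf("steering angle must satisfy |angle| < 90 degrees")
  tau <- array$x * sin(angle_deg * pi / 180) / medium$c
  off <- 0
  if (offset == "nonneg") {
    off <- -min(tau)
    tau <- tau + off
  }
  attr(tau, "offset") <- off
  tau
}

#' Focusing transmit delays
#'
#' Delays focusing a (sub-)aperture at a point:
#' \code{tau_i = (|r_f - r_ref| - |r_f - r_i|) / c}, where \code{r_ref} is
#' the aperture reference (default: the mean element position). Elements
#' farther from the focus fire earlier (more negative delay).
#'
#' @param positions element positions: numeric vector of lateral x (m), or an
#'   M x 3 matrix of coordinates.
#' @param focal_point length-3 focal point (m).
#' @param medium a \code{us_medium}.
#' @param reference optional length-3 reference position (default: column
#'   means of \code{positions}).
#' @return numeric delay vector (s).
#' @export
focus_delays <- function(positions, focal_point, medium, reference = NULL) {
  if (!is.matrix(positions)) positions <- cbind(positions, 0, 0)
  if (length(focal_point) != 3) stopf("focal_point must have length 3")
  if (is.null(reference)) reference <- colMeans(positions)
  d <- sqrt(colSums((t(positions) - focal_point)^2))
  if (any(d == 0)) stopf("focal point coincides with an element position")
  dref <- sqrt(sum((reference - focal_point)^2))
  if (dref == 0) stopf("focal point coincides with the aperture reference")
  (dref - d) / medium$c
}

#' Uniform time grid
#'
#' @param fs sampling frequency in Hz.
#' @param t0 start time in s (may be negative).
#' @param n number of samples.
#' @return an object of class \code{us_grid}.
#' @export
time_grid <- function(fs, t0 = 0, n) {
  if (fs <= 0) stopf("fs must be positive")
  if (n < 1) stopf("n must be >= 1")
  structure(list(fs = fs, t0 = t0, n = as.integer(n)), class = "us_grid")
}

#' @rdname time_grid
#' @param grid a \code{us_grid}.
#' @export
grid_times <- function(grid) grid$t0 + (seq_len(grid$n) - 1) / grid$fs
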