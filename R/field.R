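#' Quadrature rule on an element face
#'
#' Sample points and area weights discretizing the rectangular element face
#' for Rayleigh-integral evaluation. \code{rule = "gauss"} gives a
#' tensor-product Gauss-Legendre rule of order \code{nx} x \code{ny}
#' (lateral x elevation); \code{rule = "uniform"} gives a uniform
#' sub-element (midpoint) grid, either of order \code{nx} x \code{ny} or,
#' when \code{spacing} is given, spaced no coarser than \code{spacing} in
#' each direction (the dense discretization used as a brute-force reference).
#' Weights are positive and always sum to the element area.
#'
#' @param array a \code{us_array} (provides element width and height).
#' @param nx,ny number of nodes laterally / in elevation (>= 1).
#' @param rule \code{"gauss"} or \code{"uniform"}.
#' @param spacing optional node spacing in m for \code{rule = "uniform"};
#'   overrides \code{nx}, \code{ny}.
#' @return an object of class \code{us_quadrature}: list with node offsets
#'   \code{x}, \code{y} (m, relative to the element center) and weights
#'   \code{w} (m^2).
#' @examples
#' q <- element_quadrature(linear_array(1, 1, 1, 0), 2, 2)
#' q$x                       # +/- 1/(2*sqrt(3))
#' sum(q$w)                  # element area
#' @export
element_quadrature <- function(array, nx = 6, ny = 1,
                               rule = c("gauss", "uniform"), spacing = NULL) {
  rule <- match.arg(rule)
  w <- array$width; h <- array$height
  if (!is.null(spacing)) {
    if (spacing <= 0) stopf("spacing must be positive")
    rule <- "uniform"
    nx <- max(1L, ceiling(w / spacing))
    ny <- max(1L, ceiling(h / spacing))
  }
  if (nx < 1 || ny < 1) stopf("quadrature orders must be >= 1")
  if (rule == "gauss") {
    gx <- if (nx == 1) list(x = 0, w = w) else pracma::gaussLegendre(nx, -w / 2, w / 2)
    gy <- if (ny == 1) list(x = 0, w = h) else pracma::gaussLegendre(ny, -h / 2, h / 2)
  } else {
    gx <- list(x = ((seq_len(nx) - 0.5) / nx - 0.5) * w, w = rep(w / nx, nx))
    gy <- list(x = ((seq_len(ny) - 0.5) / ny - 0.5) * h, w = rep(h / ny, ny))
  }
  nodes <- expand.grid(x = gx$x, y = gy$x)
  wt <- as.vector(outer(gx$w, gy$w))
  structure(list(x = nodes$x, y = nodes$y, w = wt), class = "us_quadrature")
}

# Quadrature as a Q x 3 matrix (dx, dy, weight) for the C++ kernel.
quad_matrix <- function(quad) cbind(quad$x, quad$y, quad$w)

#' Waveform on a time grid
#'
#' @param samples numeric samples.
#' @param fs sampling frequency (Hz).
#' @param t0 time of the first sample (s).
#' @return an object of class \code{us_waveform}.
#' @export
us_waveform <- function(samples, fs, t0 = 0) {
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "us_waveform")
}

#' @rdname us_waveform
#' @param wf a \code{us_waveform}.
#' @export
wf_times <- function(wf) wf$t0 + (seq_along(wf$samples) - 1) / wf$fs

#' Transient pressure at a field point
#'
#' Evaluates the transmitted pressure waveform of one array element at a
#' point, as Rayleigh-integral quadrature with analytic time evaluation:
#' \deqn{p(r, t) = \frac{\rho_0}{2\pi} \sum_q w_q\,
#'   \frac{\dot{w}(t - d_q/c - \tau)}{d_q},}
#' where \eqn{d_q} is the distance from quadrature node \eqn{q} to the
#' point, \eqn{\dot w} the analytic time derivative of the excitation
#' normal velocity, and \eqn{\tau} an optional firing delay. The waveform is
#' causal: it is zero before \code{min(d_q)/c + delay}.
#'
#' @param array a \code{us_array}.
#' @param element element index (1-based).
#' @param point length-3 field point (m).
#' @param pulse a \code{us_pulse} (normal velocity).
#' @param medium a \code{us_medium}.
#' @param grid a \code{us_grid} on which to sample the waveform.
#' @param quad a \code{us_quadrature} (default 6 x 1 Gauss-Legendre).
#' @param delay firing delay in s applied inside the analytic evaluation.
#' @return a \code{us_waveform} (Pa) on \code{grid}.
#' @export
transient_pressure <- function(array, element, point, pulse, medium, grid,
                               quad = element_quadrature(array), delay = 0) {
  ec <- element_centers(array, element)
  dx <- point[1] - (ec[1] + quad$x)
  dy <- point[2] - (ec[2] + quad$y)
  dz <- point[3] - ec[3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(d == 0)) stopf("singular geometry: field point lies on the element face")
  t <- grid_times(grid)
  p <- numeric(grid$n)
  for (q in seq_along(d)) {
    p <- p + (quad$w[q] / d[q]) * pulse_rate(pulse, t - d[q] / medium$c - delay)
  }
  wf <- us_waveform(p * medium$rho / (2 * pi), grid$fs, grid$t0)
  attr(wf, "regen") <- function(dly) {
    transient_pressure(array, element, point, pulse, medium, grid, quad, dly)
  }
  wf
}

#' Time-shifted copy of a waveform
#'
#' Applies a time delay to a waveform, emulating the delay-handling
#' strategies of the RF synthesis pipeline:
#' \describe{
#'   \item{\code{analytic}}{re-evaluates the generating field expression at
#'     the shifted times (exact; requires the waveform to carry its
#'     generator, as waveforms from \code{\link{transient_pressure}} and the
#'     intermediate cache do);}
#'   \item{\code{cached_linear}}{discrete-time shifting with linear
#'     interpolation on the base sample grid;}
#'   \item{\code{cached_upsampled}}{linear-interpolation shifting on a 4x
#'     oversampled copy of the waveform, decimated back to the base grid
#'     (every 4th sample, aligned) with no anti-alias filter.}
#' }
#' Samples shifted beyond the grid are zero; the output stays on the input
#' grid.
#'
#' @param wf a \code{us_waveform}.
#' @param delay delay in seconds (positive delays move the waveform later).
#' @param mode delay-handling mode; see Details.
#' @return a \code{us_waveform} on the same grid.
#' @export
delayed_copy <- function(wf, delay,
                         mode = c("cached_linear", "cached_upsampled", "analytic")) {
  mode <- match.arg(mode)
  if (delay == 0 && mode != "cached_upsampled") return(wf)
  t <- wf_times(wf)
  if (mode == "analytic") {
    regen <- attr(wf, "regen")
    if (is.null(regen)) stopf("analytic mode needs a waveform that carries its generator")
    base <- attr(wf, "base_delay")
    if (is.null(base)) base <- 0
    return(regen(base + delay))
  }
  if (mode == "cached_linear") {
    s <- approx(t + delay, wf$samples, xout = t, yleft = 0, yright = 0)$y
    return(us_waveform(s, wf$fs, wf$t0))
  }
  up <- attr(wf, "up")
  if (is.null(up)) stopf("cached_upsampled mode needs a waveform carrying a 4x upsampled bank")
  t4 <- up$t0 + (seq_along(up$samples) - 1) / up$fs
  s <- approx(t4 + delay, up$samples, xout = t, yleft = 0, yright = 0)$y
  us_waveform(s, wf$fs, wf$t0)
}

#' Intermediate-field cache
#'
#' Precomputes the undelayed transmit/receive intermediate pressure
#' waveforms for every (element, scatterer) pair once, so that per-event
#' delayed copies can be produced by discrete-time shifting instead of
#' re-evaluating the field. With \code{upsample = 4} each waveform is also
#' computed at four times the base sampling frequency; shifted copies are
#' then interpolated on the oversampled grid and decimated back.
#'
#' @param array a \code{us_array}.
#' @param points N x 3 matrix of scatterer positions (m).
#' @param pulse a \code{us_pulse}.
#' @param medium a \code{us_medium}.
#' @param grid a \code{us_grid} (base sampling).
#' @param quad a \code{us_quadrature}.
#' @param upsample 1 or 4.
#' @param elements element indices to include (default all).
#' @return an object of class \code{us_cache}; retrieve waveforms with
#'   \code{cache_waveform}.
#' @export
intermediate_cache <- function(array, points, pulse, medium, grid,
                               quad = element_quadrature(array), upsample = 1,
                               elements = seq_len(array$n)) {
  if (!upsample %in% c(1, 4)) stopf("upsample must be 1 or 4")
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  grid4 <- if (upsample == 4)
    time_grid(4 * grid$fs, grid$t0, 4L * grid$n) else NULL
  bank <- lapply(elements, function(i) {
    lapply(seq_len(nrow(points)), function(n) {
      wf <- transient_pressure(array, i, points[n, ], pulse, medium, grid, quad)
      if (upsample == 4) {
        wf4 <- transient_pressure(array, i, points[n, ], pulse, medium, grid4, quad)
        attr(wf, "up") <- list(samples = wf4$samples, fs = grid4$fs, t0 = grid4$t0)
      }
      wf
    })
  })
  structure(list(bank = bank, elements = elements, grid = grid,
                 upsample = upsample), class = "us_cache")
}

#' @rdname intermediate_cache
#' @param cache a \code{us_cache}.
#' @param element element index (as passed in \code{elements}).
#' @param scatterer scatterer row index.
#' @param delay delay in s.
#' @param mode delay-handling mode (see \code{\link{delayed_copy}});
#'   defaults to linear shifting, or upsampled shifting if the cache was
#'   built with \code{upsample = 4}.
#' @export
cache_waveform <- function(cache, element, scatterer, delay = 0, mode = NULL) {
  if (is.null(mode))
    mode <- if (cache$upsample == 4) "cached_upsampled" else "cached_linear"
  i <- match(element, cache$elements)
  if (is.na(i)) stopf("element %d not present in cache", element)
  delayed_copy(cache$bank[[i]][[scatterer]], delay, mode)
}
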