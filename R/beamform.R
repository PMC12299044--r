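#' Beamforming grid
#'
#' Lateral/axial focal positions and the constant f-number controlling how
#' the receive aperture grows with depth: at depth z, channels within
#' \code{z / (2 f_number)} of the pixel's lateral position contribute.
#'
#' @param x lateral focal positions (m).
#' @param z axial focal depths (m), strictly increasing and positive.
#' @param f_number receive f-number (> 0).
#' @return an object of class \code{us_bfgrid}.
#' @export
beamform_grid <- function(x, z, f_number = 2) {
  if (any(z <= 0) || any(diff(z) <= 0)) stopf("z must be positive and strictly increasing")
  if (f_number <= 0) stopf("f-number must be positive")
  structure(list(x = x, z = z, f_number = f_number), class = "us_bfgrid")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$z, b$z))
}

#' Delay-and-sum beamforming
#'
#' Beamforms each transmit event of an RF data set onto a (z, x) pixel grid.
#' Pixel (x, z) sums, over the receive channels admitted by the constant
#' f-number, the channel traces sampled (linear interpolation) at
#' \code{t_tx(x, z) + |r_pixel - r_j| / c}. The transmit time is
#' mode-specific: the element-to-pixel flight time for synthetic aperture,
#' \code{(z cos(theta) + x sin(theta)) / c} plus the event's recorded delay
#' offset for a plane wave at angle theta, and \code{z / c} under the
#' focused transmit of a B-mode A-line. With \code{analytic = TRUE}
#' (default) the channel data is converted to its analytic signal first, so
#' frames are complex and carry phase (required for Doppler; the envelope is
#' then their modulus).
#'
#' Receive focusing is dynamic (per-depth) by default; for B-mode,
#' \code{fixed_foci} freezes the receive delay law at a set of focal depths,
#' each applied within its axial segment, the segments concatenating
#' seamlessly.
#'
#' @param rf a \code{us_rf}.
#' @param grid a \code{us_bfgrid}. For B-mode data the lateral positions
#'   must match the simulated A-lines (each event beamforms its own line).
#' @param analytic logical; beamform analytic (complex) channel data.
#' @param fixed_foci optional vector of receive focal depths (m) for B-mode
#'   fixed-focus receive; NULL (default) uses dynamic receive.
#' @param symmetric logical; when TRUE the receive aperture is additionally
#'   truncated so it stays symmetric about the pixel when the f-number cone
#'   runs off the array edge (instead of keeping the one-sided remainder).
#'   An asymmetric receive aperture tilts the effective receive direction
#'   and biases Doppler phase off-axis, so the color-flow chain uses
#'   symmetric apertures; for B-mode amplitude imaging the one-sided
#'   default keeps more aperture.
#' @return a list of \code{us_frame} objects (one per event): matrices of
#'   dimension \code{length(z) x length(x)} with attributes \code{grid} and
#'   \code{label}. Pixels with an empty receive aperture are zero and
#'   counted in attribute \code{n_empty}.
#' @export
das_beamform <- function(rf, grid, analytic = TRUE, fixed_foci = NULL,
                         symmetric = FALSE) {
  med <- rf$medium
  lapply(rf$events, function(ev)
    das_one(ev, rf, grid, med, analytic, fixed_foci, symmetric))
}

das_one <- function(ev, rf, grid, med, analytic, fixed_foci,
                    symmetric = FALSE) {
  x <- grid$x; z <- grid$z
  nz <- length(z); nx <- length(x)
  ch <- if (analytic) analytic_signal(ev$data) else ev$data
  fs <- rf$fs; t0 <- rf$t0
  xe <- rf$array$x

  if (rf$mode == "bmode") {
    ix <- which.min(abs(x - ev$aline_x))
    if (abs(x[ix] - ev$aline_x) > 1e-9)
      stopf("B-mode beamforming grid must contain the simulated A-line positions")
    xs <- x[ix]; cols <- ix
  } else {
    xs <- x; cols <- seq_len(nx)
  }
  ncol_out <- length(cols)

  t_tx <- switch(rf$mode,
    pw = {
      off <- if (is.null(ev$offset)) 0 else ev$offset
      th <- ev$angle * pi / 180
      outer(z * cos(th) / med$c, xs * sin(th) / med$c, "+") + off
    },
    sa = {
      xi <- xe[ev$tx_element]
      sqrt(outer(z^2, (xs - xi)^2, "+")) / med$c
    },
    bmode = matrix(z / med$c, nz, ncol_out)
  )

  acc <- matrix(if (analytic) 0i else 0, nz, ncol_out)
  count <- matrix(0L, nz, ncol_out)
  half_ap <- z / (2 * grid$f_number)   # per-depth receive half aperture
  if (symmetric) {
    # shrink so [x - w, x + w] never runs off the array
    room <- pmin(outer(rep(1, nz), xs) - min(xe), max(xe) - outer(rep(1, nz), xs))
    half_mat <- pmin(outer(half_ap, rep(1, ncol_out)), room)
  } else {
    half_mat <- outer(half_ap, rep(1, ncol_out))
  }

  seg <- NULL
  if (!is.null(fixed_foci)) {
    edges <- c(-Inf, (fixed_foci[-1] + fixed_foci[-length(fixed_foci)]) / 2, Inf)
    seg <- findInterval(z, edges)      # receive focus segment per depth
  }

  # two-way pulse group delay: the echo envelope of w1 * w2 is centered
  # (T_tx + T_rx)/2 after the geometric flight time; sampling there keeps
  # the image registered to the true scatterer depths
  pd <- (rf$pulse_tx$duration + rf$pulse_rx$duration) / 2

  for (j in seq_len(ncol(ch))) {
    dxj <- abs(outer(rep(1, nz), xs) - xe[j])
    ok <- dxj <= half_mat
    if (!any(ok)) next
    if (is.null(seg)) {
      t_rx <- sqrt(outer(z^2, (xs - xe[j])^2, "+")) / med$c
    } else {
      zf <- fixed_foci[seg]
      t_rx <- (sqrt(outer(zf^2, (xs - xe[j])^2, "+")) + (z - zf)) / med$c
    }
    v <- sample_linear(ch[, j], fs, t0, as.vector(t_tx + t_rx + pd))
    v[!as.vector(ok)] <- 0
    acc <- acc + matrix(v, nz, ncol_out)
    count <- count + ok
  }

  if (rf$mode == "bmode") {
    full <- matrix(if (analytic) 0i else 0, nz, nx)
    full[, cols] <- acc
    fullc <- matrix(0L, nz, nx); fullc[, cols] <- count
    acc <- full; count <- fullc
  }
  structure(acc, grid = grid, label = ev$label, n_empty = sum(count == 0),
            class = "us_frame")
}

#' Coherent compounding
#'
#' Coherently (pre-envelope) sums beamformed frames from multiple transmit
#' events on a shared grid.
#'
#' @param frames list of \code{us_frame} objects on identical grids.
#' @return a single \code{us_frame}.
#' @export
compound <- function(frames) {
  if (length(frames) == 0) stopf("no frames to compound")
  g <- attr(frames[[1]], "grid")
  for (f in frames[-1])
    if (!same_grid(attr(f, "grid"), g)) stopf("frames are on different grids")
  out <- Reduce(`+`, frames)
  attributes(out) <- attributes(frames[[1]])
  attr(out, "label") <- "compound"
  out
}

#' Envelope detection and log compression
#'
#' Computes the per-A-line envelope (the analytic-signal magnitude along
#' depth for real frames; the modulus for complex frames beamformed from
#' analytic channel data), normalizes by the global maximum, log-compresses
#' to dB, and clips at \code{-dynamic_range}.
#'
#' @param frame a \code{us_frame}.
#' @param dynamic_range display dynamic range in dB (default 60, i.e. the
#'   image spans 0 to -60 dB).
#' @return an object of class \code{us_bmode}: a dB-valued matrix (max 0)
#'   with attributes \code{grid} and \code{dynamic_range}.
#' @export
envelope_logcompress <- function(frame, dynamic_range = 60) {
  env <- if (is.complex(frame)) Mod(frame) else {
    m <- unclass(frame); attributes(m) <- list(dim = dim(frame))
    Mod(analytic_signal(m))
  }
  peak <- max(env)
  if (peak == 0) stopf("all-zero frame: envelope normalization undefined")
  img <- 20 * log10(pmax(env / peak, 10^(-dynamic_range / 20 - 2)))
  img <- pmax(img, -dynamic_range)
  structure(img, grid = attr(frame, "grid"), dynamic_range = dynamic_range,
            label = attr(frame, "label"), class = "us_bmode")
}

#' @export
print.us_bmode <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("B-mode image: %d x %d px, x [%.1f, %.1f] mm, z [%.1f, %.1f] mm, 0 to -%g dB\n",
              nrow(x), ncol(x), 1e3 * min(g$x), 1e3 * max(g$x),
              1e3 * min(g$z), 1e3 * max(g$z), attr(x, "dynamic_range")))
  invisible(x)
}

#' @export
plot.us_bmode <- function(x, ...) {
  g <- attr(x, "grid")
  image(g$x * 1e3, g$z * 1e3, t(unclass(x)), col = gray(seq(0, 1, length.out = 256)),
        xlab = "x (mm)", ylab = "z (mm)", ylim = rev(range(g$z * 1e3)),
        useRaster = TRUE, ...)
  invisible(x)
}
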