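#' Slow-time Doppler ensemble
#'
#' A stack of complex beamformed frames acquired at the pulse repetition
#' frequency on a fixed pixel grid, plus the acquisition parameters the
#' velocity estimator needs.
#'
#' @param frames complex array of dimension nz x nx x K (slow-time ordered),
#'   or a list of K equally-sized complex frames.
#' @param prf pulse repetition frequency (Hz).
#' @param f0 transmit center frequency (Hz).
#' @param flow_angle_deg beam-to-flow angle in degrees (the beam is +z;
#'   0 = axial flow, 90 would be degenerate).
#' @param medium a \code{us_medium}.
#' @param grid the \code{us_bfgrid} the frames live on.
#' @return an object of class \code{us_ensemble}.
#' @export
us_ensemble <- function(frames, prf, f0, flow_angle_deg, medium, grid = NULL) {
  if (is.list(frames))
    frames <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2)
    stopf("an ensemble needs at least K = 2 frames")
  if (prf <= 0) stopf("prf must be positive")
  structure(list(frames = frames, prf = prf, f0 = f0,
                 flow_angle_deg = flow_angle_deg, medium = medium,
                 grid = grid), class = "us_ensemble")
}

#' Wall filter (slow-time mean subtraction)
#'
#' Removes static tissue contributions by subtracting each pixel's
#' slow-time mean across the ensemble, preserving dynamic signal from
#' moving scatterers. The output's slow-time mean is zero at every pixel.
#'
#' @param ensemble a \code{us_ensemble} (K >= 2).
#' @return the filtered \code{us_ensemble}.
#' @export
wall_filter <- function(ensemble) {
  a <- ensemble$frames
  k <- dim(a)[3]
  if (k < 2) stopf("wall filter needs K >= 2 frames")
  m <- apply(a, c(1, 2), mean)
  ensemble$frames <- a - array(m, dim(a))
  ensemble
}

#' Magnitude threshold mask
#'
#' Suppresses velocity estimates where the signal is weak: pixels whose
#' slow-time mean magnitude falls below the peak magnitude times
#' \code{10^(-cutoff_db / 20)} are masked out. The reference peak is taken
#' over the supplied (typically wall-filtered) ensemble(s).
#'
#' @param ensemble a \code{us_ensemble} or a list of them (e.g. one per
#'   steering angle; the mean magnitude then pools all frames).
#' @param cutoff_db cutoff below the peak, in dB (default 4).
#' @return logical matrix: TRUE where the estimate is kept.
#' @export
magnitude_threshold <- function(ensemble, cutoff_db = 4) {
  ens_list <- if (inherits(ensemble, "us_ensemble")) list(ensemble) else ensemble
  mags <- lapply(ens_list, function(e) apply(Mod(e$frames), c(1, 2), mean))
  mag <- Reduce(`+`, mags) / length(mags)
  peak <- max(mag)
  if (peak == 0) return(mag > 0)          # all-zero ensemble: all-FALSE
  mag >= peak * 10^(-cutoff_db / 20)
}

#' Autocorrelation velocity estimation
#'
#' Phase-based flow velocity estimation from the lag-one slow-time
#' autocorrelation: per pixel
#' \deqn{\hat R = \frac{1}{K-1} \sum_{k=1}^{K-1} s_k^{*}\, s_{k+1}, \qquad
#'   v = \frac{c\, f_{PRF}}{4 \pi f_0 \cos\theta}\,
#'       \mathrm{atan2}(\mathrm{Im}\,\hat R, \mathrm{Re}\,\hat R),}
#' where \eqn{\theta} is the beam-to-flow angle; the returned velocity is
#' the angle-corrected flow speed, positive for flow with a component
#' toward the transducer. When several ensembles are supplied (one per
#' steering angle), the lag-one autocorrelations are computed per ensemble
#' and averaged coherently (complex sum) before the phase is taken, so
#' inter-angle phase offsets never mix into slow time. The magnitude of the
#' estimate never exceeds the Nyquist velocity
#' \code{c * prf / (4 f0 cos(theta))}.
#'
#' @param ensemble a (wall-filtered) \code{us_ensemble} or list of them.
#' @param mask optional logical keep-mask (from
#'   \code{\link{magnitude_threshold}}); masked-out pixels get v = 0 and
#'   valid = FALSE.
#' @return an object of class \code{us_vmap}: list with the velocity matrix
#'   \code{v} (m/s), logical \code{valid}, the \code{nyquist} bound (m/s)
#'   and the pixel \code{grid}.
#' @export
velocity_estimate <- function(ensemble, mask = NULL) {
  ens_list <- if (inherits(ensemble, "us_ensemble")) list(ensemble) else ensemble
  e1 <- ens_list[[1]]
  costh <- cos(e1$flow_angle_deg * pi / 180)
  if (abs(costh) < 1e-12) stopf("degenerate flow angle: cos(theta) = 0")
  rhat <- 0
  for (e in ens_list) {
    a <- e$frames
    k <- dim(a)[3]
    r <- 0
    for (i in seq_len(k - 1)) r <- r + Conj(a[, , i]) * a[, , i + 1]
    rhat <- rhat + r / (k - 1)
  }
  rhat <- rhat / length(ens_list)
  scale <- e1$medium$c * e1$prf / (4 * pi * e1$f0 * costh)
  v <- scale * atan2(Im(rhat), Re(rhat))
  valid <- Mod(rhat) > 0
  if (!is.null(mask)) valid <- valid & mask
  v[!valid] <- 0
  structure(list(v = v, valid = valid,
                 nyquist = abs(e1$medium$c * e1$prf / (4 * e1$f0 * costh)),
                 grid = e1$grid), class = "us_vmap")
}

#' @export
print.us_vmap <- function(x, ...) {
  cat(sprintf("Velocity map: %d x %d px, %d valid, |v| <= %.3g m/s (Nyquist %.3g m/s)\n",
              nrow(x$v), ncol(x$v), sum(x$valid), max(abs(x$v)), x$nyquist))
  invisible(x)
}

#' @export
plot.us_vmap <- function(x, ...) {
  g <- x$grid
  v <- x$v; v[!x$valid] <- NA
  image(g$x * 1e3, g$z * 1e3, t(v), col = hcl.colors(128, "Blue-Red 3"),
        zlim = c(-1, 1) * max(abs(v), na.rm = TRUE),
        xlab = "x (mm)", ylab = "z (mm)", ylim = rev(range(g$z * 1e3)),
        useRaster = TRUE, ...)
  invisible(x)
}

# 1-D Hamming-weighted moving average along each column (zero-phase,
# mask-normalized): num/den with kernel k.
smooth_cols <- function(m, k) {
  n <- nrow(m); h <- (length(k) - 1) / 2
  pad <- matrix(0, h, ncol(m))
  mp <- rbind(pad, m, pad)
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + n - 1), , drop = FALSE]
  out
}

#' Spatial smoothing of a velocity map
#'
#' 2-D separable Hamming-weighted moving average, with weights renormalized
#' within the valid mask so masked-out pixels neither contribute nor dilute
#' the average. Window extents are given in meters and converted to odd
#' pixel counts on the map's grid.
#'
#' @param vmap a \code{us_vmap}.
#' @param height axial window extent (m); default the 1.54 mm used for the
#'   vessel examples.
#' @param width lateral window extent (m); default 1.57 mm.
#' @return the smoothed \code{us_vmap}.
#' @export
spatial_smooth <- function(vmap, height = 1.54e-3, width = 1.57e-3) {
  g <- vmap$grid
  dz <- if (length(g$z) > 1) g$z[2] - g$z[1] else height
  dx <- if (length(g$x) > 1) g$x[2] - g$x[1] else width
  nh <- max(1L, 2L * floor(height / dz / 2) + 1L)
  nw <- max(1L, 2L * floor(width / dx / 2) + 1L)
  if (nh > nrow(vmap$v) || nw > ncol(vmap$v))
    stopf("smoothing window exceeds the map extent")
  kh <- as.numeric(signal::hamming(nh))
  kw <- as.numeric(signal::hamming(nw))
  vm <- vmap$v * vmap$valid
  num <- t(smooth_cols(t(smooth_cols(vm, kh)), kw))
  den <- t(smooth_cols(t(smooth_cols(vmap$valid * 1, kh)), kw))
  v <- ifelse(den > 0, num / den, 0)
  v[!vmap$valid] <- 0
  vmap$v <- v
  vmap
}

#' Lateral flow profile
#'
#' Averages a velocity map across a region to a 1-D profile. For a
#' rectangular region (\code{list(x = c(lo, hi), z = c(lo, hi))}) the
#' profile is the per-x mean over the region's depth extent. For a vessel
#' region (\code{list(center =, axis =, radius =)}, or a
#' \code{us_flow_phantom}) pixels are mapped to vessel coordinates and the
#' profile is taken across the vessel: estimates are averaged along the
#' vessel axis within the interior plus a \code{margin} (default 1 mm)
#' outside the walls, binned by the signed perpendicular distance from the
#' axis, so the profile's abscissa spans the vessel diameter.
#'
#' @param vmap a \code{us_vmap}.
#' @param region rectangle, vessel descriptor, or \code{us_flow_phantom}.
#' @param margin extra band outside the vessel walls (m) for vessel
#'   regions.
#' @param bin_width profile bin width (m) for vessel regions; defaults to
#'   the map's lateral pixel spacing. Wider bins pool more pixels per
#'   profile point.
#' @return a data.frame with columns \code{x} (profile coordinate, m),
#'   \code{v} (mean velocity, m/s), \code{n} (valid pixels per bin), and
#'   \code{v_norm} (\code{v} normalized by the profile value nearest
#'   x = 0).
#' @export
lateral_average_profile <- function(vmap, region, margin = 1e-3,
                                    bin_width = NULL) {
  g <- vmap$grid
  if (inherits(region, "us_flow_phantom"))
    region <- list(center = region$center, axis = region$axis,
                   radius = region$radius)
  if (!is.null(region$radius)) {
    u <- region$axis[c(1, 3)]
    u <- u / sqrt(sum(u^2))                  # in-plane axis direction
    nv <- c(-u[2], u[1])                     # in-plane normal
    px <- outer(rep(1, length(g$z)), g$x) - region$center[1]
    pz <- outer(g$z, rep(1, length(g$x))) - region$center[3]
    q <- px * nv[1] + pz * nv[2]             # signed distance from axis
    keep <- abs(q) <= region$radius + margin & vmap$valid
    if (!any(keep)) stopf("region does not intersect the map")
    bw <- bin_width %||%
      (if (length(g$x) > 1) g$x[2] - g$x[1] else region$radius / 10)
    bin <- round(q / bw)
    agg <- tapply(vmap$v[keep], bin[keep], mean)
    cnt <- tapply(rep(1, sum(keep)), bin[keep], sum)
    out <- data.frame(x = as.numeric(names(agg)) * bw, v = as.numeric(agg),
                      n = as.numeric(cnt))
  } else {
    inx <- g$x >= region$x[1] & g$x <= region$x[2]
    inz <- g$z >= region$z[1] & g$z <= region$z[2]
    if (!any(inx) || !any(inz)) stopf("region does not intersect the map")
    sub <- vmap$v[inz, inx, drop = FALSE]
    val <- vmap$valid[inz, inx, drop = FALSE]
    v <- colSums(sub * val) / pmax(colSums(val), 1)
    out <- data.frame(x = g$x[inx], v = v, n = colSums(val))
  }
  out <- out[order(out$x), ]
  i0 <- which.min(abs(out$x))
  out$v_norm <- if (out$v[i0] != 0) out$v / out$v[i0] else out$v
  rownames(out) <- NULL
  out
}

#' Nyquist velocity
#'
#' Maximum unambiguous (angle-corrected) Doppler velocity
#' \code{c * prf / (4 f0 cos(theta))}.
#'
#' @param medium a \code{us_medium}.
#' @param prf pulse repetition frequency (Hz).
#' @param f0 transmit center frequency (Hz).
#' @param flow_angle_deg beam-to-flow angle (degrees).
#' @export
nyquist_velocity <- function(medium, prf, f0, flow_angle_deg = 0) {
  medium$c * prf / (4 * f0 * cos(flow_angle_deg * pi / 180))
}

#' Color Doppler acquisition
#'
#' Runs the full color Doppler simulation chain on a flow phantom: for each
#' steering angle, \code{frames_per_angle} plane-wave transmissions are
#' simulated at the pulse repetition frequency, with the moving scatterers
#' advanced by \code{1/prf} between transmissions (and across angles, so
#' acquisition time is continuous); each transmission is beamformed to a
#' complex frame with analytic channel data. Static-scatterer echoes are
#' computed once per angle (they are identical across that angle's frames)
#' and added to every frame. The result is one slow-time ensemble per
#' angle, ready for \code{\link{wall_filter}} /
#' \code{\link{velocity_estimate}}.
#'
#' @param phantom a \code{us_flow_phantom}.
#' @param array a \code{us_array}.
#' @param pulse_tx transmit excitation (e.g. 4 cycles at 2.5 MHz).
#' @param pulse_rx receive excitation (e.g. 1 cycle at 2.5 MHz).
#' @param medium a \code{us_medium}.
#' @param fs RF sampling frequency (Hz).
#' @param prf pulse repetition frequency (Hz).
#' @param angles_deg plane-wave steering angles (degrees).
#' @param frames_per_angle slow-time ensemble length per angle.
#' @param bf_grid a \code{us_bfgrid} for beamforming.
#' @param quad element-face quadrature; defaults to 3 x 12 nodes (lateral x
#'   elevation) — unlike amplitude imaging, the velocity estimator needs
#'   the element height modeled so the elevation sample volume is
#'   beam-limited rather than spanning the whole vessel, and the elevation
#'   pattern of a 7 mm element converges slowly (the lateral axis of a
#'   0.3 mm element needs only a few nodes).
#' @param symmetric keep receive apertures symmetric about each pixel (see
#'   \code{\link{das_beamform}}); on by default for Doppler because an
#'   edge-truncated aperture tilts the effective beam and biases the phase.
#' @param verbose print per-frame progress.
#' @return a list of \code{us_ensemble} objects, one per angle, with the
#'   phantom's beam-to-flow angle attached.
#' @export
doppler_acquire <- function(phantom, array, pulse_tx, pulse_rx, medium, fs,
                            prf, angles_deg, frames_per_angle, bf_grid,
                            quad = element_quadrature(array, 3, 12),
                            symmetric = TRUE, verbose = FALSE) {
  all_pos <- rbind(phantom$moving$pos, phantom$static$pos)
  taus <- lapply(angles_deg, function(a) plane_wave_delays(array, a, medium))
  grid <- auto_rf_grid(array, all_pos, unlist(taus), pulse_tx, pulse_rx,
                       medium, fs)
  rx <- seq_len(array$n)
  apod <- rep(1, array$n)
  tau0 <- rep(0, array$n)
  flow_angle <- phantom$flow_angle_deg
  rf_stub <- list(mode = "pw", fs = grid$fs, t0 = grid$t0, array = array,
                  medium = medium, pulse_tx = pulse_tx, pulse_rx = pulse_rx)
  ph <- phantom
  ensembles <- vector("list", length(angles_deg))
  for (a in seq_along(angles_deg)) {
    tau <- taus[[a]]
    static_raw <- if (nrow(phantom$static$pos) > 0)
      rf_event_raw(array, phantom$static, rx, tau, apod, rx, tau0,
                   pulse_tx, pulse_rx, medium, grid, quad) else 0
    frames <- vector("list", frames_per_angle)
    for (k in seq_len(frames_per_angle)) {
      raw <- rf_event_raw(array, ph$moving, rx, tau, apod, rx, tau0,
                          pulse_tx, pulse_rx, medium, grid, quad)
      ev <- list(data = time_derivative(raw + static_raw, fs),
                 angle = angles_deg[a], offset = attr(tau, "offset"))
      frames[[k]] <- das_one(ev, rf_stub, bf_grid, medium, analytic = TRUE,
                             fixed_foci = NULL, symmetric = symmetric)
      ph <- advance_flow(ph, 1 / prf)
      if (verbose)
        message(sprintf("angle %+g deg, frame %d/%d", angles_deg[a], k,
                        frames_per_angle))
    }
    ensembles[[a]] <- us_ensemble(
      array(unlist(frames), c(dim(frames[[1]]), frames_per_angle)),
      prf, pulse_tx$f0, flow_angle, medium, bf_grid)
  }
  ensembles
}
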