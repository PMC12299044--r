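#' Default cyst-phantom feature layout
#'
#' Five point targets, five hyperechoic spheres, and five anechoic spheres
#' arranged in three depth columns inside the default background region
#' (lateral columns at -15, 0 and +15 mm; depths 40-80 mm).
#'
#' @param radius sphere radius (m) for the hyper-/anechoic regions.
#' @return data.frame with columns type, x, y, z, radius.
#' @export
cyst_features <- function(radius = 3e-3) {
  z <- seq(40e-3, 80e-3, by = 10e-3)
  rbind(
    data.frame(type = "point", x = -15e-3, y = 0, z = z, radius = 0),
    data.frame(type = "hyperechoic", x = 0, y = 0, z = z, radius = radius),
    data.frame(type = "anechoic", x = 15e-3, y = 0, z = z, radius = radius)
  )
}

#' Cyst / point-target speckle phantom
#'
#' Random background scatterers with Gaussian amplitudes (mean 0, variance
#' 1), modified by spherical features: inside anechoic spheres the
#' amplitude is set to 0, inside hyperechoic spheres it is multiplied by
#' 10, and discrete point targets with amplitude 20 are appended. The
#' defaults reproduce a 50 x 10 x 60 mm background starting 30 mm from the
#' array with five features of each class.
#'
#' Sampling is reproducible for a fixed seed; the stream order is part of
#' the API: x, then y, then z uniform draws (one \code{runif(n)} each),
#' then \code{rnorm(n)} amplitudes.
#'
#' @param region list with ranges \code{x}, \code{y}, \code{z} (each
#'   \code{c(lo, hi)}, m).
#' @param n_scatterers number of background scatterers (> 0).
#' @param features data.frame as from \code{\link{cyst_features}}.
#' @param seed RNG seed.
#' @return a \code{us_scatterers}.
#' @export
cyst_phantom <- function(region = list(x = c(-25e-3, 25e-3),
                                       y = c(-5e-3, 5e-3),
                                       z = c(30e-3, 90e-3)),
                         n_scatterers = 1e5,
                         features = cyst_features(), seed = 1) {
  if (n_scatterers <= 0) stopf("n_scatterers must be positive")
  with_seed(seed, {
    pos <- cbind(runif(n_scatterers, region$x[1], region$x[2]),
                 runif(n_scatterers, region$y[1], region$y[2]),
                 runif(n_scatterers, region$z[1], region$z[2]))
    amp <- rnorm(n_scatterers)
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      if (f$type == "point") next
      inside <- (pos[, 1] - f$x)^2 + (pos[, 2] - f$y)^2 + (pos[, 3] - f$z)^2 <=
        f$radius^2
      if (f$type == "anechoic") amp[inside] <- 0
      if (f$type == "hyperechoic") amp[inside] <- amp[inside] * 10
    }
    pts <- features[features$type == "point", , drop = FALSE]
    if (nrow(pts) > 0) {
      pos <- rbind(pos, cbind(pts$x, pts$y, pts$z))
      amp <- c(amp, rep(20, nrow(pts)))
    }
    us_scatterers(pos, amp, seed = seed)
  })
}

#' Grayscale-image template phantom
#'
#' Uses a 2-D grayscale image as a scatterer-amplitude template: scatterers
#' are distributed uniformly in a 3-D region; each scatterer's (x, z)
#' coordinates are mapped to the nearest image pixel (scatterers falling
#' outside the image extent are excluded); pixel values (0-255 scale) are
#' divided by 100, exponentiated, shifted to a zero baseline by subtracting
#' the global minimum weight, uniformly rescaled to \code{[0, max_weight]},
#' and multiplied by independent standard-normal draws, giving zero-mean
#' amplitudes whose local variance follows the image brightness.
#'
#' Stream order under a fixed seed: x, y, z uniforms, then the standard
#' normals for the retained (in-bounds) scatterers.
#'
#' @param image numeric matrix of pixel values on a 0-255 scale (rows map
#'   to z, columns to x), or the path of a grayscale PNG (read with the
#'   \pkg{png} package and rescaled to 0-255).
#' @param region list with ranges \code{x}, \code{y}, \code{z} (m).
#' @param n_scatterers number of scatterers before bounds exclusion.
#' @param seed RNG seed.
#' @param image_extent list with \code{x} and \code{z} ranges (m) the image
#'   spans; defaults to the region's x/z ranges (no exclusion).
#' @param max_weight upper end of the rescaled weights (default 1e6; the
#'   absolute scale cancels in the normalized image).
#' @return a \code{us_scatterers}.
#' @export
image_template_phantom <- function(image, region, n_scatterers, seed = 1,
                                   image_extent = NULL, max_weight = 1e6) {
  if (is.character(image)) {
    if (!requireNamespace("png", quietly = TRUE))
      stopf("reading PNG templates requires the png package")
    img <- png::readPNG(image)
    if (length(dim(img)) == 3) img <- img[, , 1]
    image <- img * 255
  }
  if (!is.matrix(image) || length(image) == 0) stopf("image must be a non-empty matrix")
  if (is.null(image_extent)) image_extent <- list(x = region$x, z = region$z)
  w <- exp(image / 100)
  w <- w - min(w)
  mw <- max(w)
  if (mw > 0) w <- w / mw * max_weight
  with_seed(seed, {
    pos <- cbind(runif(n_scatterers, region$x[1], region$x[2]),
                 runif(n_scatterers, region$y[1], region$y[2]),
                 runif(n_scatterers, region$z[1], region$z[2]))
    keep <- pos[, 1] >= image_extent$x[1] & pos[, 1] <= image_extent$x[2] &
      pos[, 3] >= image_extent$z[1] & pos[, 3] <= image_extent$z[2]
    pos <- pos[keep, , drop = FALSE]
    nr <- nrow(image); nc <- ncol(image)
    col <- pmin(pmax(round((pos[, 1] - image_extent$x[1]) /
                             diff(image_extent$x) * (nc - 1)) + 1, 1), nc)
    row <- pmin(pmax(round((pos[, 3] - image_extent$z[1]) /
                             diff(image_extent$z) * (nr - 1)) + 1, 1), nr)
    amp <- w[cbind(row, col)] * rnorm(nrow(pos))
    us_scatterers(pos, amp, seed = seed)
  })
}

#' Vessel flow phantom
#'
#' Moving scatterers uniformly distributed in a 3-D cylindrical vessel
#' embedded in a static speckle background. The vessel is tilted in the
#' imaging (x-z) plane; flow is along the vessel axis with either a laminar
#' (plug) profile, where every scatterer moves at the peak speed, or a
#' parabolic (Poiseuille) profile \code{v(rho) = peak * (1 - (rho/R)^2)}
#' with \code{rho} the radial distance from the axis. Static scatterers
#' fill a rectangular region excluding the vessel. Defaults follow the
#' carotid-artery configuration: 50,000 moving scatterers (amplitude
#' variance 1) in a 5 mm-radius vessel at 45 degrees centered 40 mm from
#' the array, and 50,000 static scatterers (amplitude variance 625) in a
#' 60 x 10 x 70 mm region starting 10 mm from the array.
#'
#' By default the flow direction is the axis direction with a negative z
#' (toward-array) component, so the estimator's toward-positive convention
#' reports positive speeds.
#'
#' Stream order under a fixed seed: moving axial positions, radii,
#' azimuths, moving amplitudes; then static positions (batched rejection
#' against the vessel), static amplitudes.
#'
#' @param n_moving,n_static scatterer counts.
#' @param radius vessel radius (m).
#' @param angle_deg vessel tilt from the beam axis (degrees, in (0, 90)).
#' @param center_depth depth of the vessel center (m).
#' @param half_length half the vessel's axial extent (m); scatterers
#'   leaving one end re-enter at the other.
#' @param static_region list with \code{x}, \code{y}, \code{z} ranges (m).
#' @param profile \code{"laminar"} or \code{"parabolic"}.
#' @param peak_speed peak flow speed (m/s).
#' @param moving_sd,static_sd amplitude standard deviations (defaults 1 and
#'   25, i.e. variances 1 and 625).
#' @param seed RNG seed.
#' @return an object of class \code{us_flow_phantom}: moving and static
#'   \code{us_scatterers}, per-scatterer velocity vectors, and the vessel
#'   geometry (center, unit axis, radius, half_length, beam-to-flow angle).
#' @export
vessel_flow_phantom <- function(n_moving = 50000, n_static = 50000,
                                radius = 5e-3, angle_deg = 45,
                                center_depth = 40e-3, half_length = 20e-3,
                                static_region = list(x = c(-30e-3, 30e-3),
                                                     y = c(-5e-3, 5e-3),
                                                     z = c(10e-3, 80e-3)),
                                profile = c("laminar", "parabolic"),
                                peak_speed = 0.5,
                                moving_sd = 1, static_sd = 25, seed = 1) {
  profile <- match.arg(profile)
  if (radius <= 0) stopf("radius must be positive")
  if (angle_deg <= 0 || angle_deg >= 90)
    stopf("vessel angle must be strictly between 0 and 90 degrees")
  a <- angle_deg * pi / 180
  center <- c(0, 0, center_depth)
  u <- c(sin(a), 0, -cos(a))     # axis/flow direction, toward the array
  e1 <- c(cos(a), 0, sin(a))     # in-plane perpendicular
  e2 <- c(0, 1, 0)
  with_seed(seed, {
    s <- runif(n_moving, -half_length, half_length)
    rho <- radius * sqrt(runif(n_moving))
    phi <- runif(n_moving, 0, 2 * pi)
    mpos <- matrix(center, n_moving, 3, byrow = TRUE) +
      outer(s, u) + outer(rho * cos(phi), e1) + outer(rho * sin(phi), e2)
    mamp <- rnorm(n_moving, sd = moving_sd)
    speed <- if (profile == "laminar") rep(peak_speed, n_moving)
             else peak_speed * (1 - (rho / radius)^2)
    vel <- outer(speed, u)

    spos <- matrix(0, 0, 3)
    tries <- 0
    while (nrow(spos) < n_static) {
      m <- max(n_static - nrow(spos), 1000L) * 2L
      cand <- cbind(runif(m, static_region$x[1], static_region$x[2]),
                    runif(m, static_region$y[1], static_region$y[2]),
                    runif(m, static_region$z[1], static_region$z[2]))
      d <- sweep(cand, 2, center)
      salong <- d %*% u
      perp2 <- rowSums(d^2) - salong^2
      outside <- perp2 > radius^2 | abs(salong) > half_length
      cand <- cand[outside, , drop = FALSE]
      if (nrow(cand) == 0) {
        tries <- tries + 1
        if (tries > 50) stopf("static region lies entirely inside the vessel")
        next
      }
      spos <- rbind(spos, cand)
    }
    spos <- spos[seq_len(n_static), , drop = FALSE]
    samp <- rnorm(n_static, sd = static_sd)

    structure(list(moving = us_scatterers(mpos, mamp, seed = seed),
                   velocities = vel,
                   static = us_scatterers(spos, samp, seed = seed),
                   center = center, axis = u, radius = radius,
                   half_length = half_length, profile = profile,
                   peak_speed = peak_speed,
                   flow_angle_deg = angle_deg, seed = seed),
              class = "us_flow_phantom")
  })
}

#' @export
print.us_flow_phantom <- function(x, ...) {
  cat(sprintf("Flow phantom: %d moving (%s, peak %.2g m/s) + %d static scatterers\n",
              nrow(x$moving$pos), x$profile, x$peak_speed, nrow(x$static$pos)))
  cat(sprintf("  vessel: radius %.1f mm at %g deg, center depth %.1f mm\n",
              x$radius * 1e3, x$flow_angle_deg, x$center[3] * 1e3))
  invisible(x)
}

#' Advance a flow phantom in time
#'
#' Moves every flowing scatterer by \code{velocity * dt}; scatterers
#' leaving the vessel's axial extent re-enter at the opposite end with the
#' same radial offset and speed (wrap-around preserves uniform density).
#' Static scatterers are unchanged.
#'
#' @param phantom a \code{us_flow_phantom}.
#' @param dt time step in seconds (>= 0).
#' @return the advanced \code{us_flow_phantom}.
#' @export
advance_flow <- function(phantom, dt) {
  if (dt < 0) stopf("dt must be non-negative")
  if (dt == 0) return(phantom)
  pos <- phantom$moving$pos + phantom$velocities * dt
  d <- sweep(pos, 2, phantom$center)
  s <- as.vector(d %*% phantom$axis)
  l <- phantom$half_length
  snew <- ((s + l) %% (2 * l)) - l
  pos <- pos + outer(snew - s, phantom$axis)
  phantom$moving$pos <- pos
  phantom
}
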