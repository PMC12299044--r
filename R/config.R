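# Configuration-driven runs: schema validation, execution, file output.
# RF data is written as raw little-endian float32 with a JSON sidecar
# describing layout and acquisition parameters; images as 8-bit PNG.

run_modes <- c("sa", "bmode", "pw", "doppler", "convergence")

#' Read a run configuration
#'
#' Reads a YAML or JSON run configuration and validates it against the
#' expected schema (see \code{\link{run_config}} for the recognized keys).
#' Validation failures name the offending field.
#'
#' @param path file path (.yaml/.yml or .json).
#' @return the validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
validate_run_config <- function(cfg) {
  need <- function(ok, field, why = "is missing or invalid") {
    if (!isTRUE(ok)) stopf("config field '%s' %s", field, why)
  }
  need(is.character(cfg$mode) && cfg$mode %in% run_modes, "mode",
       sprintf("must be one of %s", paste(run_modes, collapse = ", ")))
  a <- cfg$array
  need(!is.null(a), "array")
  need(is.numeric(a$n_elements) && a$n_elements >= 1, "array.n_elements")
  need(is.numeric(a$width_m) && a$width_m > 0, "array.width_m")
  need(is.numeric(a$height_m) && a$height_m > 0, "array.height_m")
  need(is.numeric(a$kerf_m) && a$kerf_m >= 0, "array.kerf_m")
  e <- cfg$excitation
  need(!is.null(e), "excitation")
  need(is.numeric(e$f0_hz) && e$f0_hz > 0, "excitation.f0_hz")
  need(is.numeric(e$n_cycles) && e$n_cycles > 0, "excitation.n_cycles")
  m <- cfg$medium
  need(!is.null(m), "medium")
  need(is.numeric(m$c_m_s) && m$c_m_s > 0, "medium.c_m_s")
  need(is.numeric(m$rho_kg_m3) && m$rho_kg_m3 > 0, "medium.rho_kg_m3")
  need(is.numeric(cfg$fs_hz) && cfg$fs_hz > 0, "fs_hz")
  need(is.numeric(cfg$seed), "seed")
  if (cfg$mode %in% c("sa", "bmode", "pw", "doppler")) {
    need(!is.null(cfg$phantom$type), "phantom.type")
    need(!is.null(cfg$beamforming), "beamforming")
  }
  if (cfg$mode == "pw")
    need(is.numeric(cfg$angles_deg) && length(cfg$angles_deg) >= 1, "angles_deg")
  if (cfg$mode == "doppler") {
    d <- cfg$doppler
    need(!is.null(d), "doppler")
    need(is.numeric(d$prf_hz) && d$prf_hz > 0, "doppler.prf_hz")
    need(is.numeric(d$frames_per_angle) && d$frames_per_angle >= 2,
         "doppler.frames_per_angle")
    need(is.numeric(cfg$angles_deg), "angles_deg")
  }
  cfg
}

config_phantom <- function(cfg, scale = 1) {
  p <- cfg$phantom
  n <- function(x) max(1L, round(x * scale))
  switch(p$type,
    cyst = cyst_phantom(
      region = list(x = p$region$x_m, y = p$region$y_m, z = p$region$z_m),
      n_scatterers = n(p$n_scatterers),
      features = if (is.null(p$features)) cyst_features() else p$features,
      seed = cfg$seed),
    vessel = vessel_flow_phantom(
      n_moving = n(p$n_moving), n_static = n(p$n_static),
      radius = p$radius_m, angle_deg = p$angle_deg,
      center_depth = p$center_depth_m,
      half_length = if (is.null(p$half_length_m)) 20e-3 else p$half_length_m,
      static_region = list(x = p$static_region$x_m, y = p$static_region$y_m,
                           z = p$static_region$z_m),
      profile = p$profile, peak_speed = p$peak_speed_m_s, seed = cfg$seed),
    image = image_template_phantom(
      p$image_path,
      region = list(x = p$region$x_m, y = p$region$y_m, z = p$region$z_m),
      n_scatterers = n(p$n_scatterers), seed = cfg$seed),
    stopf("config field 'phantom.type' must be cyst, vessel or image"))
}

config_bfgrid <- function(cfg, array) {
  b <- cfg$beamforming
  x <- if (!is.null(b$x_m)) seq(b$x_m[1], b$x_m[2], by = b$dx_m)
       else aline_positions(array)
  z <- seq(b$z_m[1], b$z_m[2], by = b$dz_m)
  beamform_grid(x, z, if (is.null(b$f_number)) 2 else b$f_number)
}

write_f32 <- function(x, path, meta) {
  con <- file(path, "wb")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(meta, sub("\\.f32$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_bmode_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) return(invisible(FALSE))
  dr <- attr(img, "dynamic_range")
  png::writePNG((unclass(img) + dr) / dr, path)
  invisible(TRUE)
}

write_velocity_png <- function(vmap, path) {
  if (!requireNamespace("png", quietly = TRUE)) return(invisible(FALSE))
  v <- vmap$v / max(vmap$nyquist, 1e-12)
  rgb <- array(0, c(dim(v), 3))
  rgb[, , 1] <- pmax(pmin(1, 0.5 + v), 0)       # red toward
  rgb[, , 3] <- pmax(pmin(1, 0.5 - v), 0)       # blue away
  rgb[, , 2] <- 0.1
  for (k in 1:3) {
    ch <- rgb[, , k]; ch[!vmap$valid] <- 0; rgb[, , k] <- ch
  }
  png::writePNG(rgb, path)
  invisible(TRUE)
}

#' Execute a run configuration
#'
#' Runs a full simulation described by a configuration list (see the
#' shipped examples under \code{system.file("configs", package =
#' "echosim")}): builds the array, excitation, medium and phantom,
#' synthesizes RF data for the configured imaging mode, beamforms and (for
#' imaging modes) writes a log-compressed image, or (for \code{doppler})
#' runs the color-flow chain and writes the velocity map. Artifacts go to
#' \code{cfg$output_dir}: RF traces as raw float32 + JSON sidecars, images
#' as PNG, and a provenance record (\code{provenance.json}) with the full
#' configuration, seed and package version, so every artifact is
#' reproducible from its log.
#'
#' @param cfg validated configuration list (see
#'   \code{\link{read_run_config}}).
#' @param force overwrite existing outputs (default: refuse).
#' @param scale factor applied to scatterer counts for desk-scale runs.
#' @param write_rf write per-event RF payloads (can be large).
#' @return (invisibly) a list of the main in-memory results.
#' @export
run_config <- function(cfg, force = FALSE, scale = 1, write_rf = TRUE) {
  cfg <- validate_run_config(cfg)
  dir <- cfg$output_dir
  if (is.null(dir)) stopf("config field 'output_dir' is missing or invalid")
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stopf("output directory '%s' is not empty (use force = TRUE)", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  array <- linear_array(cfg$array$n_elements, cfg$array$width_m,
                        cfg$array$height_m, cfg$array$kerf_m)
  medium <- us_medium(cfg$medium$c_m_s, cfg$medium$rho_kg_m3)
  pulse_tx <- us_pulse(cfg$excitation$f0_hz, cfg$excitation$n_cycles)
  pulse_rx <- if (is.null(cfg$excitation$rx_n_cycles)) pulse_tx
              else us_pulse(cfg$excitation$f0_hz, cfg$excitation$rx_n_cycles)
  fs <- cfg$fs_hz
  res <- list()

  if (cfg$mode == "convergence") {
    sc <- cyst_phantom(region = list(x = c(-5e-3, 5e-3), y = c(0, 0),
                                     z = c(35e-3, 45e-3)),
                       n_scatterers = max(1, round(50 * scale)),
                       features = cyst_features()[0, ], seed = cfg$seed)
    res$convergence <- convergence_study(array, sc, pulse_tx, medium)
    utils::write.csv(res$convergence, file.path(dir, "convergence.csv"),
                     row.names = FALSE)
  } else {
    phantom <- config_phantom(cfg, scale)
    bf <- config_bfgrid(cfg, array)
    if (cfg$mode == "doppler") {
      d <- cfg$doppler
      ens <- doppler_acquire(phantom, array, pulse_tx, pulse_rx, medium, fs,
                             d$prf_hz, cfg$angles_deg, d$frames_per_angle, bf)
      ens <- lapply(ens, wall_filter)
      mask <- magnitude_threshold(ens, if (is.null(d$cutoff_db)) 4 else d$cutoff_db)
      vmap <- spatial_smooth(velocity_estimate(ens, mask))
      res$vmap <- vmap
      write_f32(vmap$v, file.path(dir, "velocity.f32"),
                list(dims = dim(vmap$v), layout = "column-major float32 z-fast",
                     x_m = range(bf$x), z_m = range(bf$z),
                     nyquist_m_s = vmap$nyquist))
      write_f32(vmap$valid * 1, file.path(dir, "velocity_mask.f32"),
                list(dims = dim(vmap$v), layout = "column-major float32 z-fast"))
      write_velocity_png(vmap, file.path(dir, "velocity.png"))
    } else {
      scat <- if (inherits(phantom, "us_flow_phantom")) phantom$moving else phantom
      rf <- switch(cfg$mode,
        sa = simulate_synthetic_aperture(array, scat, pulse_tx, medium, fs,
                                         pulse_rx = pulse_rx),
        pw = simulate_plane_wave(array, scat, pulse_tx, medium, fs,
                                 cfg$angles_deg, pulse_rx = pulse_rx),
        bmode = simulate_bmode(array, scat, pulse_tx, medium, fs,
                               n_sub = cfg$n_sub %||% min(64L, array$n),
                               focus_depth = cfg$focus_depth_m %||% 60e-3,
                               aline_x = bf$x, pulse_rx = pulse_rx))
      if (write_rf)
        for (ev in rf$events)
          write_f32(ev$data, file.path(dir, paste0("rf_", gsub("[^A-Za-z0-9+.-]", "_", ev$label), ".f32")),
                    list(dims = dim(ev$data), layout = "column-major float32 time-fast",
                         fs_hz = rf$fs, t0_s = rf$t0, label = ev$label,
                         angle_deg = ev$angle, delays_s = as.numeric(ev$tau_tx)))
      frames <- das_beamform(rf, bf,
                             fixed_foci = cfg$beamforming$fixed_foci_m)
      img <- envelope_logcompress(compound(frames),
                                  cfg$beamforming$dynamic_range_db %||% 60)
      res$rf <- rf; res$image <- img
      write_bmode_png(img, file.path(dir, "bmode.png"))
    }
  }
  prov <- list(config = cfg, seed = cfg$seed, scale = scale,
               package_version = as.character(utils::packageVersion("echosim")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
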