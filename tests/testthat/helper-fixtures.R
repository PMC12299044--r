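# Shared small fixtures for the test suite.  Everything is built in code;
# sizes are kept small so individual tests run in seconds.

tissue <- us_medium()                    # 1540 m/s, 1000 kg/m^3
pulse3 <- us_pulse(3e6, 1)               # single-cycle 3 MHz
imaging_array <- function(n = 8) linear_array(n, 0.3e-3, 7e-3, 0.05e-3)

# A single point scatterer on axis.
point_target <- function(z = 30e-3, x = 0, amp = 1) {
  us_scatterers(matrix(c(x, 0, z), 1, 3), amp)
}

# A small seeded random cloud around a given depth.
small_cloud <- function(n = 20, z0 = 40e-3, half = 5e-3, seed = 99) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pos <- cbind(runif(n, -half, half), 0, runif(n, z0 - half, z0 + half))
  us_scatterers(pos, rnorm(n))
}

# Envelope peak time of a single-channel trace.
envelope_peak_time <- function(trace, fs, t0) {
  env <- Mod(analytic_signal(trace))
  t0 + (which.max(env) - 1) / fs
}

# Perpendicular in-plane distance of every pixel from a vessel axis.
vessel_perp_distance <- function(grid, phantom) {
  u <- phantom$axis[c(1, 3)]; u <- u / sqrt(sum(u^2))
  nv <- c(-u[2], u[1])
  px <- outer(rep(1, length(grid$z)), grid$x) - phantom$center[1]
  pz <- outer(grid$z, rep(1, length(grid$x))) - phantom$center[3]
  abs(px * nv[1] + pz * nv[2])
}
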