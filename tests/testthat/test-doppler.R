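dummy_grid <- beamform_grid(seq(-1e-3, 1e-3, 1e-3), seq(1e-3, 3e-3, 1e-3), 2)

make_ensemble <- function(frames, prf = 5000, f0 = 2.5e6, angle = 0) {
  us_ensemble(frames, prf, f0, angle, tissue, dummy_grid)
}

test_that("wall filtering removes static signal exactly", {
  K <- 6
  static <- matrix(rnorm(9) + 1i * rnorm(9), 3, 3)
  moving <- array(rnorm(9 * K) + 1i * rnorm(9 * K), c(3, 3, K))
  both <- array(0i, c(3, 3, K))
  for (k in 1:K) both[, , k] <- static + moving[, , k]
  wf_both <- wall_filter(make_ensemble(both))
  wf_mov <- wall_filter(make_ensemble(moving))
  expect_equal(wf_both$frames, wf_mov$frames, tolerance = 1e-12)
  # identical frames cancel completely
  same <- array(rep(static, K), c(3, 3, K))
  expect_lt(max(Mod(wall_filter(make_ensemble(same))$frames)), 1e-14)
  # output slow-time mean is zero at every pixel
  expect_lt(max(Mod(apply(wf_both$frames, c(1, 2), mean))), 1e-14)
  one <- array(static, c(3, 3, 1))
  expect_error(wall_filter(make_ensemble(one)), "at least K = 2")
})

test_that("magnitude thresholding keeps pixels within the cutoff of the peak", {
  fr <- array(0i, c(1, 2, 3))
  fr[1, 1, ] <- 1; fr[1, 2, ] <- 0.5
  ens <- make_ensemble(fr)
  m4 <- magnitude_threshold(ens, 4)
  expect_equal(as.vector(m4), c(TRUE, FALSE))     # 0.5 < 10^(-0.2) = 0.631
  m0 <- magnitude_threshold(ens, 0)
  expect_equal(as.vector(m0), c(TRUE, FALSE))     # only the peak survives
  mInf <- magnitude_threshold(ens, Inf)
  expect_true(all(mInf))
  zero <- make_ensemble(array(0i, c(1, 2, 3)))
  expect_false(any(magnitude_threshold(zero, 4)))
})

test_that("rigid axial motion maps to velocity exactly", {
  f0 <- 2.5e6; prf <- 5000; lam <- 1540 / f0
  K <- 10
  phase <- 2 * pi * f0 * 2 * (lam / 8) / 1540     # lambda/8 toward per PRI
  base <- matrix(rnorm(9) + 1i * rnorm(9), 3, 3)
  fr <- array(0i, c(3, 3, K))
  for (k in 1:K) fr[, , k] <- base * exp(1i * (k - 1) * phase)
  vm <- velocity_estimate(make_ensemble(fr, prf, f0))
  expect_equal(max(abs(vm$v - (lam / 8) * prf)), 0, tolerance = 1e-6 * (lam / 8) * prf)
  # reversing the flow negates the estimate everywhere
  frr <- array(0i, c(3, 3, K))
  for (k in 1:K) frr[, , k] <- base * exp(-1i * (k - 1) * phase)
  vr <- velocity_estimate(make_ensemble(frr, prf, f0))
  expect_equal(vr$v, -vm$v, tolerance = 1e-12)
})

test_that("the estimator is invariant to global phase and amplitude", {
  set.seed(11)
  K <- 8
  fr <- array(rnorm(4 * 4 * K) + 1i * rnorm(4 * 4 * K), c(4, 4, K))
  v0 <- velocity_estimate(make_ensemble(fr))
  v1 <- velocity_estimate(make_ensemble(fr * (3.7 * exp(1.2i))))
  expect_equal(v1$v, v0$v, tolerance = 1e-12)
  # and never exceeds the Nyquist bound
  expect_lte(max(abs(v0$v)), v0$nyquist * (1 + 1e-12))
  # static ensembles give zero velocity after wall filtering
  st <- wall_filter(make_ensemble(array(rep(fr[, , 1], K), c(4, 4, K))))
  expect_true(all(velocity_estimate(st)$v == 0))
})

test_that("angle degeneracy and multi-angle averaging behave", {
  K <- 4
  fr <- array(1 + 0i, c(2, 2, K))
  expect_error(velocity_estimate(make_ensemble(fr, angle = 90)), "degenerate")
  # averaging identical ensembles changes nothing
  e <- make_ensemble(fr)
  expect_equal(velocity_estimate(list(e, e))$v, velocity_estimate(e)$v)
})

test_that("spatial smoothing is a normalized Hamming moving average", {
  nz <- 21; nx <- 21
  g <- beamform_grid(seq_len(nx) * 1e-4, seq_len(nz) * 1e-4, 2)
  mk <- function(v, valid = matrix(TRUE, nz, nx))
    structure(list(v = v, valid = valid, nyquist = 1, grid = g),
              class = "us_vmap")
  # constant map unchanged
  cm <- spatial_smooth(mk(matrix(2.5, nz, nx)), 5e-4, 5e-4)
  expect_equal(cm$v, matrix(2.5, nz, nx), tolerance = 1e-12)
  # single-pixel window: identity
  v <- matrix(rnorm(nz * nx), nz, nx)
  expect_equal(spatial_smooth(mk(v), 1e-9, 1e-9)$v, v)
  # impulse response: normalized outer product of 1-D Hamming windows
  imp <- matrix(0, nz, nx); imp[11, 11] <- 1
  sm <- spatial_smooth(mk(imp), 5e-4, 7e-4)
  kh <- as.numeric(signal::hamming(5)); kw <- as.numeric(signal::hamming(7))
  expected <- outer(kh, kw) / (sum(kh) * sum(kw))
  expect_equal(sm$v[9:13, 8:14], expected, tolerance = 1e-12)
  expect_error(spatial_smooth(mk(v), 1, 1), "exceeds")
})

test_that("lateral profiles average the expected regions", {
  nz <- 30; nx <- 25
  g <- beamform_grid(seq(-3e-3, 3e-3, length.out = nx),
                     seq(35e-3, 45e-3, length.out = nz), 2)
  uni <- structure(list(v = matrix(0.7, nz, nx), valid = matrix(TRUE, nz, nx),
                        nyquist = 1, grid = g), class = "us_vmap")
  pr <- lateral_average_profile(uni, list(x = c(-2e-3, 2e-3),
                                          z = c(37e-3, 43e-3)))
  expect_true(all(abs(pr$v - 0.7) < 1e-12))
  expect_true(all(abs(pr$v_norm - 1) < 1e-12))
  expect_error(lateral_average_profile(uni, list(x = c(1, 2), z = c(1, 2))),
               "intersect")
})

test_that("vessel-coordinate profiles recover a synthetic parabola", {
  # construct a map whose value is the parabolic profile of a 45-degree
  # vessel, then check the binned profile reproduces it
  nz <- 80; nx <- 80
  g <- beamform_grid(seq(-8e-3, 8e-3, length.out = nx),
                     seq(32e-3, 48e-3, length.out = nz), 2)
  ph <- list(center = c(0, 0, 40e-3), axis = c(sin(pi / 4), 0, -cos(pi / 4)),
             radius = 4e-3)
  u <- ph$axis[c(1, 3)]; nv <- c(-u[2], u[1])
  px <- outer(rep(1, nz), g$x) - ph$center[1]
  pz <- outer(g$z, rep(1, nx)) - ph$center[3]
  q <- px * nv[1] + pz * nv[2]
  v <- pmax(1 - (q / ph$radius)^2, 0)
  vm <- structure(list(v = v, valid = abs(q) < ph$radius + 1e-3, nyquist = 2,
                       grid = g), class = "us_vmap")
  pr <- lateral_average_profile(vm, ph)
  i0 <- which.min(abs(pr$x))
  expect_equal(pr$v[i0], 1, tolerance = 0.05)
  fit <- lm(v ~ I(x^2), data = pr[abs(pr$x) <= ph$radius, ])
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("a translating scatterer cloud is recovered within five percent", {
  # axial rigid motion, theta = 0, one steering angle, noiseless
  a <- imaging_array(16)
  vtrue <- 0.2; prf <- 4000; f0 <- 2.5e6
  ph <- vessel_flow_phantom(n_moving = 150, n_static = 0, radius = 2e-3,
                            angle_deg = 45, center_depth = 25e-3,
                            half_length = 2.5e-3, profile = "laminar",
                            peak_speed = vtrue, seed = 5,
                            static_region = list(x = c(-1e-3, 1e-3),
                                                 y = c(-1e-3, 1e-3),
                                                 z = c(20e-3, 22e-3)))
  # override the velocities: rigid axial translation toward the array
  ph$velocities <- matrix(rep(c(0, 0, -vtrue), each = 150), ncol = 3)
  ph$flow_angle_deg <- 0
  ph$half_length <- 1    # effectively no recycling over the ensemble
  # narrowband two-way pulse so the spectral centroid sits at the nominal
  # f0 the estimator assumes (a broadband receive pulse shifts the echo
  # centroid upward and scales all estimates accordingly)
  ptx <- us_pulse(f0, 4); prx <- us_pulse(f0, 4)
  bf <- beamform_grid(seq(-2e-3, 2e-3, by = 0.35e-3), seq(22e-3, 28e-3, by = 0.5e-3), 1.5)
  ens <- doppler_acquire(ph, a, ptx, prx, tissue, 20e6, prf, 0, 8, bf)
  vm <- velocity_estimate(lapply(ens, wall_filter),
                          magnitude_threshold(lapply(ens, wall_filter), 10))
  inv <- vessel_perp_distance(bf, ph) <= ph$radius & vm$valid
  expect_gt(sum(inv), 20)
  expect_equal(mean(vm$v[inv]), vtrue, tolerance = 0.05)
})
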