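test_that("forward projection is linear and annihilates the zero image", {
  g <- scan_geometry(30, 40, 24, 24, pixel_size = 1)
  expect_equal(max(abs(forward_project(matrix(0, 24, 24), g)$values)), 0)
  set.seed(11)
  f1 <- matrix(rnorm(24 * 24), 24)
  f2 <- matrix(rnorm(24 * 24), 24)
  lhs <- forward_project(2.5 * f1 - 1.25 * f2, g)$values
  rhs <- 2.5 * forward_project(f1, g)$values - 1.25 * forward_project(f2, g)$values
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("backprojection is the exact numerical adjoint of the projector", {
  set.seed(21)
  geoms <- list(scan_geometry(90, 96, 64, 64, pixel_size = 1),
                scan_geometry(50, 70, 40, 56, pixel_size = 0.7,
                              detector_spacing = 0.9))
  for (g in geoms) {
    for (rep in 1:10) {
      f <- matrix(rnorm(g$image_rows * g$image_cols), g$image_rows)
      s <- matrix(rnorm(g$n_views * g$n_detectors), g$n_views)
      ip1 <- sum(forward_project(f, g)$values * s)
      ip2 <- sum(f * back_project(sinogram(s, g)))
      expect_lt(abs(ip1 - ip2) / max(abs(ip1), 1e-12), 1e-6)
    }
  }
  expect_equal(max(abs(back_project(
    sinogram(matrix(0, 90, 96), geoms[[1L]])))), 0)
})

test_that("a single nonzero ray backprojects only onto pixels it crosses", {
  g <- scan_geometry(4, 31, 24, 24, pixel_size = 1)
  s <- matrix(0, 4, 31)
  s[1L, 16L] <- 1  # view at angle 0, central detector: vertical center line
  img <- back_project(sinogram(s, g))
  hit <- which(img != 0, arr.ind = TRUE)
  expect_true(all(hit[, "col"] %in% c(12L, 13L)))
  expect_equal(nrow(unique(hit)), nrow(hit))
})

test_that("central ray through a uniform disk matches the analytic chord", {
  g <- scan_geometry(36, 95, 96, 96, pixel_size = 1)
  R <- 30; mu <- 0.05
  img <- aa_disk(96, 96, c(48.5, 48.5), R, mu)
  sino <- forward_project(img, g)$values
  central <- sino[, 48L]  # s = 0 for every view
  expect_true(all(abs(central - 2 * R * mu) / (2 * R * mu) < 0.01))
})

test_that("FBP inverts the projector on smooth phantoms and is linear", {
  g <- scan_geometry(180, 185, 128, 128, pixel_size = 1)
  expect_equal(max(abs(fbp_reconstruct(sinogram(matrix(0, 180, 185), g)))), 0)
  ph <- smooth_phantom(128)
  sino <- forward_project(ph, g)
  rec <- fbp_reconstruct(sino)
  expect_lt(rmse(rec, ph) / sqrt(mean(ph^2)), 0.05)
  disk <- aa_disk(128, 128, c(64.5, 64.5), 40, 0.02)
  sd2 <- forward_project(disk, g)
  expect_lt(rmse(fbp_reconstruct(sd2), disk) / sqrt(mean(disk^2)), 0.05)
  rec2 <- fbp_reconstruct(sinogram(2 * sino$values, g))
  expect_lt(max(abs(rec2 - 2 * rec)), 1e-10)
  expect_error(fbp_reconstruct(sino, "butterworth"), "unknown FBP filter")
})

test_that("SART has consistent data as a fixed point and solves the 1-pixel system", {
  g <- scan_geometry(60, 95, 64, 64, pixel_size = 1)
  img <- aa_disk(64, 64, c(32.5, 32.5), 20, 0.04)
  sino <- forward_project(img, g)
  expect_lt(max(abs(sart_update(img, sino, relaxation = 1) - img)), 1e-10)

  # one pixel, one ray of weight w, datum p, relaxation 1, start 0 -> p / w
  g1 <- scan_geometry(1, 1, 1, 1, pixel_size = 3)
  w <- forward_project(matrix(1, 1, 1), g1)$values[1L, 1L]
  out <- sart_update(matrix(0, 1, 1), sinogram(matrix(6, 1, 1), g1),
                     relaxation = 1)
  expect_equal(out[1L, 1L], 6 / w, tolerance = 1e-12)
  expect_error(sart_update(img, sino, relaxation = 0), "relaxation")
})

test_that("SART residual decreases monotonically on noiseless data", {
  g <- scan_geometry(90, 95, 64, 64, pixel_size = 1)
  ph <- smooth_phantom(64) + aa_disk(64, 64, c(40.5, 28.5), 9, 0.02)
  sino <- forward_project(ph, g)
  w <- projection_weights(g)
  f <- matrix(0, 64, 64)
  res <- numeric(25)
  for (it in seq_len(25)) {
    f <- sart_update(f, sino, relaxation = 0.2, weights = w)
    res[it] <- sqrt(sum((forward_project(f, g)$values - sino$values)^2))
  }
  expect_true(all(diff(res) < 0))
})

test_that("the data subproblem reduces to SART as tau -> 0 and applies the exact pointwise step", {
  cfg <- tiny_config()
  st <- build_study(cfg)
  sinos <- simulate_channel_sinograms(st$phantom, st$basis, st$spectrum,
                                      st$windows, st$geometry,
                                      noise = FALSE)
  C <- length(sinos$channels)
  F0 <- array(0, c(64, 64, C))
  plain <- solve_data_subproblem(F0, sinos, coeffs = NULL, Fc_vol = NULL,
                                 tau = 1, n_sweeps = 3L)
  coeffs <- lapply(seq_len(C), function(i)
    list(a = matrix(1, 64, 64), b = matrix(0, 64, 64)))
  Fc <- array(0.01, c(64, 64, C))
  coupled <- solve_data_subproblem(F0, sinos, coeffs, Fc, tau = 1e-12,
                                   n_sweeps = 3L)
  expect_lt(max(abs(coupled - plain)), 1e-8)

  # pointwise closed form: one sweep, compare against a manual computation
  w <- projection_weights(st$geometry)
  tau <- 0.8; tp <- tau / (1 + tau)
  one <- solve_data_subproblem(F0, sinos, coeffs, Fc, tau = tau,
                               n_sweeps = 1L, nonneg = FALSE, weights = w)
  for (ch in seq_len(C)) {
    fs <- sart_update(F0[, , ch], sinos$channels[[ch]], 0.2,
                      nonneg = FALSE, weights = w)
    manual <- (fs + tp * 1 * (Fc[, , ch] - 0)) / (1 + tp)
    expect_lt(max(abs(one[, , ch] - manual)), 1e-12)
  }
  expect_error(solve_data_subproblem(F0, sinos, coeffs, Fc, tau = -1), "tau")
})

test_that("the coupled data objective is non-increasing over sweeps on noiseless data", {
  cfg <- tiny_config()
  st <- build_study(cfg)
  sinos <- simulate_channel_sinograms(st$phantom, st$basis, st$spectrum,
                                      st$windows, st$geometry, noise = FALSE)
  C <- length(sinos$channels)
  fb <- fbp_volume(sinos)
  bt <- build_transformed_volume(fb, 1L, llt_params(radius = 3, eps = 5e-7))
  tau <- 0.5
  objective <- function(F) {
    pred <- array(0, dim(F))
    for (i in seq_len(C)) pred[, , i] <- bt$coeffs[[i]]$a * F[, , i] + bt$coeffs[[i]]$b
    elltct:::data_residual2(F, sinos) + tau * sum((bt$values - pred)^2)
  }
  F <- array(0, c(64, 64, C))
  vals <- objective(F)
  for (k in 1:6) {
    F <- solve_data_subproblem(F, sinos, bt$coeffs, bt$values, tau,
                               n_sweeps = 1L)
    vals <- c(vals, objective(F))
  }
  expect_true(all(diff(vals) <= 1e-8 * vals[1L]))
})

test_that("geometry and sinogram constructors validate their invariants", {
  expect_error(scan_geometry(10, 20, 16, 16, pixel_size = -1), "positive")
  expect_error(scan_geometry(3, 20, 16, 16, angles = c(0, 0.5, 0.4)),
               "increasing")
  g <- scan_geometry(10, 20, 16, 16)
  expect_error(sinogram(matrix(0, 9, 20), g), "geometry expects")
  expect_error(forward_project(matrix(0, 8, 16), g), "geometry expects")
  g2 <- scan_geometry(10, 20, 16, 16, pixel_size = 2)
  s1 <- sinogram(matrix(0, 10, 20), g)
  s2 <- sinogram(matrix(0, 10, 20), g2)
  expect_error(sinogram_set(list(s1, s2)), "share one geometry")
})
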