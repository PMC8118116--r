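test_that("surrogate attenuation curves follow the two-term law and decrease", {
  grid <- seq(20, 120, by = 1)
  basis <- toy_attenuation_model(c("water", "bone", "muscle", "fat", "titanium"),
                                 grid)
  expect_true(all(basis$mu > 0))
  expect_true(all(apply(basis$mu, 2L, function(m) all(diff(m) < 0))))
  # 1/E^3 functional form: mu(E) - c is proportional to E^-3, so the ratio
  # of differences at three energies is fixed by the grid alone
  for (m in basis$materials) {
    mu <- function(E) basis$mu[match(E, grid), m]
    lhs <- (mu(20) - mu(120)) / (mu(40) - mu(120))
    rhs <- (20^-3 - 120^-3) / (40^-3 - 120^-3)
    expect_equal(as.numeric(lhs), rhs, tolerance = 1e-10)
  }
  expect_error(toy_attenuation_model("adamantium"), "unknown material")
})

test_that("a single-energy window reduces the polychromatic model to the ray transform", {
  cfg <- tiny_config()
  st <- build_study(cfg)
  spec <- st$spectrum
  E0 <- 60
  win <- energy_windows(E0, E0 + 1)  # contains exactly one grid point
  sinos <- simulate_channel_sinograms(st$phantom, st$basis, spec, win,
                                      st$geometry, noise = FALSE)
  mu_map <- matrix(0, 64, 64)
  for (m in names(st$phantom$fractions))
    mu_map <- mu_map + st$phantom$fractions[[m]] *
      st$basis$mu[match(E0, st$basis$energies), m]
  ref <- forward_project(mu_map, st$geometry)$values
  expect_lt(max(abs(sinos$channels[[1L]]$values - ref)), 1e-8)
})

test_that("an empty phantom produces all-zero sinograms", {
  cfg <- tiny_config()
  st <- build_study(cfg)
  empty <- make_phantom(list(), 64, 64, pixel_size = 0.8)
  empty$fractions <- list(water = matrix(0, 64, 64))
  sinos <- simulate_channel_sinograms(empty, st$basis, st$spectrum,
                                      st$windows, st$geometry, noise = FALSE)
  for (ch in sinos$channels) expect_equal(max(abs(ch$values)), 0)
})

test_that("noise is reproducible given the seed and absent when disabled", {
  cfg <- tiny_config()
  st <- build_study(cfg)
  sim <- function(noise, seed = 5L)
    simulate_channel_sinograms(st$phantom, st$basis, st$spectrum, st$windows,
                               st$geometry, noise = noise, seed = seed)
  a <- sim(TRUE); b <- sim(TRUE); c3 <- sim(TRUE, seed = 6L)
  expect_identical(lapply(a$channels, `[[`, "values"),
                   lapply(b$channels, `[[`, "values"))
  expect_false(identical(a$channels[[1L]]$values, c3$channels[[1L]]$values))
  d <- sim(FALSE); e <- sim(FALSE, seed = 99L)
  expect_identical(lapply(d$channels, `[[`, "values"),
                   lapply(e$channels, `[[`, "values"))
})

test_that("widening a window never decreases expected transmitted counts", {
  cfg <- tiny_config()
  st <- build_study(cfg)
  spec <- st$spectrum
  # fixed absolute spectrum: bypass per-bin normalisation by comparing
  # expected counts per unit emitted photon, window [50, hi) growing
  counts <- sapply(c(60, 70, 80, 90), function(hi) {
    win <- energy_windows(50, hi)
    s <- simulate_channel_sinograms(st$phantom, st$basis, spec, win,
                                    st$geometry, photons_per_ray = 1,
                                    noise = FALSE)
    idx <- which(spec$energies >= 50 & spec$energies < hi)
    # undo the per-bin budget normalisation: scale by the window weight
    mean(attr(s, "expected_counts")[[1L]]) * sum(spec$weights[idx])
  })
  expect_true(all(diff(counts) > 0))
})

test_that("Poisson sampling matches the expected count to Monte Carlo accuracy", {
  # air rays: empty phantom, every ray carries photons_per_ray in expectation
  g <- scan_geometry(40, 100, 16, 16, pixel_size = 1)
  ph <- make_phantom(list(), 16, 16)
  ph$fractions <- list(water = matrix(0, 16, 16))
  basis <- toy_attenuation_model("water")
  spec <- default_spectrum()
  win <- energy_windows(30, 90)
  s <- simulate_channel_sinograms(ph, basis, spec, win, g,
                                  photons_per_ray = 1e4, noise = TRUE,
                                  seed = 12L)
  counts <- 1e4 * exp(-s$channels[[1L]]$values)  # invert the log transform
  n <- length(counts)
  se <- sqrt(1e4 / n)
  expect_lt(abs(mean(counts) - 1e4), 3 * se)
})

test_that("make_phantom paints disks deterministically with last-wins overlap", {
  empty <- make_phantom(list(), 32, 32)
  expect_length(empty$fractions, 0L)

  r <- 20
  one <- make_phantom(list(list(shape = "disk", material = "water",
                                radius = r)), 128, 128)
  n_px <- sum(one$fractions$water > 0)
  expect_lt(abs(n_px - pi * r^2), r)

  two <- make_phantom(list(
    list(shape = "disk", material = "water", center = c(20, 20), radius = 6),
    list(shape = "disk", material = "bone", center = c(44, 44), radius = 6)
  ), 64, 64)
  expect_equal(sum(two$fractions$water * two$fractions$bone), 0)

  lap <- make_phantom(list(
    list(shape = "disk", material = "water", center = c(32, 32), radius = 10),
    list(shape = "disk", material = "bone", center = c(32, 36), radius = 10)
  ), 64, 64)
  expect_equal(sum(lap$fractions$water * lap$fractions$bone), 0)
  expect_true(lap$fractions$bone[32, 36] == 1 && lap$fractions$water[32, 36] == 0)

  expect_error(make_phantom(list(list(shape = "disk", material = "water",
                                      radius = 4, fraction = 1.2)), 16, 16),
               "fraction")
  expect_error(make_phantom(list(list(shape = "square", material = "water",
                                      radius = 4)), 16, 16), "unsupported shape")
})

test_that("spectrum and window constructors validate invariants", {
  expect_error(source_spectrum(c(20, 20), c(1, 1)), "strictly increasing")
  expect_error(source_spectrum(c(20, 30), c(0, 0)), "positive total")
  expect_error(energy_windows(c(30, 50), c(60, 80)), "disjoint")
  expect_error(energy_windows(50, 40), "hi > lo")
  cfg <- tiny_config()
  st <- build_study(cfg)
  expect_error(
    simulate_channel_sinograms(st$phantom, st$basis, st$spectrum,
                               energy_windows(121, 130), st$geometry,
                               noise = FALSE),
    "no spectrum grid point")
})
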