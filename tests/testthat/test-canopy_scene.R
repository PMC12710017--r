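# Scene geometry, four-component rendering, shadow fraction, fesc and the
# canopy mixing model.

fake_sun <- function(zenith, azimuth) {
  structure(list(zenith = zenith, azimuth = azimuth, daylight = zenith < 90),
            class = "solar_geometry")
}

test_that("scene construction enforces geometry invariants", {
  lay <- orchard_layout(2, 3, row_spacing = 3.5, tree_spacing = 2)
  expect_equal(nrow(lay), 6)
  expect_equal(sort(unique(lay$x)), c(1, 3, 5))   # exact lattice, no jitter
  sc <- orchard_scene(lay, lai = 3)
  vol <- 4 / 3 * pi * sc$crown$ax * sc$crown$ay * sc$crown$az
  area <- (sc$extent["xmax"] - sc$extent["xmin"]) *
    (sc$extent["ymax"] - sc$extent["ymin"])
  expect_equal(sc$lai_scene, as.numeric(sum(sc$trees$u * vol) / area),
               tolerance = 1e-6)
  expect_error(orchard_scene(orchard_layout(1, 2, tree_spacing = 0.8)),
               "spacing")
  expect_error(orchard_layout(0, 3), "positive")
})

test_that("opaque crown viewed and lit from nadir has no shaded leaf pixels", {
  sc <- orchard_scene(orchard_layout(1, 1), lai = 60, margin = 1)
  img <- render_four_component(sc, fake_sun(0.001, 180), resolution = 0.05)
  inside <- img$crown_id == 1
  expect_gt(sum(img$labels[inside] == 1L), 0)
  expect_equal(sum(img$labels[inside] == 2L), 0)
})

test_that("sphere shadow area matches the line-sphere projection oracle", {
  crown <- list(ax = 1, ay = 1, az = 1, base = 0.8)
  sc <- orchard_scene(orchard_layout(1, 1), crown = crown, lai = 80,
                      margin = 3.5)
  sun <- fake_sun(45, 180)
  res <- 0.02
  img <- render_four_component(sc, sun, resolution = res, supersample = 2)
  # oracle: ground point is shaded iff the ray toward the sun passes within
  # r of the sphere centre (closed form, pixel centres outside the footprint)
  ext <- img$extent
  nx <- ncol(img$labels); ny <- nrow(img$labels)
  cx <- ext["xmin"] + (seq_len(nx) - 0.5) * res
  cy <- ext["ymin"] + (seq_len(ny) - 0.5) * res
  PX <- matrix(cx, ny, nx, byrow = TRUE)
  PY <- matrix(cy, ny, nx)
  ctr <- c(sc$trees$x[1], sc$trees$y[1], sc$trees$zc[1])
  sv <- c(sin(45 * pi / 180) * sin(pi), sin(45 * pi / 180) * cos(pi),
          cos(45 * pi / 180))
  sv <- c(0, -sin(45 * pi / 180), cos(45 * pi / 180))  # azimuth 180: from south
  vx <- ctr[1] - PX; vy <- ctr[2] - PY; vz <- ctr[3]
  dot <- vx * sv[1] + vy * sv[2] + vz * sv[3]
  cxp <- vy * sv[3] - vz * sv[2]
  cyp <- vz * sv[1] - vx * sv[3]
  czp <- vx * sv[2] - vy * sv[1]
  dist <- sqrt(cxp^2 + cyp^2 + czp^2)
  outside <- (PX - ctr[1])^2 + (PY - ctr[2])^2 > crown$ax^2
  oracle_shadow <- outside & dist < crown$ax & dot > 0
  got <- outside & img$labels == 4L
  expect_lt(abs(sum(got) - sum(oracle_shadow)) / sum(oracle_shadow), 0.05)
})

test_that("component fractions sum to one over every pixel", {
  d <- fx_diurnal()
  img <- d$images[[1]]
  tot <- img$f_sl + img$f_sh + img$f_sg + img$f_shg
  expect_lt(max(abs(tot - 1)), 1e-9)
})

test_that("crown shadow fraction handles the degenerate label patterns", {
  all_sun <- manual_four_component(matrix(1L, 4, 4))
  expect_equal(crown_shadow_fraction(all_sun, 1), 0)
  all_shade <- manual_four_component(matrix(2L, 4, 4))
  expect_equal(crown_shadow_fraction(all_shade, 1), 1)
  no_leaf <- manual_four_component(matrix(3L, 4, 4))
  expect_error(crown_shadow_fraction(no_leaf, 1), "leaf")
})

test_that("fesc approaches one as foliage density vanishes", {
  sc <- scene_with_lai(lut_scene(), 0.02)
  sun <- sun_position(40.154, 116.133, "2021-08-31", 12, 8)
  fe <- estimate_fesc(sc, sun, n_photons = 5000, seed = 3)
  expect_gt(fe$fesc, 1 - 5 * max(fe$se, 0.01))
})

test_that("fesc decreases along a leaf-area-density ladder", {
  sun <- sun_position(40.154, 116.133, "2021-08-31", 10, 8)
  fes <- vapply(c(1, 3, 5), function(lai)
    estimate_fesc(scene_with_lai(lut_scene(), lai), sun,
                  n_photons = 8000, seed = 7)$fesc, numeric(1))
  expect_true(all(diff(fes) < 0))
})

test_that("fesc estimates agree across photon budgets within 3 SE", {
  sc <- scene_with_lai(lut_scene(), 3)
  sun <- sun_position(40.154, 116.133, "2021-08-31", 12, 8)
  a <- estimate_fesc(sc, sun, n_photons = 1e5, seed = 2)
  b <- estimate_fesc(sc, sun, n_photons = 1e6, seed = 4)
  expect_lt(abs(a$fesc - b$fesc), 3 * sqrt(a$se^2 + b$se^2))
  expect_error(estimate_fesc(sc, sun, omega_nir = 1.2), "omega")
  expect_error(estimate_fesc(sc, sun, n_photons = 10), "photons")
})

test_that("mixing model limits are exact", {
  lo <- prospect5(leaf_biochem(cab = 50, cw = 0.02, cm = 0.01))
  soil <- soil_spectrum()
  # single sunlit-leaf component with no multiple scattering: BRF == rho
  brf <- synthesize_canopy_brf(c(1, 0, 0, 0), lo, soil, shadow_fraction = 0,
                               mixing = mixing_params(p0 = 0, p1 = 0))
  expect_identical(brf, lo$reflectance)
  # vanishing single-scattering albedo: no gain for any p
  dark <- list(reflectance = rep(1e-9, 10), transmittance = rep(0, 10))
  brf2 <- synthesize_canopy_brf(c(0.5, 0.5, 0, 0), dark, rep(0.1, 10), 0.9)
  expect_lt(max(brf2), 1e-8)
  expect_error(synthesize_canopy_brf(c(0.5, 0.4, 0, 0), lo, soil, 0),
               "fractions")
})

test_that("red and NIR bands respond oppositely to the shadow fraction", {
  lo <- prospect5(leaf_biochem(cab = 50, cw = 0.02, cm = 0.01))
  soil <- soil_spectrum()
  sfs <- seq(0, 0.6, by = 0.05)
  brf <- sapply(sfs, function(sf)
    resample_to_bands(400:2500,
                      synthesize_canopy_brf(c(1 - sf, sf, 0, 0), lo, soil, sf)))
  expect_true(all(diff(brf["RED", ]) < 0))
  expect_true(all(diff(brf["GREEN", ]) < 0))
  expect_true(all(diff(brf["NIR", ]) > 0))
})

test_that("lookup-table cardinality follows the factorial grid", {
  lut <- fx_mini_lut()
  expect_equal(nrow(lut), 8 * lut_size(lut_grid_mini()))
  expect_equal(length(unique(lut$time)), 8)
  need <- c("time", "sza", "saa", "shadow_fraction", "fesc", "n_struct",
            "cab", "cxc", "cbrown", "cw", "cm", "lai", uav_bands()$name)
  expect_true(all(need %in% names(lut)))
  M <- as.matrix(lut[, uav_bands()$name])
  expect_true(all(M >= 0 & M <= 1))
  g1 <- lut_grid(n_levels = c(n_struct = 1, cab = 1, cw = 1, lai = 1))
  expect_equal(lut_size(g1), 1)
  lut1 <- build_lut(grid = g1, times = c(12, 13), fesc_photons = 1000)
  expect_equal(nrow(lut1), 2)
  expect_error(build_lut(times = numeric(0)), "times")
})
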