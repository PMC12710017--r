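# Leaf radiative-transfer model: interface transmissivity, plate model,
# energy conservation and pigment response.

test_that("tav matches the numeric Fresnel-integration oracle", {
  expect_equal(tav(90, 1.0), 1.0)
  for (n in c(1.05, 1.2, 1.45, 1.6))
    for (alpha in c(20, 40, 59, 90))
      expect_equal(tav(alpha, n), tav_numeric(alpha, n), tolerance = 1e-6,
                   info = sprintf("alpha=%g n=%g", alpha, n))
  # physics-forced monotonicity: more index contrast, more interface loss
  ns <- seq(1.0, 1.6, by = 0.05)
  expect_true(all(diff(tav(90, ns)) < 0))
  expect_error(tav(0, 1.4), "alpha")
  expect_error(tav(40, 0.9), "refractive")
})

test_that("zero absorber conserves energy exactly", {
  for (N in c(1, 1.5, 2.7)) {
    lo <- prospect5(leaf_biochem(n_struct = N, cab = 0, cxc = 0, cbrown = 0,
                                 cw = 0, cm = 0))
    expect_lt(max(abs(lo$reflectance + lo$transmittance - 1)), 1e-9)
  }
})

test_that("plate model matches the independent transfer-matrix oracle", {
  cases <- list(
    leaf_biochem(n_struct = 1.5, cab = 40, cxc = 8, cbrown = 0,
                 cw = 0.01, cm = 0.009),                      # reference leaf
    leaf_biochem(n_struct = 1, cab = 20, cw = 0.01, cm = 0.01),
    leaf_biochem(n_struct = 3, cab = 70, cw = 0.03, cm = 0.01),
    leaf_biochem(n_struct = 2.2, cab = 55, cbrown = 0.5, cw = 0.02,
                 cm = 0.005))
  for (bc in cases) {
    got <- prospect5(bc)
    ref <- prospect_oracle(bc)
    expect_lt(max(abs(got$reflectance - ref$reflectance)), 1e-4)
    expect_lt(max(abs(got$transmittance - ref$transmittance)), 1e-4)
  }
})

test_that("chlorophyll absorbs in the visible only", {
  lo20 <- prospect5(leaf_biochem(cab = 20, cxc = 5, cw = 0.01, cm = 0.009))
  lo70 <- prospect5(leaf_biochem(cab = 70, cxc = 5, cw = 0.01, cm = 0.009))
  at <- function(lo, wl) lo$reflectance[lo$wavelength == wl]
  expect_lt(at(lo70, 550), at(lo20, 550))
  expect_lt(at(lo70, 670), at(lo20, 670))
  expect_lt(abs(at(lo70, 840) - at(lo20, 840)), 1e-6)
})

test_that("structure parameter raises NIR reflectance, lowers transmittance", {
  at <- function(lo, wl) lo$reflectance[lo$wavelength == wl]
  att <- function(lo, wl) lo$transmittance[lo$wavelength == wl]
  los <- lapply(c(1, 1.5, 2, 3), function(N)
    prospect5(leaf_biochem(n_struct = N, cab = 40, cw = 0.01, cm = 0.009)))
  rn <- vapply(los, at, numeric(1), wl = 840)
  tn <- vapply(los, att, numeric(1), wl = 840)
  expect_true(all(diff(rn) > 0))
  expect_true(all(diff(tn) < 0))
})

test_that("energy and absorption invariants hold across the grid", {
  base <- list(n_struct = 1.8, cab = 45, cxc = 10, cbrown = 0.2,
               cw = 0.015, cm = 0.008)
  lo <- prospect5(do.call(leaf_biochem, base))
  expect_true(all(is.finite(lo$reflectance)) && all(is.finite(lo$transmittance)))
  expect_identical(lo$wavelength, prospect_coefficients()$wavelength)
  expect_true(all(lo$reflectance + lo$transmittance <= 1 + 1e-9))
  # absorptance increases with every constituent at fixed others
  absb <- function(b) {
    l <- prospect5(do.call(leaf_biochem, b))
    1 - l$reflectance - l$transmittance
  }
  a0 <- absb(base)
  for (nm in c("cab", "cxc", "cbrown", "cw", "cm")) {
    b2 <- base
    b2[[nm]] <- b2[[nm]] * 1.5 + 0.01
    expect_true(all(absb(b2) - a0 >= -1e-9), info = nm)
  }
})

test_that("parameter validation rejects invalid biochemistry", {
  expect_error(leaf_biochem(n_struct = 0.5), "n_struct")
  expect_error(leaf_biochem(cab = -1), "contents")
  expect_error(plate_transmission(-0.1), "k")
})

test_that("coefficient tables round-trip through CSV", {
  co <- prospect_coefficients()
  expect_true(all(co$refractive_index > 1))
  expect_true(all(as.matrix(co[, -(1:2)]) >= 0))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(co, path, row.names = FALSE)
  co2 <- read_coefficients(path)
  expect_equal(co2$k_cab, co$k_cab, tolerance = 1e-12)
  lo <- prospect5(leaf_biochem(), coeffs = co2)
  expect_true(all(is.finite(lo$reflectance)))
})
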