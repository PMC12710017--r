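# Orchard layouts, ground-truth sampling, survey rendering and crown
# reflectance extraction.

test_that("presets reproduce the mapped orchard tree counts", {
  expect_equal(nrow(orchard_preset("orchard1")), 429)
  expect_equal(nrow(orchard_preset("orchard2")), 215)
  expect_equal(nrow(orchard_preset("mini")), 48)
  l1 <- orchard_preset("mini", seed = 2)
  l2 <- orchard_preset("mini", seed = 2)
  expect_identical(l1, l2)
})

test_that("truth sampling honours truncation and moments", {
  tr <- sample_truth(1000, seed = 31)
  expect_true(all(tr$lcc >= 40 & tr$lcc <= 85))
  expect_true(all(tr$lai >= 1 & tr$lai <= 6))
  expect_identical(tr$ccc, tr$lcc * tr$lai)
  expect_identical(tr, sample_truth(1000, seed = 31))
  # oracle: analytic truncated-normal mean and sd for mu 60, sd 10 on [40, 85]
  a <- (40 - 60) / 10; b <- (85 - 60) / 10
  Z <- pnorm(b) - pnorm(a)
  mu_t <- 60 + 10 * (dnorm(a) - dnorm(b)) / Z
  var_t <- 100 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
  se <- sqrt(var_t / 1000)
  expect_lt(abs(mean(tr$lcc) - mu_t), 3 * se)
  expect_error(sample_truth(10, lcc_bounds = c(80, 40)), "inverted")
})

test_that("crown reflectance extraction averages the right pixels", {
  labels <- matrix(3L, 4, 4)
  labels[1, 1] <- 1L; labels[1, 2] <- 2L
  cid <- matrix(0L, 4, 4)
  cid[1, 1] <- 1L; cid[1, 2] <- 1L; cid[2, 1] <- 2L
  bands <- array(0.1, c(4, 4, 5), dimnames = list(NULL, NULL, uav_bands()$name))
  bands[1, 1, ] <- 0.2; bands[1, 2, ] <- 0.4; bands[2, 1, ] <- 0.33
  survey <- structure(list(bands = bands, crown_id = cid, labels = labels,
                           truth = data.frame(tree_id = 1:2, lcc = c(50, 60),
                                              lai = c(3, 3), ccc = c(150, 180)),
                           resolution = 1,
                           extent = c(xmin = 0, xmax = 4, ymin = 0, ymax = 4)),
                      class = "synthetic_survey")
  cr <- extract_crown_reflectance(survey)
  expect_equal(cr$NIR[1], 0.3)          # two-pixel crown (0.2, 0.4)
  expect_equal(cr$NIR[2], 0.33)         # single-pixel crown
  # masking drops the shaded pixel of crown 1
  crm <- extract_crown_reflectance(survey, mask = "sunlit")
  expect_equal(crm$NIR[1], 0.2)
  expect_equal(crm$n_px[1], 1L)
})

test_that("survey rendering is reproducible and physically ordered", {
  lay <- orchard_layout(1, 2, tree_spacing = 2.5)
  tr <- data.frame(tree_id = 1:2, lcc = c(55, 55), lai = c(3, 3),
                   ccc = c(165, 165))
  s1 <- render_survey(lay, tr, time = 12, resolution = 0.05, seed = 9)
  s2 <- render_survey(lay, tr, time = 12, resolution = 0.05, seed = 9)
  expect_identical(s1$bands, s2$bands)
  expect_identical(s1$crown_id, s2$crown_id)
  # identical truth and symmetric geometry: nearly identical crown means
  cr <- extract_crown_reflectance(s1)
  expect_equal(cr$NIR[1], cr$NIR[2], tolerance = 0.02)
  expect_error(render_survey(lay, tr, resolution = 0.2), "resolution")
  expect_error(render_survey(lay, tr[1, ], time = 12), "one row per tree")
})

test_that("crown NIR increases with true LAI at fixed chlorophyll", {
  lay <- orchard_layout(1, 2, tree_spacing = 2.5)
  nir <- vapply(c(1.5, 3, 4.5), function(lai) {
    tr <- data.frame(tree_id = 1:2, lcc = 55, lai = lai, ccc = 55 * lai)
    s <- render_survey(lay, tr, time = 12, resolution = 0.05, noise_std = 0,
                       seed = 3)
    mean(extract_crown_reflectance(s)$NIR)
  }, numeric(1))
  expect_true(all(diff(nir) > 0))
})

test_that("noon survey is brighter in red and darker in NIR than morning", {
  lay <- orchard_layout(2, 3)
  tr <- sample_truth(6, seed = 5)
  s12 <- render_survey(lay, tr, time = 12, resolution = 0.05, noise_std = 0)
  s09 <- render_survey(lay, tr, time = 9, resolution = 0.05, noise_std = 0)
  c12 <- extract_crown_reflectance(s12)
  c09 <- extract_crown_reflectance(s09)
  expect_gt(mean(c12$RED), mean(c09$RED))
  expect_lt(mean(c12$NIR), mean(c09$NIR))
})

test_that("masking raises the visible-band crown mean", {
  survey <- fx_survey()
  cr <- extract_crown_reflectance(survey)
  crm <- extract_crown_reflectance(survey, mask = "sunlit")
  expect_true(mean(crm$RED) >= mean(cr$RED))
  expect_true(mean(crm$GREEN) >= mean(cr$GREEN))
})
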