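# Curve-fit R2, shadow-resistance ranking, rate of change and the
# disturbance-sensitivity sweep.

test_that("curve-fit R2 reproduces closed-form cases", {
  vi <- seq(-1, 1, length.out = 20)
  expect_equal(fit_vi_cab_r2(vi, 2 * vi + 1), 1)
  expect_equal(fit_vi_cab_r2(vi, rep(5, 20)), 0)
  # pure quadratic on a symmetric design: linear fit explains nothing
  vi5 <- -2:2
  expect_equal(fit_vi_cab_r2(vi5, vi5^2, families = "linear"), 0)
  expect_equal(fit_vi_cab_r2(vi5, vi5^2, families = "quadratic"), 1)
  expect_equal(fit_vi_cab_r2(vi5, vi5^2), 1)
  expect_error(fit_vi_cab_r2(c(1, 2), c(1, 2)), "pairs")
})

test_that("ranking sums per-case ranks with deterministic tie handling", {
  r2 <- matrix(c(0.9, 0.5, 0.1,
                 0.8, 0.6, 0.2,
                 0.7, 0.6, 0.3), nrow = 3,
               dimnames = list(c("A", "B", "C"), paste0("case", 1:3)))
  rk <- rank_vis(r2)
  expect_equal(rk$table$vi, c("A", "B", "C"))
  expect_equal(rk$table$summed_rank, c(3, 6, 9))
  # dominance: best in all cases -> summed rank = n_cases
  expect_equal(rk$table$summed_rank[1], ncol(r2))
  # single case: summed rank equals that case's rank
  rk1 <- rank_vis(r2[, 1, drop = FALSE])
  expect_equal(rk1$table$summed_rank, 1:3)
  # exact tie resolved by registry (row) order, deterministically
  r2t <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("X", "Y"), "case1"))
  expect_equal(rank_vis(r2t)$ranks[, 1], c(X = 1L, Y = 2L))
  expect_identical(rank_vis(r2t)$table, rank_vis(r2t)$table)
  expect_error(rank_vis(matrix(c(0.1, NA), 2, 1)), "missing")
})

test_that("row permutation leaves summed ranks unchanged", {
  set.seed(9)
  r2 <- matrix(runif(21 * 8), 21, 8,
               dimnames = list(paste0("vi", 1:21), paste0("case", 1:8)))
  rk <- rank_vis(r2)
  perm <- sample.int(21)
  rk2 <- rank_vis(r2[perm, ])
  m1 <- stats::setNames(rk$table$summed_rank, rk$table$vi)
  m2 <- stats::setNames(rk2$table$summed_rank, rk2$table$vi)
  expect_equal(m1[names(m2)], m2)
})

test_that("adding a duplicate VI only inserts a tie", {
  set.seed(10)
  r2 <- matrix(runif(5 * 3), 5, 3, dimnames = list(paste0("v", 1:5), NULL))
  base <- rank_vis(r2)$table
  r2b <- rbind(r2, dup = r2[3, ])
  aug <- rank_vis(r2b)$table
  ord_base <- setdiff(base$vi, "v3")
  ord_aug <- setdiff(aug$vi, c("v3", "dup"))
  expect_equal(ord_aug, ord_base)
})

test_that("rate of change is baseline-referenced and non-negative", {
  s <- c(`9` = 0.25, `12` = 0.2, `15` = 0.3)
  rc <- rate_of_change(s, "12")
  expect_equal(unname(rc["12"]), 0)
  expect_equal(unname(rc["9"]), 0.25)
  expect_true(all(rc >= 0))
  expect_error(rate_of_change(s, "10"), "reference")
  expect_error(rate_of_change(c(`9` = 1, `12` = 0), "12"), "zero")
})

test_that("red band changes faster with shadow than the NIR band", {
  # diurnal band series of the default crown at fixed biochemistry
  d <- fx_diurnal()
  lo <- prospect5(leaf_biochem(cab = 50, cw = 0.02, cm = 0.01))
  soil <- soil_spectrum()
  brf <- sapply(seq_along(d$hours), function(i) {
    fr <- component_fractions(d$images[[i]], 5)
    sf <- crown_shadow_fraction(d$images[[i]], 5)
    resample_to_bands(400:2500, synthesize_canopy_brf(fr, lo, soil, sf))
  })
  colnames(brf) <- d$hours
  rc_red <- rate_of_change(brf["RED", ], "12")
  rc_nir <- rate_of_change(brf["NIR", ], "12")
  expect_gt(rc_red[["9"]], rc_nir[["9"]])
  # NIR changes are negligible near the reference hour
  expect_lt(max(rc_nir[c("11", "13")]), 0.05)
})

test_that("disturbance sensitivity separates pigment and structure indices", {
  expect_equal(fit_vi_cab_r2(rep(0.4, 50), runif(50, 1, 5)), 0)
  lut <- fx_mini_lut()
  ds <- disturbance_sensitivity(lut)
  expect_gt(ds["DVI", "lai"], ds["NDVI-RE", "lai"])
  expect_gt(ds["NDVI-RE", "cab"], ds["NDVI", "cab"])
  expect_error(disturbance_sensitivity(lut, nuisances = "cm"), "degenerate")
})
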