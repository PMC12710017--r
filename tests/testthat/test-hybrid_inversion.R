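# Dataset splitting, Gaussian-process regression, iterative VI selection,
# trait prediction and accuracy metrics.

test_that("7:3 split is exact, disjoint, exhaustive and seeded", {
  sp <- split_dataset(10, seed = 3)
  expect_length(sp$train, 7)
  expect_length(sp$validation, 3)
  expect_equal(sort(c(sp$train, sp$validation)), 1:10)
  sp2 <- split_dataset(10, seed = 3)
  expect_identical(sp, sp2)
  big <- split_dataset(20160, seed = 1)
  expect_length(big$train, 14112)
  expect_length(big$validation, 6048)
  expect_error(split_dataset(5), "samples")
  expect_error(split_dataset(100, ratio = 1.2), "ratio")
})

test_that("GPR recovers a noiseless linear response", {
  set.seed(4)
  x <- matrix(runif(80, 0, 1), ncol = 1, dimnames = list(NULL, "v"))
  y <- 3 * x[, 1] + 2
  m <- gpr_fit(x[1:60, , drop = FALSE], y[1:60], seed = 1)
  pred <- gpr_predict(m, x[61:80, , drop = FALSE])
  expect_gt(evaluate_accuracy(y[61:80], pred)$r2, 0.99)
  # prediction on training rows interpolates within twice the noise sd
  ptr <- gpr_predict(m, x[1:60, , drop = FALSE], se = TRUE)
  noise_sd <- sqrt(m$sn2) * m$y_sd
  expect_lt(max(abs(ptr$mean - y[1:60])), 2 * max(noise_sd, 1e-3))
  expect_true(all(ptr$sd >= 0))
})

test_that("duplicate rows with equal targets fit via jitter", {
  x <- matrix(rep(c(0.1, 0.5, 0.9), each = 10), ncol = 1)
  y <- rep(c(1, 2, 3), each = 10)
  m <- gpr_fit(x, y, seed = 2)
  expect_true(is.finite(m$nll))
  p <- gpr_predict(m, matrix(0.5))
  expect_equal(p, 2, tolerance = 0.2)
  expect_error(gpr_fit(matrix(NA_real_, 30, 1), rnorm(30)), "finite")
})

test_that("selection stops immediately when one VI carries the signal", {
  set.seed(6)
  n <- 300
  lut <- data.frame(BLUE = runif(n, 0.02, 0.1), GREEN = runif(n, 0.03, 0.15),
                    RED = runif(n, 0.02, 0.15), REDEDGE = runif(n, 0.1, 0.4),
                    NIR = runif(n, 0.3, 0.7))
  vis <- compute_vis(lut)
  lut$cab <- 20 + 10 * vis$DVI            # depends on the first-ranked VI only
  sel <- iterative_vi_selection(c("DVI", "NDVI", "GNDVI"), lut, seed = 1,
                                max_train = 150, n_val = 100)
  expect_length(sel$chosen, 1)
  expect_equal(sel$chosen, "DVI")
  # k_max bound respected
  sel2 <- iterative_vi_selection(c("DVI", "NDVI", "GNDVI"), lut, seed = 1,
                                 k_max = 2, max_train = 150, n_val = 100)
  expect_lte(length(sel2$chosen), 2)
  expect_error(iterative_vi_selection(character(0), lut), "empty")
})

test_that("accuracy metrics follow their definitions", {
  obs <- c(50, 55, 60, 65, 70)
  m <- evaluate_accuracy(obs, obs)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$nrmse, 0)
  # consistency of the headline triple: rmse 6.86 at mean 56.05 -> 12.24%
  set.seed(8)
  o <- rnorm(400, sd = 5)
  o <- o - mean(o) + 56.05
  p <- o + 6.86
  m2 <- evaluate_accuracy(o, p)
  expect_equal(m2$rmse, 6.86, tolerance = 1e-12)
  expect_equal(m2$nrmse, 6.86 / 56.05 * 100, tolerance = 1e-9)
  expect_equal(round(m2$nrmse, 2), 12.24)
  expect_equal(evaluate_accuracy(obs, rep(3, 5))$r2, 0)
  expect_error(evaluate_accuracy(obs, obs[1:3]), "lengths")
  expect_error(evaluate_accuracy(c(-1, 1), c(1, 2)), "zero mean")
})

test_that("trait prediction forms CCC as the exact product", {
  est <- data.frame(tree_id = 1:3, lcc = c(50, 60, 70), lai = c(3, 2, 1))
  est$ccc <- est$lcc * est$lai
  expect_identical(est$ccc[1], 150)
  inv <- fx_inversion()
  expect_identical(inv$unmasked$est$ccc,
                   inv$unmasked$est$lcc * inv$unmasked$est$lai)
  # every tree gets a finite estimate, shaded crowns included (no masking)
  expect_true(all(is.finite(inv$unmasked$est$lcc)))
  expect_true(all(is.finite(inv$unmasked$est$ccc)))
})

test_that("selection, training and prediction are reproducible", {
  lut <- fx_mini_lut()
  rk <- rank_vis(vi_case_r2(lut))
  s1 <- iterative_vi_selection(rk$table$vi, lut, seed = 42, k_max = 2,
                               max_train = 150, n_val = 200)
  s2 <- iterative_vi_selection(rk$table$vi, lut, seed = 42, k_max = 2,
                               max_train = 150, n_val = 200)
  expect_identical(s1$step_rmse, s2$step_rmse)
  expect_identical(s1$chosen, s2$chosen)
})
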