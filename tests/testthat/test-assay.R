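make_plate <- function(cond_vals, ctrl_vals, substrate = 1) {
  rbind(
    data.frame(condition = "FruK", substrate_mM = substrate,
               replicate = seq_along(cond_vals), luminescence = cond_vals),
    data.frame(condition = "buffer", substrate_mM = NA,
               replicate = seq_along(ctrl_vals), luminescence = ctrl_vals))
}

test_that("fold change and its propagated SD match hand calculation", {
  # condition 3000 +/- 300 vs control 1000 +/- 100 -> 3.0 +/- 0.424
  fc <- fold_change(make_plate(c(2700, 3000, 3300), c(900, 1000, 1100)))
  expect_equal(fc$fold, 3.0)
  expect_equal(fc$sd, 3 * sqrt(0.1^2 + 0.1^2), tolerance = 1e-12)
  # identical condition and control values give fold exactly 1
  fc1 <- fold_change(make_plate(c(900, 1000, 1100), c(900, 1000, 1100)))
  expect_equal(fc1$fold, 1.0)
})

test_that("fold change is scale invariant and handles degenerate replicates", {
  a <- fold_change(make_plate(c(2700, 3000, 3300), c(900, 1000, 1100)))
  b <- fold_change(make_plate(17 * c(2700, 3000, 3300), 17 * c(900, 1000, 1100)))
  expect_equal(a$fold, b$fold)
  expect_equal(a$sd, b$sd)
  single <- fold_change(make_plate(3000, 1000))
  expect_equal(single$fold, 3.0)
  expect_true(is.na(single$sd))
  bad <- make_plate(c(1, 2, 3), c(1, 2, 3))
  bad$luminescence[bad$condition == "buffer"] <- c(1, 1, 1)
  bad$luminescence <- bad$luminescence - 10  # nonpositive values
  expect_error(fold_change(bad), "luminescence|control")
})

test_that("independent experiments are averaged with the SD of per-experiment folds", {
  d1 <- make_plate(c(2700, 3000, 3300), c(900, 1000, 1100)); d1$experiment <- "e1"
  d2 <- make_plate(c(3500, 4000, 4500), c(900, 1000, 1100)); d2$experiment <- "e2"
  fc <- fold_change(rbind(d1, d2))
  expect_equal(fc$fold, mean(c(3, 4)))
  expect_equal(fc$sd, stats::sd(c(3, 4)))
  expect_equal(fc$n_experiments, 2L)
})

test_that("ATP calibration inverts exactly on log-log-linear data", {
  conc <- c(0.03, 0.1, 0.3, 1, 4)
  lum <- 5e3 * conc^1.1
  cal <- atp_calibration(conc, lum)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  back <- cal$inverse(lum)
  expect_equal(back$conc_mM, conc, tolerance = 1e-6)
  expect_false(any(back$extrapolated))
  # unit slope: inverse is signal over gain
  cal1 <- atp_calibration(conc, 2e4 * conc)
  expect_equal(cal1$inverse(1e4)$conc_mM, 0.5, tolerance = 1e-9)
  expect_true(cal1$inverse(2e4 * 50)$extrapolated)
  expect_error(atp_calibration(c(1, 2, 3), c(10, 20, 30)), "decade")
})

test_that("noisy calibration recovers concentrations within 15%", {
  set.seed(31)
  conc <- 10^seq(log10(0.03), log10(4), length.out = 8)
  lum <- 1e4 * conc * exp(rnorm(8, 0, 0.1))
  cal <- atp_calibration(conc, lum)
  back <- cal$inverse(1e4 * conc)
  expect_true(all(abs(back$conc_mM - conc) / conc < 0.15))
})

test_that("concentration trend flags monotone responses and their direction", {
  s <- c(0.1, 0.5, 1, 2, 5, 10, 15)
  up <- concentration_trend(s, c(1, 1.2, 1.5, 1.9, 2.4, 2.8, 3), n_perm = 2000, seed = 4)
  expect_equal(up$rho, 1)
  expect_lt(up$p_one_sided, 0.01)
  expect_true(up$monotone_increase)
  down <- concentration_trend(s, rev(c(1, 1.2, 1.5, 1.9, 2.4, 2.8, 3)),
                              n_perm = 2000, seed = 4)
  expect_equal(down$rho, -1)
  expect_false(down$monotone_increase)
  flat <- concentration_trend(s, rep(2, 7), n_perm = 100, seed = 1)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$rho))
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(55)
  p <- vapply(1:200, function(i) {
    concentration_trend(1:8, rnorm(8), n_perm = 400, seed = i)$p_two_sided
  }, numeric(1))
  rejections <- mean(p <= 0.05)
  ci <- stats::qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})

test_that("half-max timing is exact on a noiseless logistic and equivariant", {
  t <- seq(0, 22, 0.5)
  od <- 1 / (1 + exp(-0.8 * (t - 5)))
  m <- half_max_time(t, od)
  expect_true(m$reached)
  expect_equal(m$t_half, 5, tolerance = 0.26)
  # +2 h time shift moves t1/2 by exactly +2 h
  m2 <- half_max_time(t + 2, od)
  expect_equal(m2$t_half - m$t_half, 2)
  # OD rescaling leaves t1/2 unchanged
  m3 <- half_max_time(t, 0.37 * od)
  expect_equal(m3$t_half, m$t_half)
})

test_that("unreachable half-max is flagged and propagates through delays", {
  t <- seq(0, 4, 0.5)
  od <- c(0.05, 0.06, 0.07, 0.08, 0.09, 0.1, 0.11, 0.12, 0.12)
  # against a known plateau of 1.0 the series never reaches half-max
  m <- half_max_time(t, od, capacity = 1.0)
  expect_false(m$reached)
  expect_true(is.na(m$t_half))
  ok <- half_max_time(t, od)  # relative to its own maximum it does
  expect_true(ok$reached)
  expect_true(is.na(growth_delay(ok, m)))
  expect_error(half_max_time(t, rep(0, 9)), "od600")
})

test_that("growth delay is a signed difference of half-max times", {
  g1 <- simulate_growth(midpoint_h = 5, noise_sd = 0, seed = 1)
  g2 <- simulate_growth(midpoint_h = 8.4, noise_sd = 0, seed = 1)
  m1 <- half_max_time(g1$data$time_h, g1$data$od600)
  m2 <- half_max_time(g2$data$time_h, g2$data$od600)
  expect_equal(growth_delay(m2, m1), 3.4, tolerance = 0.25)
  expect_equal(growth_delay(m1, m1), 0)
  expect_equal(growth_delay(m1, m2), -growth_delay(m2, m1))
})
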