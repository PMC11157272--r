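make_hyperbolic_curve <- function(kd, X = seq(-10, -6, length.out = 12),
                                  c = 0.1, ymax = 1, id = "c1") {
  data.frame(curve_id = id, conc_M = 10^X,
             signal = hyperbolic_signal(10^X, kd, c = c, ymax = ymax))
}

test_that("noiseless hyperbolic data are recovered to 0.1%", {
  kd <- 1e-8
  fit <- fit_titration(make_hyperbolic_curve(kd), model = "hyperbolic")
  expect_true(fit$converged)
  expect_lt(abs(fit$kd - kd) / kd, 1e-3)
  expect_equal(unname(coef(fit)["c.c1"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["ymax.c1"]), 1, tolerance = 1e-6)
})

test_that("a constant-signal curve raises the non-identifiability flag", {
  d <- data.frame(curve_id = "flat", conc_M = 10^seq(-10, -7, length.out = 6),
                  signal = rep(0.5, 6))
  fit <- fit_titration(d, model = "hyperbolic")
  expect_true(fit$curves$nonidentifiable[1])
})

test_that("fitting depleted data with the hyperbolic model biases Kd upward", {
  kd <- 2e-9
  dt <- 10 * kd
  conc <- 10^seq(-10.5, -7, length.out = 14)
  d <- data.frame(curve_id = "dep", conc_M = conc,
                  signal = quadratic_signal(conc, kd, dt, c = 0.05, ymax = 1))
  fit <- fit_titration(d, model = "hyperbolic")
  expect_gt(fit$kd, kd * 1.5)
  # the fit sits at the minimum of an independent grid scan of the same model
  grid <- seq(-10, -7, by = 0.002)
  rss <- vapply(grid, function(lkd) {
    sum(stats::resid(stats::lm(d$signal ~ I(conc / (10^lkd + conc))))^2)
  }, numeric(1))
  expect_equal(log10(fit$kd), grid[which.min(rss)], tolerance = 0.005)
  expect_gt(grid[which.min(rss)], log10(kd))
})

test_that("the global optimum matches a profile-RSS grid scan on noiseless curves", {
  sim <- simulate_titration(kd = 2e-9, n_curves = 3, noise_sd = 0, seed = 21)
  fit <- fit_titration(sim)
  expect_true(fit$converged)
  expect_equal(fit$kd, 2e-9, tolerance = 1e-4)
  grid <- seq(log10(2e-9) - 0.05, log10(2e-9) + 0.05, by = 0.001)
  rss <- profile_rss_scan(sim$data, grid)
  expect_equal(grid[which.min(rss)], log10(fit$kd), tolerance = 0.0011)
})

test_that("a duplicated single curve pools to the single-curve Kd", {
  sim <- simulate_titration(kd = 3e-9, n_curves = 1, noise_sd = 0.02, seed = 9)
  single <- fit_titration(sim)
  dup <- sim$data
  dup2 <- dup; dup2$curve_id <- "copy"
  glob <- fit_titration(rbind(dup, dup2))
  expect_equal(glob$kd, single$kd, tolerance = 1e-5)
})

test_that("sharing Kd never beats per-curve fits constrained to the same Kd", {
  sim <- simulate_titration(kd = 2e-9, n_curves = 4, noise_sd = 0.03, seed = 5)
  glob <- fit_titration(sim)
  per_curve_rss <- sum(vapply(split(sim$data, sim$data$curve_id), function(d) {
    fit_titration(d, kd = glob$kd)$rss
  }, numeric(1)))
  expect_lte(glob$rss, per_curve_rss + 1e-10)
})

test_that("median Kd recovery bias is below 5% at study conditions", {
  bias <- vapply(1:7, function(s) {
    sim <- simulate_titration(kd = 2e-9, n_curves = 10,
                              dt_range = c(0.5e-9, 5e-9), noise_sd = 0.02,
                              seed = 100 + s)
    fit <- fit_titration(sim)
    (fit$kd - 2e-9) / 2e-9
  }, numeric(1))
  expect_lt(abs(stats::median(bias)), 0.05)
})

test_that("fit methods are mutually consistent", {
  sim <- simulate_titration(kd = 2e-9, n_curves = 2, noise_sd = 0.02, seed = 3)
  fit <- fit_titration(sim)
  y <- unlist(lapply(split(sim$data, sim$data$curve_id), `[[`, "signal"),
              use.names = FALSE)
  expect_equal(fitted(fit) + residuals(fit), y)
  # predict on the training grid reproduces fitted values
  nd <- do.call(rbind, lapply(split(sim$data, sim$data$curve_id), function(d) d))
  expect_equal(predict(fit, nd[, c("curve_id", "conc_M")]), fitted(fit))
  # manual model evaluation agrees with predict
  p1 <- predict(fit, data.frame(curve_id = fit$curves$curve_id[1], conc_M = 1e-9))
  tab <- fit$curves[1, ]
  expect_equal(p1, tab$c + tab$ymax *
                 (quadratic_signal(1e-9, fit$kd, tab$dt)), tolerance = 1e-12)
  expect_output(print(fit), "shared Kd")
  expect_output(print(summary(fit)), "curve_id")
})

test_that("wald and bootstrap intervals behave sensibly", {
  sim0 <- simulate_titration(kd = 2e-9, n_curves = 3, noise_sd = 0, seed = 2)
  fit0 <- fit_titration(sim0)
  ci0 <- confint(fit0, method = "bootstrap", n_boot = 60, seed = 1)
  expect_lt(diff(as.vector(ci0)) / fit0$kd, 1e-4)  # noiseless: width ~ 0

  sim <- simulate_titration(kd = 2e-9, n_curves = 5, noise_sd = 0.02, seed = 8)
  fit <- fit_titration(sim)
  ci_a <- confint(fit, method = "bootstrap", n_boot = 60, seed = 7)
  ci_b <- confint(fit, method = "bootstrap", n_boot = 60, seed = 7)
  expect_identical(as.vector(ci_a), as.vector(ci_b))  # seeded reproducibility
  expect_lt(ci_a[1], fit$kd)
  expect_gt(ci_a[2], fit$kd)
  expect_warning(confint(fit, method = "bootstrap", n_boot = 20, seed = 1),
                 "n_boot")
})
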