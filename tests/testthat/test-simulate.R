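test_that("titration generator honours the depletion model exactly when noiseless", {
  kd <- 2e-9
  sim <- simulate_titration(kd = kd, n_curves = 1, dt_range = c(kd, kd),
                            conc = c(0, kd, 10 * kd), noise_sd = 0, seed = 1)
  tr <- sim$truth
  # zero titrant: signal equals the baseline exactly
  expect_equal(sim$data$signal[1], tr$c[1])
  # L = DT = Kd: closed-form bound fraction (3 - sqrt(5))/2
  expect_equal(sim$data$signal[2], tr$c[1] + tr$ymax[1] * (3 - sqrt(5)) / 2)
})

test_that("generators are reproducible under a fixed seed", {
  expect_identical(simulate_titration(seed = 42)$data,
                   simulate_titration(seed = 42)$data)
  expect_identical(simulate_afm_peaks(seed = 42)$peaks,
                   simulate_afm_peaks(seed = 42)$peaks)
  expect_identical(simulate_growth(seed = 42)$data,
                   simulate_growth(seed = 42)$data)
  expect_identical(simulate_plate(seed = 42)$data,
                   simulate_plate(seed = 42)$data)
  # different seeds differ
  expect_false(identical(simulate_titration(seed = 1)$data$signal,
                         simulate_titration(seed = 2)$data$signal))
})

test_that("generator specs are validated with field-naming errors", {
  expect_error(simulate_titration(kd = 0), "kd")
  expect_error(simulate_titration(conc = c(1e-8, 1e-9)), "conc")
  expect_error(simulate_titration(noise_sd = -0.1), "noise_sd")
  expect_error(simulate_afm_peaks(fractions = c(0.5, 0.2), masses = c(1e5, 2e5)),
               "fractions")
  expect_error(simulate_growth(horizon_h = 0.1, interval_h = 0.5), "horizon")
  expect_error(simulate_plate(control_mean = -5), "control_mean")
})

test_that("noiseless AFM peaks round-trip to their true masses", {
  sim <- simulate_afm_peaks(n = 30, noise_frac = 0, dna_bound_frac = 0.5, seed = 7)
  masses <- afm_mass_table(sim$peaks)
  expect_equal(masses$mass_da, sim$truth$true_mass_da, tolerance = 1e-9)
})

test_that("two well-separated AFM populations are recovered by 2-class clustering", {
  sim <- simulate_afm_peaks(masses = c(75998, 219508), fractions = c(0.6, 0.4),
                            n = 80, noise_frac = 0.05, dna_bound_frac = 0,
                            seed = 11)
  masses <- afm_mass_table(sim$peaks)
  cl <- cluster1d(masses$mass_da, k = 2)
  # class sizes must match the exact component counts of the simulation
  truth_counts <- as.vector(table(sim$truth$component))
  expect_equal(as.vector(cl$sizes), truth_counts)
  expect_equal(cl$assignments, sim$truth$component)
})

test_that("DNA-free simulations leave the DNA columns unpopulated", {
  sim <- simulate_afm_peaks(n = 20, dna_bound_frac = 0, seed = 3)
  expect_true(all(is.na(sim$peaks$h_dna_nm)))
  expect_true(all(is.na(sim$peaks$w_dna_nm)))
  expect_false(any(sim$peaks$dna_bound))
})

test_that("growth generator midpoint is recovered by the half-max estimator", {
  g <- simulate_growth(midpoint_h = 5, noise_sd = 0, seed = 1)
  m <- half_max_time(g$data$time_h, g$data$od600)
  expect_true(m$reached)
  expect_equal(m$t_half, 5, tolerance = 0.26)  # within one interpolation step
})

test_that("plate generator with unit fold function centres fold estimates on 1", {
  pl <- simulate_plate(fold_fn = function(s) 1, n_replicates = 10, seed = 13)
  fc <- fold_change(pl$data)
  expect_true(all(abs(fc$fold - 1) < 3 * fc$sd / sqrt(fc$n_replicates) + 0.15))
  expect_lt(abs(mean(fc$fold) - 1), 0.1)
})

test_that("a 3x fold at 10% noise is recovered within the ratio-of-means spread", {
  pl <- simulate_plate(fold_fn = function(s) 3, n_replicates = 3,
                       control_sd = 100, control_mean = 1000, seed = 17)
  fc <- fold_change(pl$data)
  # Monte-Carlo oracle for the SD of a ratio of replicate means
  set.seed(99)
  ratios <- vapply(1:4000, function(i) {
    mean(rnorm(3, 3000, 300)) / mean(rnorm(3, 1000, 100))
  }, numeric(1))
  expect_true(all(abs(fc$fold - 3) < 4 * stats::sd(ratios)))
  expect_lt(abs(mean(fc$fold) - 3), 3 * stats::sd(ratios) / sqrt(nrow(fc)) + 0.1)
})
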