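test_that("DP clustering reproduces hand-checked partitions", {
  cl <- cluster1d(c(1, 2, 3, 10, 11, 12), k = 2)
  expect_equal(cl$centers, c(2, 11))
  expect_equal(cl$tot_withinss, 4.0)
  expect_equal(as.vector(cl$sizes), c(3L, 3L))
  # fixing the top class pins the largest observations
  cl3 <- cluster1d(c(1, 2, 3, 10, 11, 12, 100), k = 3, fixed_top_class_size = 1)
  expect_equal(cl3$centers, c(2, 11, 100))
  bf <- brute_force_cluster(c(1, 2, 3, 10, 11, 12, 100), 3, fixed_top_class_size = 1)
  expect_equal(cl3$tot_withinss, bf$wcss)
})

test_that("k = n gives singleton classes with zero WCSS", {
  x <- c(4, 1, 9, 2)
  cl <- cluster1d(x, k = 4)
  expect_equal(cl$tot_withinss, 0)
  expect_equal(as.vector(cl$sizes), rep(1L, 4))
})

test_that("DP equals exhaustive enumeration, with and without the top-class constraint", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:15, 1)
    k <- sample(1:min(4, n), 1)
    x <- round(runif(n, 0, 100), 2)
    expect_equal(cluster1d(x, k)$tot_withinss,
                 brute_force_cluster(x, k)$wcss, tolerance = 1e-9)
    if (k >= 2) {
      t <- sample(seq_len(n - k + 1), 1)
      expect_equal(cluster1d(x, k, fixed_top_class_size = t)$tot_withinss,
                   brute_force_cluster(x, k, fixed_top_class_size = t)$wcss,
                   tolerance = 1e-9)
    }
  }
})

test_that("WCSS is non-increasing in k and invariant to input order", {
  set.seed(11)
  x <- c(rnorm(20, 70000, 4000), rnorm(15, 140000, 6000), rnorm(7, 220000, 8000))
  wcss <- vapply(1:5, function(k) cluster1d(x, k)$tot_withinss, numeric(1))
  expect_true(all(diff(wcss) <= 1e-9))
  perm <- sample(length(x))
  cl_a <- cluster1d(x, 3)
  cl_b <- cluster1d(x[perm], 3)
  expect_equal(cl_a$centers, cl_b$centers)
  expect_equal(cl_a$assignments[perm], cl_b$assignments)
})

test_that("BIC model selection finds well-separated populations and single ones", {
  set.seed(23)
  x2 <- c(rnorm(30, 0, 1), rnorm(30, 8, 1))  # separation 8 SD
  expect_equal(choose_k(x2, 1:4)$k, 2)
  x1 <- rnorm(40)
  expect_equal(choose_k(x1, 1:4)$k, 1)
  expect_identical(choose_k(x2, 1:4)$table, choose_k(x2, 1:4)$table)
  expect_error(choose_k(x1, integer()), "k_range")
})

test_that("class means map to ladder entries with the ambiguity rule", {
  lad <- reference_ladder()
  fake <- function(mean) {
    structure(list(k = 1L, assignments = 1L, centers = mean, sizes = 1L,
                   sds = NA_real_, withinss = 0, tot_withinss = 0,
                   constraint = "none"), class = "cluster1d")
  }
  a <- assign_stoichiometry(fake(76000), lad)
  expect_equal(a$label, "Cra homodimer")
  expect_equal(a$residual_da, 2)
  expect_false(a$ambiguous)
  # midway between the two homodimers: both (dimer)1 labels reported
  b <- assign_stoichiometry(fake(71700), lad)
  expect_true(b$ambiguous)
  expect_match(b$label, "FruK homodimer")
  expect_match(b$label, "Cra homodimer")
  d <- assign_stoichiometry(fake(219000), lad)
  expect_equal(d$tier, 3L)
  expect_equal(d$residual_da, 508)
})

test_that("synthetic ladder populations are recovered end-to-end across seeds", {
  # per-dimension noise of 0.058 gives ~10% CV on the reconstructed mass
  ok <- vapply(1:20, function(s) {
    sim <- simulate_afm_peaks(n = 60, noise_frac = 0.058, dna_bound_frac = 0.5,
                              seed = 3000 + s)
    masses <- afm_mass_table(sim$peaks)
    cl <- cluster1d(masses$mass_da, k = 3)
    calls <- assign_stoichiometry(cl)
    se <- ifelse(is.na(cl$sds), Inf, cl$sds / sqrt(cl$sizes))
    identical(calls$tier, c(1L, 2L, 3L)) &&
      all(abs(cl$centers - c(75998, 143510, 219508)) < 3 * se)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
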