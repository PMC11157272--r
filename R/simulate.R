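# Seeded synthetic-data generators for every input kind the pipeline reads.
# One top-level seed; each generator draws from its own substream (fixed
# offset) so adding one generator never reshuffles the draws of another.

#' Simulate equilibrium titration curves with ligand depletion
#'
#' Generates plateau titration curves from the quadratic depletion model: a
#' single true Kd shared by all curves, with per-curve baseline, amplitude
#' and fixed-component concentration DT drawn from the stated ranges, plus
#' i.i.d. Gaussian noise expressed as a fraction of each curve's amplitude.
#' The defaults emulate a BLI experiment in the intermediate binding regime:
#' Kd = 2e-9 M, ten curves, effective immobilized-DNA concentrations spanning
#' 0.5-5 nM, 2% noise.
#'
#' @param kd true shared dissociation constant, M (> 0).
#' @param n_curves number of curves.
#' @param dt_range min/max of the per-curve fixed-component concentration, M;
#'   DT is drawn log-uniformly.
#' @param conc titrant concentration grid, M, sorted, >= 0 (zero allowed as a
#'   baseline point). Default: 12 log-spaced points over 10^-10.5..10^-7.5 M.
#' @param baseline_range,ymax_range uniform ranges for the per-curve baseline
#'   `c` and amplitude `Ymax` (signal units).
#' @param noise_sd additive Gaussian noise SD as a fraction of each curve's
#'   `Ymax` (default 0.02).
#' @param n complex stoichiometry (default 1).
#' @param seed integer seed.
#' @return object of class `"titration_sim"`: list with `data` (columns
#'   `curve_id`, `conc_M`, `signal`) and `truth` (per-curve `c`, `ymax`, `dt`
#'   plus the shared `kd`, `n`, `noise_sd`).
#' @examples
#' sim <- simulate_titration(seed = 7)
#' head(sim$data)
#' @export
simulate_titration <- function(kd = 2e-9, n_curves = 10,
                               dt_range = c(0.5e-9, 5e-9),
                               conc = 10^seq(-10.5, -7.5, length.out = 12),
                               baseline_range = c(0.02, 0.2),
                               ymax_range = c(0.8, 1.2),
                               noise_sd = 0.02, n = 1, seed = 1) {
  check_positive(kd, "kd")
  n_curves <- check_count(n_curves, "n_curves")
  check_positive(dt_range, "dt_range")
  if (length(dt_range) != 2L || dt_range[1] > dt_range[2]) {
    stop_field("dt_range", "must be c(min, max) with min <= max")
  }
  check_nonneg(conc, "conc")
  if (is.unsorted(conc)) stop_field("conc", "must be sorted increasing")
  check_nonneg(noise_sd, "noise_sd")
  check_positive(n, "n")
  seed <- check_seed(seed)
  set.seed(substream_seed(seed, 101L))

  dts <- exp(stats::runif(n_curves, log(dt_range[1]), log(dt_range[2])))
  cs <- stats::runif(n_curves, baseline_range[1], baseline_range[2])
  ymaxs <- stats::runif(n_curves, ymax_range[1], ymax_range[2])
  ids <- sprintf("curve_%02d", seq_len(n_curves))

  data <- do.call(rbind, lapply(seq_len(n_curves), function(j) {
    mu <- quadratic_signal(conc, kd = kd, dt = dts[j], c = cs[j],
                           ymax = ymaxs[j], n = n)
    data.frame(curve_id = ids[j], conc_M = conc,
               signal = mu + stats::rnorm(length(conc), 0, noise_sd * ymaxs[j]),
               stringsAsFactors = FALSE)
  }))
  truth <- data.frame(curve_id = ids, c = cs, ymax = ymaxs, dt = dts,
                      kd = kd, n = n, noise_sd = noise_sd,
                      stringsAsFactors = FALSE)
  structure(list(data = data, truth = truth, seed = seed),
            class = "titration_sim")
}

#' Simulate AFM peak measurements at known masses
#'
#' Draws particles from a mixture of populations at stated true masses. Each
#' particle's true protein volume follows from its mass via the specific
#' volume; for DNA-bound particles a cylindrical-segment DNA volume is added
#' to the deposited complex volume. The total volume is decomposed into a
#' height and two half-height widths consistent with the elliptic-cylinder
#' geometry under a lognormal height/aspect model, then fractional Gaussian
#' measurement noise is applied per dimension. With zero noise, running the
#' analysis chain ([afm_mass_table()]) returns every particle's true mass
#' exactly.
#'
#' @param masses true population masses, Da.
#' @param fractions mixing fractions (must sum to 1). Defaults place 45/40/15%
#'   of particles at the (dimer)1/(dimer)2/(dimer)3 ladder masses.
#' @param n number of particles.
#' @param specific_volume ml/g used for the mass-to-volume conversion.
#' @param height_meanlog,height_sdlog lognormal parameters of the peak height
#'   (nm); default median 2 nm.
#' @param aspect_meanlog,aspect_sdlog lognormal parameters of the long/orth
#'   width ratio; default median 1.3.
#' @param noise_frac fractional Gaussian measurement SD per dimension.
#' @param dna_bound_frac fraction of particles deposited on DNA.
#' @param dna_height,dna_width median adjacent-DNA height and width (nm).
#' @param dna_sdlog lognormal spread of the DNA geometry.
#' @param seed integer seed.
#' @return object of class `"afm_sim"`: list with `peaks` (the measurement
#'   table read by [afm_mass_table()]) and `truth` (`peak_id`, `component`,
#'   `true_mass_da`, `dna_bound`).
#' @examples
#' sim <- simulate_afm_peaks(n = 20, noise_frac = 0, seed = 3)
#' range(afm_mass_table(sim$peaks)$mass_da - sim$truth$true_mass_da)
#' @export
simulate_afm_peaks <- function(masses = c(75998, 143510, 219508),
                               fractions = c(0.45, 0.40, 0.15),
                               n = 60, specific_volume = 0.67,
                               height_meanlog = log(2), height_sdlog = 0.15,
                               aspect_meanlog = log(1.3), aspect_sdlog = 0.1,
                               noise_frac = 0.05, dna_bound_frac = 0.5,
                               dna_height = 0.5, dna_width = 6,
                               dna_sdlog = 0.15, seed = 1) {
  check_positive(masses, "masses")
  check_nonneg(fractions, "fractions")
  if (length(fractions) != length(masses)) {
    stop_field("fractions", "must match length of masses")
  }
  if (abs(sum(fractions) - 1) > 1e-8) stop_field("fractions", "must sum to 1")
  n <- check_count(n, "n")
  check_positive(specific_volume, "specific_volume")
  check_nonneg(noise_frac, "noise_frac")
  if (dna_bound_frac < 0 || dna_bound_frac > 1) {
    stop_field("dna_bound_frac", "must be in [0, 1]")
  }
  check_positive(c(dna_height, dna_width), "dna geometry")
  seed <- check_seed(seed)
  set.seed(substream_seed(seed, 202L))

  comp <- sample.int(length(masses), n, replace = TRUE, prob = fractions)
  true_mass <- masses[comp]
  v_prot <- mw_to_volume(true_mass, specific_volume)
  bound <- stats::runif(n) < dna_bound_frac

  h_dna <- w_dna <- rep(NA_real_, n)
  v_dna <- rep(0, n)
  if (any(bound)) {
    h_dna[bound] <- stats::rlnorm(sum(bound), log(dna_height), dna_sdlog)
    w_dna[bound] <- stats::rlnorm(sum(bound), log(dna_width), dna_sdlog)
    v_dna[bound] <- (2 / 3) * h_dna[bound] * w_dna[bound]^2
  }
  v_tot <- v_prot + v_dna

  h <- stats::rlnorm(n, height_meanlog, height_sdlog)
  aspect <- stats::rlnorm(n, aspect_meanlog, aspect_sdlog)
  w_orth <- sqrt(4 * v_tot / (pi * h * aspect))
  w_long <- aspect * w_orth

  jitter <- function(x) x * (1 + stats::rnorm(length(x), 0, noise_frac))
  peaks <- data.frame(
    peak_id = sprintf("peak_%03d", seq_len(n)),
    h_nm = jitter(h), w_long_nm = jitter(w_long), w_orth_nm = jitter(w_orth),
    dna_bound = bound,
    h_dna_nm = ifelse(bound, jitter(h_dna), NA_real_),
    w_dna_nm = ifelse(bound, jitter(w_dna), NA_real_),
    stringsAsFactors = FALSE)
  truth <- data.frame(peak_id = peaks$peak_id, component = comp,
                      true_mass_da = true_mass, dna_bound = bound,
                      stringsAsFactors = FALSE)
  structure(list(peaks = peaks, truth = truth, seed = seed,
                 specific_volume = specific_volume), class = "afm_sim")
}

#' Simulate a logistic growth curve
#'
#' Symmetric logistic OD curve sampled on a regular grid with additive
#' Gaussian noise (clamped at zero): defaults emulate an overnight
#' plate-reader run, OD measured every 30 min for 22 h.
#'
#' @param capacity carrying capacity, OD units.
#' @param rate logistic growth rate, 1/h (> 0).
#' @param midpoint_h inflection (half-capacity) time, h.
#' @param interval_h sampling interval, h (default 0.5).
#' @param horizon_h total duration, h; must exceed `midpoint_h` and allow at
#'   least one interval.
#' @param noise_sd additive OD noise SD (default 0.01).
#' @param seed integer seed.
#' @param strain strain label carried into the series.
#' @return object of class `"growth_sim"`: list with `data` (`strain`,
#'   `time_h`, `od600`, `replicate`) and `truth` (`capacity`, `rate`,
#'   `midpoint_h`).
#' @examples
#' g <- simulate_growth(midpoint_h = 6, seed = 2)
#' half_max_time(g$data$time_h, g$data$od600)
#' @export
simulate_growth <- function(capacity = 1.0, rate = 0.8, midpoint_h = 5,
                            interval_h = 0.5, horizon_h = 22,
                            noise_sd = 0.01, seed = 1, strain = "strain") {
  check_positive(capacity, "capacity")
  check_positive(rate, "rate")
  check_positive(interval_h, "interval_h")
  if (horizon_h < interval_h) stop_field("horizon_h", "shorter than one sampling interval")
  if (horizon_h <= midpoint_h) stop_field("horizon_h", "must exceed midpoint_h")
  check_nonneg(noise_sd, "noise_sd")
  seed <- check_seed(seed)
  set.seed(substream_seed(seed, 303L))

  t <- seq(0, horizon_h, by = interval_h)
  mu <- capacity / (1 + exp(-rate * (t - midpoint_h)))
  od <- pmax(0, mu + stats::rnorm(length(t), 0, noise_sd))
  structure(list(
    data = data.frame(strain = strain, time_h = t, od600 = od, replicate = 1L,
                      stringsAsFactors = FALSE),
    truth = list(capacity = capacity, rate = rate, midpoint_h = midpoint_h),
    seed = seed), class = "growth_sim")
}

#' Simulate a luciferase plate with buffer controls and ATP standards
#'
#' Replicate luminescence values per substrate level are drawn around
#' `fold_fn(substrate) * control_mean` with the control's coefficient of
#' variation; buffer-only controls are drawn around `control_mean` with
#' `control_sd`. ATP calibration rows follow a power-law response over the
#' standard range. Defaults emulate a triplicate assay across the
#' physiological substrate range 0.1-15 mM with ATP standards 0.03-4 mM.
#'
#' @param substrate_mM substrate levels, mM.
#' @param n_replicates technical replicates per level (>= 1).
#' @param fold_fn true fold-increase as a function of substrate (mM);
#'   default a saturating response rising from 1.
#' @param control_mean,control_sd buffer-only control mean and SD
#'   (luminescence units; mean must be > 0).
#' @param condition label for the enzyme-containing wells.
#' @param atp_conc_mM ATP standard concentrations, mM.
#' @param atp_gain,atp_slope power-law calibration `gain * conc^slope`.
#' @param atp_noise_frac fractional noise on the standards.
#' @param seed integer seed.
#' @return object of class `"plate_sim"`: list with `data` (rows for the
#'   condition and the `"buffer"` control, read by [fold_change()]), `atp`
#'   (`conc_mM`, `luminescence`) and `truth` (true folds per level and the
#'   calibration parameters).
#' @examples
#' pl <- simulate_plate(seed = 5)
#' fold_change(pl$data)
#' @export
simulate_plate <- function(substrate_mM = c(0.1, 0.5, 1, 2, 5, 10, 15),
                           n_replicates = 3,
                           fold_fn = function(s) 1 + 2 * s / (s + 2),
                           control_mean = 1000, control_sd = 100,
                           condition = "FruK",
                           atp_conc_mM = c(0.03, 0.1, 0.3, 1, 4),
                           atp_gain = 1e4, atp_slope = 1,
                           atp_noise_frac = 0.05, seed = 1) {
  check_positive(substrate_mM, "substrate_mM")
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_positive(control_mean, "control_mean")
  check_nonneg(control_sd, "control_sd")
  check_positive(atp_conc_mM, "atp_conc_mM")
  seed <- check_seed(seed)
  set.seed(substream_seed(seed, 404L))

  folds <- vapply(substrate_mM, fold_fn, numeric(1))
  check_positive(folds, "fold_fn output")
  cv <- control_sd / control_mean
  cond_rows <- do.call(rbind, lapply(seq_along(substrate_mM), function(i) {
    mu <- folds[i] * control_mean
    data.frame(condition = condition, substrate_mM = substrate_mM[i],
               replicate = seq_len(n_replicates),
               luminescence = stats::rnorm(n_replicates, mu, cv * mu),
               stringsAsFactors = FALSE)
  }))
  ctrl_rows <- data.frame(condition = "buffer", substrate_mM = NA_real_,
                          replicate = seq_len(n_replicates),
                          luminescence = stats::rnorm(n_replicates, control_mean, control_sd),
                          stringsAsFactors = FALSE)
  atp <- data.frame(conc_mM = atp_conc_mM,
                    luminescence = atp_gain * atp_conc_mM^atp_slope *
                      (1 + stats::rnorm(length(atp_conc_mM), 0, atp_noise_frac)))
  structure(list(data = rbind(cond_rows, ctrl_rows), atp = atp,
                 truth = list(substrate_mM = substrate_mM, fold = folds,
                              control_mean = control_mean, control_sd = control_sd,
                              atp_gain = atp_gain, atp_slope = atp_slope),
                 seed = seed), class = "plate_sim")
}
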