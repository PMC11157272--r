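#' Fold change of luminescence over buffer-only controls
#'
#' For each substrate level, the fold increase is the ratio of the mean
#' condition luminescence to the mean of the buffer-only controls, with the
#' SD propagated to first order:
#' \deqn{sd = fold \sqrt{(sd_c/\bar y_c)^2 + (sd_0/\bar y_0)^2}.}
#' When an `experiment` column is present, folds are computed per independent
#' experiment against that experiment's own controls and the reported value
#' is the mean across experiments with the SD of the per-experiment folds.
#'
#' @param data `data.frame` with columns `condition`, `substrate_mM`,
#'   `replicate`, `luminescence`; optional `experiment`. Control rows carry
#'   `condition == control`.
#' @param control label of the buffer-only control rows (default `"buffer"`).
#' @return `data.frame` with one row per substrate level: `substrate_mM`,
#'   `fold`, `sd` (`NA` with a single replicate and a single experiment),
#'   `n_replicates`, `n_experiments`.
#' @examples
#' pl <- simulate_plate(seed = 1)
#' fold_change(pl$data)
#' @export
fold_change <- function(data, control = "buffer") {
  req <- c("condition", "substrate_mM", "replicate", "luminescence")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop_field("data", paste("missing column(s):", paste(miss, collapse = ", ")))
  if (!"experiment" %in% names(data)) data$experiment <- 1L
  ctrl <- data[data$condition == control, , drop = FALSE]
  cond <- data[data$condition != control, , drop = FALSE]
  if (!nrow(ctrl)) stop_field("data", "no buffer-control rows found")
  exps <- unique(data$experiment)
  levels_mM <- sort(unique(cond$substrate_mM))
  per <- lapply(exps, function(e) {
    c0 <- ctrl$luminescence[ctrl$experiment == e]
    if (!length(c0)) stop_field("data", sprintf("experiment '%s' lacks controls", e))
    m0 <- mean(c0)
    if (m0 <= 0) stop_field("data", "control mean must be > 0")
    s0 <- if (length(c0) > 1) stats::sd(c0) else NA_real_
    do.call(rbind, lapply(levels_mM, function(s) {
      y <- cond$luminescence[cond$experiment == e & cond$substrate_mM == s]
      if (!length(y)) return(NULL)
      m <- mean(y); sdev <- if (length(y) > 1) stats::sd(y) else NA_real_
      fold <- m / m0
      # first-order propagation on the replicate SDs (not SEs), per convention
      prop_sd <- if (is.na(sdev) || is.na(s0)) NA_real_ else
        fold * sqrt((sdev / m)^2 + (s0 / m0)^2)
      data.frame(experiment = e, substrate_mM = s, fold = fold, sd = prop_sd,
                 n_replicates = length(y))
    }))
  })
  per <- do.call(rbind, per)
  out <- do.call(rbind, lapply(levels_mM, function(s) {
    d <- per[per$substrate_mM == s, , drop = FALSE]
    if (nrow(d) > 1L) {
      data.frame(substrate_mM = s, fold = mean(d$fold), sd = stats::sd(d$fold),
                 n_replicates = sum(d$n_replicates), n_experiments = nrow(d))
    } else {
      data.frame(substrate_mM = s, fold = d$fold, sd = d$sd,
                 n_replicates = d$n_replicates, n_experiments = 1L)
    }
  }))
  rownames(out) <- NULL
  out
}

#' ATP calibration of a luminescence readout
#'
#' Fits a log-log linear calibration `log10(signal) ~ log10(conc)` to ATP
#' standards and returns an invertible calibration object. The inverse maps
#' luminescence back to apparent ATP concentration; values outside the
#' calibrated concentration range are flagged as extrapolations.
#'
#' @param conc_mM standard concentrations, mM (> 0, at least 3 points
#'   spanning at least one decade).
#' @param luminescence measured signals (> 0).
#' @return object of class `"atp_calibration"`: list with `intercept`,
#'   `slope`, `r_squared`, `range_mM`, and function `inverse(signal)`
#'   returning a `data.frame` with `conc_mM` and `extrapolated`.
#' @examples
#' cal <- atp_calibration(c(0.03, 0.1, 0.5, 1, 4), 1e4 * c(0.03, 0.1, 0.5, 1, 4))
#' cal$inverse(5e3)
#' @export
atp_calibration <- function(conc_mM, luminescence) {
  check_positive(conc_mM, "conc_mM")
  check_positive(luminescence, "luminescence")
  if (length(conc_mM) < 3L || length(conc_mM) != length(luminescence)) {
    stop_field("conc_mM", "need >= 3 matched calibration points")
  }
  if (max(conc_mM) / min(conc_mM) < 10) {
    stop_field("conc_mM", "calibration must span at least one decade")
  }
  fit <- stats::lm(log10(luminescence) ~ log10(conc_mM))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  ly <- log10(luminescence)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((ly - mean(ly))^2)
  rng <- range(conc_mM)
  inverse <- function(signal) {
    check_positive(signal, "signal")
    conc <- 10^((log10(signal) - a) / b)
    eps <- 1e-8 * diff(rng)
    data.frame(conc_mM = conc,
               extrapolated = conc < rng[1] - eps | conc > rng[2] + eps)
  }
  structure(list(intercept = a, slope = b, r_squared = r2,
                 range_mM = rng, inverse = inverse),
            class = "atp_calibration")
}

#' @export
print.atp_calibration <- function(x, ...) {
  cat(sprintf("ATP calibration: log10(signal) = %.4g + %.4g log10(conc_mM)\n",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.5f, valid range %.3g-%.3g mM\n",
              x$r_squared, x$range_mM[1], x$range_mM[2]))
  invisible(x)
}

#' Monotone concentration-dependence of fold changes
#'
#' Spearman rank correlation between substrate concentration and fold change,
#' with a seeded permutation p-value. The one-sided p (increasing trend) is
#' used for the monotone flag at alpha = 0.05; the two-sided p is reported as
#' well.
#'
#' @param substrate_mM substrate levels (>= 4 distinct values).
#' @param fold fold changes at those levels.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @param alpha significance level for the monotone flag.
#' @return list with `rho`, `p_one_sided`, `p_two_sided`, `monotone_increase`,
#'   `n_perm`.
#' @export
concentration_trend <- function(substrate_mM, fold, n_perm = 10000,
                                seed = 1, alpha = 0.05) {
  if (length(substrate_mM) < 4L || length(fold) != length(substrate_mM)) {
    stop_field("substrate_mM", "need >= 4 matched substrate levels")
  }
  if (stats::sd(fold) == 0) {
    return(list(rho = NA_real_, p_one_sided = NA_real_, p_two_sided = NA_real_,
                monotone_increase = FALSE, n_perm = n_perm,
                degenerate = TRUE))
  }
  rho <- stats::cor(substrate_mM, fold, method = "spearman")
  set.seed(check_seed(seed))
  perm <- vapply(seq_len(n_perm), function(i) {
    stats::cor(substrate_mM, sample(fold), method = "spearman")
  }, numeric(1))
  p1 <- (sum(perm >= rho) + 1) / (n_perm + 1)
  p2 <- (sum(abs(perm) >= abs(rho)) + 1) / (n_perm + 1)
  list(rho = rho, p_one_sided = p1, p_two_sided = p2,
       monotone_increase = rho > 0 && p1 <= alpha, n_perm = n_perm,
       degenerate = FALSE)
}

#' Half-maximal timing of a growth curve
#'
#' The maximum OD is taken from a 3-point running-median smoothed series (to
#' resist single-point spikes); the half-max time is the first crossing of
#' half that maximum, located by linear interpolation between the flanking
#' samples. If the series never reaches half of its maximum-so-far the
#' crossing is marked unreachable rather than extrapolated.
#'
#' @param time_h time grid, hours, strictly increasing, >= 5 points.
#' @param od600 optical-density values, >= 0.
#' @param capacity optional known plateau OD; when given, the half-max level
#'   is `capacity / 2` instead of half the observed maximum, and a series
#'   that never reaches it is marked unreachable.
#' @return object of class `"growth_metrics"`: list with `max_od`, `t_half`
#'   (h, `NA` if unreachable), `reached` (logical).
#' @examples
#' t <- seq(0, 22, 0.5)
#' half_max_time(t, 1 / (1 + exp(-0.8 * (t - 5))))
#' @export
half_max_time <- function(time_h, od600, capacity = NULL) {
  if (length(time_h) < 5L || length(od600) != length(time_h)) {
    stop_field("time_h", "need >= 5 matched time points")
  }
  if (any(diff(time_h) <= 0)) stop_field("time_h", "must be strictly increasing")
  check_nonneg(od600, "od600")
  if (all(od600 == 0)) stop_field("od600", "all-zero series")
  sm <- stats::runmed(od600, k = 3, endrule = "median")
  max_od <- max(sm)
  half <- if (is.null(capacity)) max_od / 2 else capacity / 2
  reached <- FALSE; t_half <- NA_real_
  above <- sm >= half
  ix <- which(above)[1]
  if (!is.na(ix)) {
    reached <- TRUE
    if (ix == 1L) {
      t_half <- time_h[1]
    } else {
      y0 <- sm[ix - 1L]; y1 <- sm[ix]
      t_half <- time_h[ix - 1L] + (half - y0) / (y1 - y0) * (time_h[ix] - time_h[ix - 1L])
    }
  }
  structure(list(max_od = max_od, t_half = t_half, reached = reached),
            class = "growth_metrics")
}

#' @export
print.growth_metrics <- function(x, ...) {
  cat(sprintf("growth metrics: max OD %.3f, t1/2 %s\n", x$max_od,
              if (x$reached) sprintf("%.2f h", x$t_half) else "unreachable"))
  invisible(x)
}

#' Growth delay between two strains
#'
#' Difference of half-maximal times, `t_half(test) - t_half(reference)`.
#' Positive values mean the test strain is delayed; negative values (test
#' faster) are preserved. If either crossing is unreachable the delay is
#' unreachable (`NA`).
#'
#' @param test,reference [half_max_time()] results.
#' @return delay in hours (`NA` if either t1/2 is unreachable).
#' @export
growth_delay <- function(test, reference) {
  stopifnot(inherits(test, "growth_metrics"), inherits(reference, "growth_metrics"))
  if (!test$reached || !reference$reached) return(NA_real_)
  test$t_half - reference$t_half
}
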