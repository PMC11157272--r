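#' Fit equilibrium titration curves, singly or globally with a shared Kd
#'
#' Weighted nonlinear least-squares fit of plateau titration data to either
#' the hyperbolic isotherm ([hyperbolic_signal()]) or the ligand-depletion
#' quadratic model ([quadratic_signal()]). With several curves the
#' dissociation constant is shared across all of them while every curve keeps
#' its own baseline `c`, amplitude `Ymax` and (for the quadratic model)
#' effective fixed-component concentration `DT` — the global-fit protocol that
#' makes Kd identifiable in the intermediate binding regime, where single
#' curves cannot separate affinity from depletion.
#'
#' Kd and DT are optimised on the log10 scale, which enforces positivity and
#' equalises step sizes across decades. For any trial (Kd, DT) the model is
#' linear in (c, Ymax), so those are profiled out exactly by weighted linear
#' least squares (variable projection); the nonlinear search therefore runs
#' over only `1 + n_curves` parameters. The optimiser is Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) with a multistart over `kd_starts`. Standard errors
#' come from the Jacobian of the full parameter vector at the optimum.
#'
#' @param data a `data.frame` with columns `curve_id`, `conc_M` (titrant
#'   concentration, molar, >= 0) and `signal`; optional `signal_sd` (per-point
#'   SD used as inverse-variance weights) and `DT_hint_M` (per-curve starting
#'   value for DT). Output of [simulate_titration()] is accepted directly.
#' @param model `"quadratic"` (default; ligand depletion) or `"hyperbolic"`.
#' @param kd optional fixed Kd (molar). When supplied, Kd is not estimated.
#' @param dt optional fixed DT (molar): a scalar recycled to all curves or a
#'   vector named by `curve_id`. When `NULL` (default) DT is estimated per
#'   curve (quadratic model only).
#' @param n complex stoichiometry, fixed (default 1).
#' @param dt_start default DT starting value (molar) for curves without a
#'   `DT_hint_M`; 1e-9 M, the typical effective concentration of immobilized
#'   DNA on a BLI tip.
#' @param kd_starts multistart grid for Kd (molar); default 7 log-spaced
#'   values over 1e-12 to 1e-5.
#' @param active_fraction fraction of the fixed component that is binding
#'   active. Fitted DT values are effective concentrations and are *not*
#'   corrected; when `active_fraction < 1` the summary additionally reports
#'   `dt / active_fraction`.
#' @param control list passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `"titration_fit"` with methods [print()],
#'   [summary()], [coef()], [predict()], [fitted()], [residuals()], [plot()],
#'   [simulate()] and [confint()]. Key elements: `kd`, `kd_se`, `curves`
#'   (per-curve parameter table with regime labels and identifiability flags),
#'   `rss`, `sigma`, `converged`.
#' @examples
#' sim <- simulate_titration(kd = 2e-9, n_curves = 3, noise_sd = 0, seed = 1)
#' fit <- fit_titration(sim)
#' coef(fit)["kd"]
#' @seealso [binding_regime()], [simulate_titration()]
#' @export
fit_titration <- function(data,
                          model = c("quadratic", "hyperbolic"),
                          kd = NULL,
                          dt = NULL,
                          n = 1,
                          dt_start = 1e-9,
                          kd_starts = 10^seq(-12, -5, length.out = 7),
                          active_fraction = 1,
                          control = list(maxiter = 200)) {
  model <- match.arg(model)
  if (inherits(data, "titration_sim")) data <- data$data
  curves <- .tv_split_curves(data, dt_start = dt_start)
  check_positive(n, "n")
  check_positive(dt_start, "dt_start")
  check_positive(kd_starts, "kd_starts")
  check_positive(active_fraction, "active_fraction")
  if (!is.null(kd)) check_positive(kd, "kd")
  if (!is.null(dt)) {
    check_positive(dt, "dt")
    dt <- .tv_expand_dt(dt, names(curves))
  }

  fit <- .tv_optimize(curves, model, n = n,
                      kd_fixed = kd, dt_fixed = dt,
                      kd_starts = if (is.null(kd)) kd_starts else numeric(),
                      control = control)
  .tv_finish_fit(fit, curves, model, n, active_fraction,
                 kd_fixed = kd, dt_fixed = dt, call = match.call())
}

# ---- internal: data handling -------------------------------------------------

.tv_split_curves <- function(data, dt_start = 1e-9) {
  req <- c("curve_id", "conc_M", "signal")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop_field("data", paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(data$conc_M) || any(data$conc_M < 0)) {
    stop_field("conc_M", "must be non-missing and >= 0")
  }
  if (anyNA(data$signal)) stop_field("signal", "must be non-missing")
  ids <- unique(as.character(data$curve_id))
  curves <- lapply(ids, function(id) {
    d <- data[as.character(data$curve_id) == id, , drop = FALSE]
    if (nrow(d) < 4L) stop_field("data", sprintf("curve '%s' has < 4 points", id))
    if (length(unique(d$conc_M)) < 2L) {
      stop_field("data", sprintf("curve '%s' has < 2 distinct concentrations", id))
    }
    w <- if ("signal_sd" %in% names(d) && all(is.finite(d$signal_sd)) && all(d$signal_sd > 0)) {
      1 / d$signal_sd^2
    } else {
      rep(1, nrow(d))
    }
    hint <- if ("DT_hint_M" %in% names(d)) d$DT_hint_M[1] else NA_real_
    list(id = id, conc = d$conc_M, y = d$signal, w = w,
         dt_start = if (is.finite(hint) && hint > 0) hint else dt_start)
  })
  names(curves) <- ids
  curves
}

.tv_expand_dt <- function(dt, ids) {
  if (length(dt) == 1L && is.null(names(dt))) {
    dt <- rep(dt, length(ids))
    names(dt) <- ids
  }
  if (!all(ids %in% names(dt))) stop_field("dt", "must be a scalar or named by curve_id")
  dt[ids]
}

# ---- internal: variable-projection residuals ---------------------------------

# bound fraction under each model
.tv_frac <- function(conc, kd, dt, n, model) {
  if (model == "hyperbolic") {
    conc / (kd + conc)
  } else {
    a <- n + conc / dt + kd / dt
    disc <- a * a - 4 * n * conc / dt
    disc[disc < 0] <- 0
    (a - sqrt(disc)) / (2 * n)
  }
}

# exact WLS solve of y ~ c + ymax * f for one curve; robust to a constant f
.tv_linear <- function(f, y, w) {
  X <- cbind(1, f)
  A <- crossprod(X, X * w)
  b <- crossprod(X, y * w)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta) || anyNA(beta) || any(!is.finite(beta))) {
    beta <- c(sum(w * y) / sum(w), 0)
  }
  c(beta)
}

# weighted residual vector over all curves for nonlinear parameters theta;
# theta layout: [log10 kd (if free)] + per-curve log10 dt (quadratic, if free)
.tv_resid <- function(theta, curves, model, n, kd_fixed, dt_fixed) {
  m <- length(curves)
  i <- 1L
  kd <- if (is.null(kd_fixed)) {
    k <- 10^theta[i]; i <- i + 1L; k
  } else kd_fixed
  unlist(lapply(seq_len(m), function(j) {
    cv <- curves[[j]]
    dt <- if (model == "hyperbolic") {
      NA_real_
    } else if (is.null(dt_fixed)) {
      10^theta[i + j - 1L]
    } else {
      dt_fixed[[j]]
    }
    f <- .tv_frac(cv$conc, kd, dt, n, model)
    beta <- .tv_linear(f, cv$y, cv$w)
    (cv$y - beta[1] - beta[2] * f) * sqrt(cv$w)
  }), use.names = FALSE)
}

.tv_theta_start <- function(lkd, curves, model, kd_fixed, dt_fixed) {
  th <- if (is.null(kd_fixed)) lkd else numeric()
  if (model == "quadratic" && is.null(dt_fixed)) {
    th <- c(th, log10(vapply(curves, `[[`, numeric(1), "dt_start")))
  }
  th
}

.tv_optimize <- function(curves, model, n, kd_fixed, dt_fixed, kd_starts, control) {
  ctl <- do.call(minpack.lm::nls.lm.control, control)
  starts <- if (is.null(kd_fixed)) log10(kd_starts) else NA_real_
  best <- NULL
  for (lkd in starts) {
    theta0 <- .tv_theta_start(lkd, curves, model, kd_fixed, dt_fixed)
    if (length(theta0) == 0L) {
      # fully linear problem: nothing to optimise
      r <- .tv_resid(numeric(), curves, model, n, kd_fixed, dt_fixed)
      cand <- list(theta = numeric(), rss = sum(r^2), info = 1L)
    } else {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = theta0, fn = .tv_resid, curves = curves,
                           model = model, n = n, kd_fixed = kd_fixed,
                           dt_fixed = dt_fixed, control = ctl),
        error = function(e) NULL)
      if (is.null(fit)) next
      cand <- list(theta = fit$par, rss = fit$deviance, info = fit$info)
    }
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  if (is.null(best)) {
    stop("titration fit failed: no multistart attempt converged", call. = FALSE)
  }
  best
}

# full parameter vector (for covariance): [log10 kd] + per-curve (c, ymax[, log10 dt])
.tv_full_resid <- function(phi, curves, model, n, kd_fixed, dt_fixed) {
  i <- 1L
  kd <- if (is.null(kd_fixed)) { k <- 10^phi[i]; i <- i + 1L; k } else kd_fixed
  per <- if (model == "quadratic" && is.null(dt_fixed)) 3L else 2L
  unlist(lapply(seq_along(curves), function(j) {
    cv <- curves[[j]]
    base <- i + (j - 1L) * per
    cc <- phi[base]; ym <- phi[base + 1L]
    dt <- if (model == "hyperbolic") NA_real_
          else if (is.null(dt_fixed)) 10^phi[base + 2L] else dt_fixed[[j]]
    f <- .tv_frac(cv$conc, kd, dt, n, model)
    (cv$y - cc - ym * f) * sqrt(cv$w)
  }), use.names = FALSE)
}

.tv_num_jac <- function(fn, x, ...) {
  f0 <- fn(x, ...)
  J <- matrix(NA_real_, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- max(1e-7, abs(x[k]) * 1e-7)
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    J[, k] <- (fn(xp, ...) - fn(xm, ...)) / (2 * h)
  }
  J
}

.tv_finish_fit <- function(best, curves, model, n, active_fraction,
                           kd_fixed, dt_fixed, call) {
  m <- length(curves)
  theta <- unname(best$theta)
  i <- 1L
  kd <- if (is.null(kd_fixed)) { k <- 10^theta[i]; i <- i + 1L; k } else kd_fixed

  # recover per-curve parameters at the optimum
  tab <- do.call(rbind, lapply(seq_len(m), function(j) {
    cv <- curves[[j]]
    dt <- if (model == "hyperbolic") NA_real_
          else if (is.null(dt_fixed)) 10^theta[i + j - 1L] else dt_fixed[[j]]
    f <- .tv_frac(cv$conc, kd, dt, n, model)
    beta <- .tv_linear(f, cv$y, cv$w)
    fspan <- diff(range(f))
    data.frame(curve_id = cv$id, c = beta[1], ymax = beta[2], dt = dt,
               frac_span = fspan,
               nonidentifiable = (beta[2] == 0) || (fspan < 0.2),
               regime = if (model == "quadratic")
                 binding_regime(dt, kd)$label else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL

  fitted_list <- lapply(seq_len(m), function(j) {
    cv <- curves[[j]]
    f <- .tv_frac(cv$conc, kd, tab$dt[j], n, model)
    tab$c[j] + tab$ymax[j] * f
  })
  res_list <- lapply(seq_len(m), function(j) curves[[j]]$y - fitted_list[[j]])
  w_all <- unlist(lapply(curves, `[[`, "w"), use.names = FALSE)
  res_all <- unlist(res_list, use.names = FALSE)
  rss <- sum(w_all * res_all^2)

  per <- if (model == "quadratic" && is.null(dt_fixed)) 3L else 2L
  p <- (if (is.null(kd_fixed)) 1L else 0L) + per * m
  N <- length(res_all)
  df_res <- max(N - p, 1L)
  sigma2 <- rss / df_res

  # covariance from the full parameter vector
  phi <- c(if (is.null(kd_fixed)) log10(kd),
           unlist(lapply(seq_len(m), function(j) {
             c(tab$c[j], tab$ymax[j],
               if (per == 3L) log10(tab$dt[j]))
           })))
  kd_se <- NA_real_; lkd_se <- NA_real_; cov_phi <- NULL
  if (is.null(kd_fixed)) {
    J <- .tv_num_jac(.tv_full_resid, phi, curves = curves, model = model,
                     n = n, kd_fixed = kd_fixed, dt_fixed = dt_fixed)
    cov_phi <- tryCatch(sigma2 * chol2inv(chol(crossprod(J))),
                        error = function(e) NULL)
    if (!is.null(cov_phi)) {
      lkd_se <- sqrt(cov_phi[1, 1])
      kd_se <- kd * log(10) * lkd_se
    }
  }

  structure(list(
    kd = kd, kd_se = kd_se, log10kd = log10(kd), log10kd_se = lkd_se,
    kd_fixed = !is.null(kd_fixed),
    curves = tab, model = model, n = n,
    rss = rss, sigma = sqrt(sigma2), df.residual = N - p, nobs = N,
    converged = best$info %in% 1:3,
    active_fraction = active_fraction,
    fitted_by_curve = fitted_list, residuals_by_curve = res_list,
    input = curves, call = call), class = "titration_fit")
}

# ---- methods -----------------------------------------------------------------

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Equilibrium titration fit (%s model, n = %g)\n", x$model, x$n))
  cat(sprintf("  curves: %d, observations: %d\n", nrow(x$curves), x$nobs))
  if (x$kd_fixed) {
    cat(sprintf("  Kd (fixed): %.3g M\n", x$kd))
  } else {
    cat(sprintf("  shared Kd: %.3g M (SE %.2g M)\n", x$kd, x$kd_se))
  }
  cat(sprintf("  weighted RSS: %.4g, sigma: %.3g, converged: %s\n",
              x$rss, x$sigma, x$converged))
  if (any(x$curves$nonidentifiable)) {
    cat("  warning: non-identifiable curve(s): ",
        paste(x$curves$curve_id[x$curves$nonidentifiable], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.titration_fit <- function(object, ...) {
  tab <- object$curves
  if (object$active_fraction < 1 && object$model == "quadratic") {
    tab$dt_corrected <- tab$dt / object$active_fraction
  }
  out <- list(kd = object$kd, kd_se = object$kd_se, kd_fixed = object$kd_fixed,
              model = object$model, n = object$n, curves = tab,
              rss = object$rss, sigma = object$sigma,
              df.residual = object$df.residual, converged = object$converged)
  class(out) <- "summary.titration_fit"
  out
}

#' @export
print.summary.titration_fit <- function(x, ...) {
  cat(sprintf("Equilibrium titration fit (%s model, n = %g)\n", x$model, x$n))
  if (x$kd_fixed) cat(sprintf("Kd fixed at %.4g M\n", x$kd))
  else cat(sprintf("Shared Kd: %.4g M  (SE %.3g M)\n", x$kd, x$kd_se))
  cat(sprintf("Weighted RSS %.4g on %d residual df (sigma %.3g); converged: %s\n\n",
              x$rss, x$df.residual, x$sigma, x$converged))
  print(x$curves, digits = 4)
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) {
  tab <- object$curves
  out <- c(kd = object$kd)
  for (j in seq_len(nrow(tab))) {
    nm <- tab$curve_id[j]
    v <- c(tab$c[j], tab$ymax[j], tab$dt[j])
    names(v) <- paste(c("c", "ymax", "dt"), nm, sep = ".")
    out <- c(out, if (object$model == "hyperbolic") v[1:2] else v)
  }
  out
}

#' @export
fitted.titration_fit <- function(object, ...) {
  unlist(object$fitted_by_curve, use.names = FALSE)
}

#' @export
residuals.titration_fit <- function(object, ...) {
  unlist(object$residuals_by_curve, use.names = FALSE)
}

#' Predict plateau signals from a titration fit
#'
#' @param object a [fit_titration()] result.
#' @param newdata optional `data.frame` with `curve_id` and `conc_M`; defaults
#'   to the fitted data.
#' @param ... unused.
#' @return numeric vector of predicted signals.
#' @export
predict.titration_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  tab <- object$curves
  idx <- match(as.character(newdata$curve_id), tab$curve_id)
  if (anyNA(idx)) stop_field("newdata", "unknown curve_id")
  f <- .tv_frac(newdata$conc_M, object$kd, tab$dt[idx], object$n, object$model)
  tab$c[idx] + tab$ymax[idx] * f
}

#' Plot titration data and fitted curves
#'
#' Signal versus log10 titrant concentration, one colour per curve, with the
#' fitted model drawn over a fine concentration grid.
#'
#' @param x a [fit_titration()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.titration_fit <- function(x, ...) {
  conc <- unlist(lapply(x$input, `[[`, "conc"), use.names = FALSE)
  y <- unlist(lapply(x$input, `[[`, "y"), use.names = FALSE)
  lx <- log10(pmax(conc, min(conc[conc > 0]) / 10))
  cols <- grDevices::hcl.colors(max(nrow(x$curves), 2L), "Dark 3")
  graphics::plot(lx, y, type = "n",
                 xlab = "log10 titrant concentration (M)", ylab = "signal", ...)
  for (j in seq_len(nrow(x$curves))) {
    cv <- x$input[[j]]
    pos <- cv$conc[cv$conc > 0]
    graphics::points(log10(pmax(cv$conc, min(pos) / 10)), cv$y,
                     col = cols[j], pch = 16)
    grid_l <- seq(log10(min(pos)) - 1, log10(max(pos)) + 0.5, length.out = 120)
    f <- .tv_frac(10^grid_l, x$kd, x$curves$dt[j], x$n, x$model)
    graphics::lines(grid_l, x$curves$c[j] + x$curves$ymax[j] * f, col = cols[j])
  }
  invisible(x)
}

#' Simulate responses from a fitted titration model
#'
#' Parametric simulation: Gaussian noise with the fit's residual scale (scaled
#' by the per-point weights where present) added to the fitted values.
#'
#' @param object a [fit_titration()] result.
#' @param nsim number of simulated response sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a `data.frame` with one column per simulation, rows aligned with
#'   the fitted data.
#' @export
simulate.titration_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(check_seed(seed))
  mu <- fitted(object)
  w <- unlist(lapply(object$input, `[[`, "w"), use.names = FALSE)
  sds <- object$sigma / sqrt(w)
  out <- as.data.frame(lapply(seq_len(nsim), function(i) mu + stats::rnorm(length(mu), 0, sds)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Confidence interval for the shared dissociation constant
#'
#' `method = "wald"` (default) uses the asymptotic SE of log10(Kd);
#' `method = "bootstrap"` runs a parametric bootstrap — noise at the fitted
#' residual scale is re-simulated on the fitted curves, the global fit is
#' re-run from the fitted parameters, and the percentile interval of the
#' bootstrap Kd distribution is returned.
#'
#' @param object a converged [fit_titration()] result with free Kd.
#' @param parm only `"kd"` is supported.
#' @param level confidence level (default 0.95).
#' @param method `"wald"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates; fewer than 50 triggers a warning.
#' @param seed integer seed for the bootstrap.
#' @param ... unused.
#' @return a 1 x 2 matrix of interval endpoints (molar); for the bootstrap,
#'   the replicate Kd values are attached as attribute `"boot_kd"`.
#' @export
confint.titration_fit <- function(object, parm = "kd", level = 0.95,
                                  method = c("wald", "bootstrap"),
                                  n_boot = 200, seed = NULL, ...) {
  method <- match.arg(method)
  if (!identical(parm, "kd")) stop_field("parm", "only 'kd' is supported")
  if (object$kd_fixed) stop("Kd was fixed in this fit; no interval available", call. = FALSE)
  alpha <- (1 - level) / 2
  if (method == "wald") {
    z <- stats::qnorm(1 - alpha)
    ci <- 10^(object$log10kd + c(-1, 1) * z * object$log10kd_se)
  } else {
    if (n_boot < 50) warning("n_boot < 50: bootstrap interval will be unstable")
    if (!is.null(seed)) set.seed(check_seed(seed))
    kds <- vapply(seq_len(n_boot), function(b) {
      .tv_refit_boot(object)
    }, numeric(1))
    ci <- stats::quantile(kds, c(alpha, 1 - alpha), names = FALSE, type = 7)
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list("kd", sprintf("%.1f %%", 100 * c(alpha, 1 - alpha))))
  if (method == "bootstrap") attr(out, "boot_kd") <- kds
  out
}

# one parametric-bootstrap refit, warm-started at the fitted parameters;
# noise is resimulated at each curve's own residual scale so that curves of
# different amplitude (and hence different absolute noise) stay comparably
# noisy in the resamples
.tv_refit_boot <- function(object) {
  curves <- object$input
  per <- if (object$model == "quadratic") 3L else 2L
  for (j in seq_along(curves)) {
    mu <- object$fitted_by_curve[[j]]
    r <- object$residuals_by_curve[[j]]
    w <- curves[[j]]$w
    sigma_j <- sqrt(sum(w * r^2) / max(length(r) - per, 1L))
    curves[[j]]$y <- mu + stats::rnorm(length(mu), 0, sigma_j / sqrt(w))
    curves[[j]]$dt_start <- object$curves$dt[j]
  }
  theta0 <- .tv_theta_start(object$log10kd, curves, object$model, NULL, NULL)
  fit <- minpack.lm::nls.lm(par = theta0, fn = .tv_resid, curves = curves,
                            model = object$model, n = object$n,
                            kd_fixed = NULL, dt_fixed = NULL,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  10^unname(fit$par[1])
}
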