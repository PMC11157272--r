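#' Hyperbolic equilibrium binding isotherm
#'
#' Plateau signal of an equilibrium titration in the non-depleting
#' ("equilibrium") regime, where the free titrant concentration equals the
#' total titrant concentration:
#' \deqn{Y = c + Y_{max} \frac{L}{K_d + L}}
#' with \eqn{L} the titrant concentration. Valid only when the fixed binding
#' partner is at least 10-fold below \eqn{K_d} (see [binding_regime()]);
#' otherwise ligand depletion biases the apparent affinity and
#' [quadratic_signal()] must be used.
#'
#' @param conc titrant concentration(s), molar. Non-negative.
#' @param kd equilibrium dissociation constant, molar. Must be > 0.
#' @param c baseline signal at zero titrant.
#' @param ymax saturation amplitude (signal units).
#' @return Numeric vector of plateau signals, bounded in `[c, c + ymax]` and
#'   non-decreasing in `conc` when `ymax > 0`.
#' @seealso [quadratic_signal()], [binding_regime()], [fit_titration()]
#' @examples
#' hyperbolic_signal(2e-9, kd = 2e-9, c = 0, ymax = 1)  # half saturation: 0.5
#' @export
hyperbolic_signal <- function(conc, kd, c = 0, ymax = 1) {
  check_positive(kd, "kd")
  check_nonneg(conc, "conc")
  c + ymax * conc / (kd + conc)
}

#' Ligand-depletion (quadratic) equilibrium binding model
#'
#' Plateau signal of an equilibrium titration when the fixed component is not
#' far below \eqn{K_d}, so a non-negligible fraction of the titrant is bound
#' (the "stoichiometric" or "intermediate" regime). With \eqn{L} the total
#' titrant concentration, \eqn{D_T} the total concentration of the fixed
#' species and \eqn{n} the complex stoichiometry,
#' \deqn{Y = c + Y_{max}\,\frac{a - \sqrt{a^2 - 4 n L / D_T}}{2n},\quad
#'       a = n + \frac{L}{D_T} + \frac{K_d}{D_T}.}
#' The discriminant is mathematically non-negative; round-off can drive it
#' slightly below zero, in which case it is clamped at 0.
#'
#' @inheritParams hyperbolic_signal
#' @param dt total concentration of the fixed species, molar. Must be > 0.
#' @param n stoichiometry of the complex (dimensionless, default 1). Must be > 0.
#' @return Numeric vector of plateau signals, bounded in `[c, c + ymax]` and
#'   non-decreasing in `conc` when `ymax > 0`.
#' @examples
#' # at L = DT = Kd and n = 1 the bound fraction is (3 - sqrt(5))/2
#' quadratic_signal(2e-9, kd = 2e-9, dt = 2e-9)
#' @export
quadratic_signal <- function(conc, kd, dt, c = 0, ymax = 1, n = 1) {
  check_positive(kd, "kd")
  check_positive(dt, "dt")
  check_positive(n, "n")
  check_nonneg(conc, "conc")
  a <- n + conc / dt + kd / dt
  disc <- a * a - 4 * n * conc / dt
  disc[disc < 0] <- 0
  c + ymax * (a - sqrt(disc)) / (2 * n)
}

#' Classify the binding regime of an equilibrium assay
#'
#' An equilibrium binding measurement is classified by the ratio of the fixed
#' component's total concentration to the dissociation constant. Only when the
#' fixed component is at least 10-fold below Kd does the simple hyperbolic
#' isotherm apply ("equilibrium" regime); at 10-fold above Kd the titration is
#' "stoichiometric" (the curve reports concentration, not affinity), and in
#' between the depletion-corrected quadratic model is required. Ratios exactly
#' at 0.1 or 10 are assigned to the outer regimes.
#'
#' @param dt fixed-component total concentration, molar (> 0).
#' @param kd dissociation constant, molar (> 0).
#' @return Object of class `"binding_regime"`: a list with `label` (one of
#'   `"equilibrium"`, `"intermediate"`, `"stoichiometric"`) and `ratio`
#'   (`dt / kd`).
#' @examples
#' binding_regime(dt = 2.5e-9, kd = 2e-9)  # intermediate, ratio 1.25
#' @export
binding_regime <- function(dt, kd) {
  check_positive(dt, "dt")
  check_positive(kd, "kd")
  stopifnot(length(dt) == 1L, length(kd) == 1L)
  ratio <- dt / kd
  label <- if (ratio <= 0.1) "equilibrium" else if (ratio >= 10) "stoichiometric" else "intermediate"
  structure(list(label = label, ratio = ratio), class = "binding_regime")
}

#' @export
print.binding_regime <- function(x, ...) {
  cat(sprintf("binding regime: %s (DT/Kd = %.3g)\n", x$label, x$ratio))
  invisible(x)
}
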