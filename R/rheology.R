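#' Power-law (Ostwald-de Waele) fluid
#'
#' Constitutive model eta = K * gamma_dot^(n - 1) with consistency index K
#' (Pa.s^n) and flow behavior index n. Shear thinning corresponds to n < 1.
#'
#' @param K Consistency index, Pa.s^n, > 0.
#' @param n Flow behavior index, dimensionless, > 0.
#' @param r_squared Goodness of the log-log fit in \[0, 1\] (NA when the
#'   parameters were not fitted).
#' @param fit_range Shear-rate window of validity, length-2 numeric (1/s).
#' @param label Optional provenance label (e.g. concentration / pH).
#' @return An object of class `power_law_fluid`.
#' @export
power_law_fluid <- function(K, n, r_squared = NA_real_,
                            fit_range = c(NA_real_, NA_real_), label = NULL) {
  if (!is.finite(K) || K <= 0) stop("K must be positive")
  if (!is.finite(n) || n <= 0) stop("n must be positive")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]")
  }
  structure(list(K = K, n = n, r_squared = r_squared,
                 fit_range = as.numeric(fit_range), label = label),
            class = "power_law_fluid")
}

#' @export
print.power_law_fluid <- function(x, ...) {
  cat(sprintf("Power-law fluid%s: K = %.4g Pa.s^n, n = %.4g%s\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$K, x$n,
              if (is.na(x$r_squared)) "" else sprintf(" (R^2 = %.4f)", x$r_squared)))
  if (x$n < 1) cat("  shear thinning\n") else if (x$n > 1) cat("  shear thickening\n")
  invisible(x)
}

#' Fit the power law to a flow curve
#'
#' Log-transforms shear rate and viscosity and fits an ordinary least-squares
#' line: the slope is n - 1 and the intercept log(K). A warning (not an error)
#' is raised when R^2 of the fit drops below 0.95, the usual quality bar for
#' flow-sweep data in the power-law region.
#'
#' @param curve A [flow_curve].
#' @param fit_range Optional length-2 shear-rate window (1/s); only points with
#'   `fit_range[1] <= shear_rate <= fit_range[2]` are used. Default: all points.
#' @return A [power_law_fluid] with `r_squared` and `fit_range` filled in.
#' @examples
#' fc <- flow_curve(10^seq(-1, 3, length.out = 30),
#'                  5.78 * 10^seq(-1, 3, length.out = 30)^(0.12 - 1))
#' fit_power_law(fc)
#' @export
fit_power_law <- function(curve, fit_range = NULL) {
  stopifnot(inherits(curve, "flow_curve"))
  rate <- curve$shear_rate
  visc <- curve$viscosity
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2L, fit_range[1] < fit_range[2])
    keep <- rate >= fit_range[1] & rate <= fit_range[2]
    rate <- rate[keep]
    visc <- visc[keep]
  }
  if (length(rate) < 3L) stop("need at least 3 points in the fit range")
  fit <- stats::lm(log(visc) ~ log(rate))
  slope <- unname(stats::coef(fit)[2])
  n <- slope + 1
  K <- exp(unname(stats::coef(fit)[1]))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(visc) - mean(log(visc)))^2)
  # a flat (Newtonian) curve has zero total variance; a perfect fit by definition
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  if (r2 < 0.95) {
    warning(sprintf("log-log fit R^2 = %.3f < 0.95; power law may not describe these data", r2))
  }
  if (n <= 0) stop("fitted behavior index n <= 0; data are not power-law-like")
  power_law_fluid(K = K, n = n, r_squared = r2,
                  fit_range = c(min(rate), max(rate)))
}

#' Apparent viscosity of a power-law fluid
#'
#' @param fluid A [power_law_fluid].
#' @param shear_rate Shear rate(s), 1/s, > 0 (vectorized).
#' @return Apparent viscosity eta = K * shear_rate^(n - 1), Pa.s.
#' @export
viscosity_at <- function(fluid, shear_rate) {
  stopifnot(inherits(fluid, "power_law_fluid"))
  if (any(!is.finite(shear_rate)) || any(shear_rate <= 0)) {
    stop("shear_rate must be positive")
  }
  fluid$K * shear_rate^(fluid$n - 1)
}

#' Kelvin-Voigt viscoelastic material
#'
#' Lumped description of a gel (or support bath) as a Hookean spring E in
#' parallel with a Newtonian dashpot eta0, plus Poisson ratio and density for
#' the continuum finite-element model. Under constant stress sigma it creeps as
#' (sigma/E) * (1 - exp(-E t / eta0)).
#'
#' @param E Spring constant (Young's modulus), Pa, > 0.
#' @param eta0 Dashpot viscosity (low-shear Newtonian viscosity), Pa.s, >= 0.
#' @param nu Poisson ratio in \[0, 0.5). Default 0.49 (water-rich gels are
#'   nearly incompressible).
#' @param rho Density, kg/m^3. Default 1000 (hydrogels are mostly water).
#' @param G0 Low-strain storage modulus the spring was derived from, Pa
#'   (provenance; NA if E was given directly).
#' @param label Optional provenance label.
#' @return An object of class `kelvin_voigt`.
#' @export
kelvin_voigt <- function(E, eta0, nu = 0.49, rho = 1000, G0 = NA_real_,
                         label = NULL) {
  if (!is.finite(E) || E <= 0) stop("E must be positive")
  if (!is.finite(eta0) || eta0 < 0) stop("eta0 must be non-negative")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5)")
  if (!is.finite(rho) || rho <= 0) stop("rho must be positive")
  structure(list(E = E, eta0 = eta0, nu = nu, rho = rho, G0 = G0, label = label),
            class = "kelvin_voigt")
}

#' @export
print.kelvin_voigt <- function(x, ...) {
  cat(sprintf("Kelvin-Voigt material%s: E = %.4g Pa, eta0 = %.4g Pa.s, nu = %.3g, rho = %g kg/m^3\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$E, x$eta0, x$nu, x$rho))
  if (x$eta0 > 0) cat(sprintf("  creep time constant eta0/E = %.3g s\n", x$eta0 / x$E))
  invisible(x)
}

#' Derive a Kelvin-Voigt material from oscillatory moduli
#'
#' Converts a low-strain storage modulus G0 into the spring constant E of the
#' Kelvin-Voigt model. Two conversion conventions are supported:
#' `"tabulated"` (default) applies E = 2 * G0, the relation the reference
#' lumped-parameter characterization of these gels actually follows;
#' `"poisson"` applies the elasticity relation E = 2 * (1 + nu) * G0. The two
#' coincide only at nu = 0; with nu = 0.49 they differ by a factor 1.49, so the
#' choice is exposed rather than silently made.
#'
#' @param G0 Low-strain storage modulus, Pa, > 0.
#' @param eta0 Low-shear viscosity for the dashpot, Pa.s.
#' @param nu Poisson ratio in \[0, 0.5).
#' @param rho Density, kg/m^3.
#' @param convention `"tabulated"` or `"poisson"` (see Details).
#' @param label Optional provenance label.
#' @return A [kelvin_voigt] material.
#' @examples
#' kelvin_voigt_from_moduli(G0 = 369, eta0 = 5237.4)            # E = 738 Pa
#' kelvin_voigt_from_moduli(G0 = 15, nu = 0.49, eta0 = 231.4,
#'                          convention = "poisson")              # E = 44.7 Pa
#' @export
kelvin_voigt_from_moduli <- function(G0, eta0 = 0, nu = 0.49, rho = 1000,
                                     convention = c("tabulated", "poisson"),
                                     label = NULL) {
  convention <- match.arg(convention)
  if (!is.finite(G0) || G0 <= 0) stop("G0 must be positive")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5)")
  E <- switch(convention, tabulated = 2 * G0, poisson = 2 * (1 + nu) * G0)
  kelvin_voigt(E = E, eta0 = eta0, nu = nu, rho = rho, G0 = G0, label = label)
}

#' Estimate the yield stress of a flow curve
#'
#' Fits the Herschel-Bulkley law tau = tau_y + K * gamma_dot^n to the
#' stress-rate curve by nonlinear least squares (Levenberg-Marquardt). The
#' fitted tau_y is a convenience estimate of the low-shear stress plateau;
#' treat it as approximate. A negative fitted yield stress is clamped to 0
#' with a warning, as is a failed fit.
#'
#' @param curve A [flow_curve] including a low-shear plateau (at least 5
#'   points below 1 1/s).
#' @return Estimated yield stress tau_y, Pa (>= 0). The full Herschel-Bulkley
#'   parameter set is attached as attribute `"hb"`.
#' @export
estimate_yield_stress <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  if (sum(curve$shear_rate < 1) < 5L) {
    stop("need at least 5 points below 1 1/s to resolve the low-shear plateau")
  }
  rate <- curve$shear_rate
  stress <- curve$shear_stress
  # starting values: plateau level for tau_y, high-shear power law for (K, n)
  tau0 <- max(min(stress), 0)
  hi <- rate >= stats::median(rate)
  resid_hi <- pmax(stress[hi] - tau0, .Machine$double.eps)
  line <- stats::lm(log(resid_hi) ~ log(rate[hi]))
  start <- list(tau_y = tau0,
                K = exp(unname(stats::coef(line)[1])),
                n = max(unname(stats::coef(line)[2]), 0.05))
  fit <- tryCatch(
    minpack.lm::nlsLM(stress ~ tau_y + K * rate^n, start = start,
                      lower = c(tau_y = -Inf, K = 1e-12, n = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Herschel-Bulkley fit failed; returning yield stress 0")
    return(structure(0, hb = NULL))
  }
  p <- stats::coef(fit)
  tau_y <- unname(p["tau_y"])
  if (tau_y < 0) {
    warning("fitted yield stress negative; clamped to 0")
    tau_y <- 0
  }
  structure(tau_y, hb = list(tau_y = tau_y, K = unname(p["K"]), n = unname(p["n"])))
}

#' Serialize fitted rheology parameters to JSON
#'
#' @param x A [power_law_fluid] or [kelvin_voigt] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rheology_json <- function(x, path) {
  stopifnot(inherits(x, "power_law_fluid") || inherits(x, "kelvin_voigt"))
  jsonlite::write_json(c(list(class = class(x)[1]), unclass(x)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
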