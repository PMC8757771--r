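#' Fully developed power-law velocity profile in a circular pipe
#'
#' u(r) = ((3n+1)/(n+1)) * (Q / (pi R^2)) * (1 - (r/R)^((n+1)/n)). The profile
#' flattens toward plug flow as n decreases; n = 1 recovers the parabolic
#' Poiseuille profile.
#'
#' @param fluid A [power_law_fluid].
#' @param radius Pipe radius, m, > 0.
#' @param flow_rate Volumetric flow rate, m^3/s, > 0.
#' @param n_radial Number of radial sample points (>= 2), spanning 0..R.
#' @return Data frame with columns `r` (m) and `u` (m/s).
#' @export
velocity_profile <- function(fluid, radius, flow_rate, n_radial = 101L) {
  stopifnot(inherits(fluid, "power_law_fluid"),
            radius > 0, flow_rate > 0, n_radial >= 2L)
  n <- fluid$n
  r <- seq(0, radius, length.out = n_radial)
  v_mean <- flow_rate / (pi * radius^2)
  u <- ((3 * n + 1) / (n + 1)) * v_mean * (1 - (r / radius)^((n + 1) / n))
  data.frame(r = r, u = u)
}

#' Plug-like region extent of power-law pipe flow
#'
#' Radial fraction r*/R of the section over which the axial velocity stays at
#' or above `threshold` times the centerline velocity. For the fully developed
#' power-law profile this is (1 - threshold)^(n / (n + 1)): it depends only on
#' the behavior index n, not on the pipe radius or flow rate, and grows toward
#' 1 as n -> 0 (plug flow).
#'
#' @param fluid A [power_law_fluid].
#' @param threshold Fraction of centerline velocity defining the plug,
#'   in (0, 1). Default 0.95.
#' @return Dimensionless fraction in (0, 1).
#' @examples
#' plug_fraction(power_law_fluid(5.78, 0.12))  # 0.725: >70% of the section
#' @export
plug_fraction <- function(fluid, threshold = 0.95) {
  stopifnot(inherits(fluid, "power_law_fluid"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1")
  }
  n <- fluid$n
  (1 - threshold)^(n / (n + 1))
}

#' Wall shear rate and stress in a circular pipe (Rabinowitsch-Mooney)
#'
#' The true wall shear rate of a power-law fluid is the Newtonian apparent
#' rate 4Q/(pi R^3) = 8V/D corrected by the Rabinowitsch-Mooney factor
#' (3n+1)/(4n); the wall stress follows from the constitutive law
#' tau_w = K * gamma_w^n.
#'
#' @param fluid A [power_law_fluid].
#' @param radius Pipe radius, m, > 0.
#' @param flow_rate Volumetric flow rate, m^3/s, > 0.
#' @return List with `wall_shear_rate` (1/s) and `wall_shear_stress` (Pa).
#' @examples
#' f <- power_law_fluid(5.78, 0.12)
#' Q <- pi * (0.2e-3)^2 * 9e-3
#' wall_shear(f, 0.2e-3, Q)  # rate 510 1/s, stress ~12.2 Pa
#' @export
wall_shear <- function(fluid, radius, flow_rate) {
  stopifnot(inherits(fluid, "power_law_fluid"), radius > 0, flow_rate > 0)
  n <- fluid$n
  apparent <- 4 * flow_rate / (pi * radius^3)  # = 8V/D
  rate <- (3 * n + 1) / (4 * n) * apparent
  list(wall_shear_rate = rate, wall_shear_stress = fluid$K * rate^n)
}

#' Pressure drop across one extrusion-train segment
#'
#' Fully developed laminar flow under one of three rheological models:
#' \describe{
#'   \item{`power_law`}{the power law itself, wall stress from [wall_shear()].}
#'   \item{`newtonian_K`}{Newtonian with viscosity equal to the consistency
#'     index K (model 1) — a deliberately crude upper bound.}
#'   \item{`newtonian_avg_shear`}{Newtonian with the power-law viscosity
#'     evaluated at a fixed reference shear rate (model 2), normally the
#'     average needle shear rate 8V/D from [average_shear_rate()].}
#' }
#' A cylinder uses the closed form dp = 2 tau_w L / R. A cone is integrated
#' axially under the lubrication approximation (locally fully developed flow)
#' with `n_slices` midpoint slices.
#'
#' @param fluid A [power_law_fluid].
#' @param segment An [extrusion_segment].
#' @param flow_rate Volumetric flow rate, m^3/s, > 0.
#' @param model One of `"power_law"`, `"newtonian_K"`, `"newtonian_avg_shear"`.
#' @param reference_shear_rate Reference shear rate (1/s) for
#'   `newtonian_avg_shear`; ignored otherwise.
#' @param n_slices Axial slices for cone integration. Default 400.
#' @return Pressure drop, Pa.
#' @export
segment_pressure_drop <- function(fluid, segment, flow_rate,
                                  model = c("power_law", "newtonian_K",
                                            "newtonian_avg_shear"),
                                  reference_shear_rate = NULL,
                                  n_slices = 400L) {
  stopifnot(inherits(fluid, "power_law_fluid"),
            inherits(segment, "extrusion_segment"), flow_rate > 0)
  model <- match.arg(model)
  if (model == "newtonian_avg_shear" &&
      (is.null(reference_shear_rate) || reference_shear_rate <= 0)) {
    stop("newtonian_avg_shear requires a positive reference_shear_rate")
  }
  grad <- function(R) {  # local fully developed pressure gradient, Pa/m
    apparent <- 4 * flow_rate / (pi * R^3)
    tau_w <- switch(model,
      power_law = {
        n <- fluid$n
        fluid$K * ((3 * n + 1) / (4 * n) * apparent)^n
      },
      newtonian_K = fluid$K * apparent,
      newtonian_avg_shear =
        viscosity_at(fluid, reference_shear_rate) * apparent)
    2 * tau_w / R
  }
  if (segment$kind == "cylinder" ||
      segment$radius_in == segment$radius_out) {
    grad(segment$radius_in) * segment$length
  } else {
    # lubrication approximation: integrate the local gradient along the taper
    z_mid <- (seq_len(n_slices) - 0.5) / n_slices
    R_mid <- segment$radius_in + z_mid * (segment$radius_out - segment$radius_in)
    sum(vapply(R_mid, grad, numeric(1))) * segment$length / n_slices
  }
}

#' Steady flow solution for a whole extrusion system
#'
#' Chains [segment_pressure_drop()] and [wall_shear()] over the train. The
#' flow rate is fixed by the piston velocity through continuity; the cumulative
#' pressure is zero at the needle tip (outlet) and maximal at the piston face.
#'
#' @param system An [extrusion_system].
#' @param fluid A [power_law_fluid].
#' @param inlet_velocity Piston velocity, m/s, > 0.
#' @param model Rheological model, see [segment_pressure_drop()].
#' @return An object of class `system_flow_profile`: list with `flow_rate`,
#'   `outlet_velocity`, `total_pressure` (Pa), `segments` (data frame of
#'   per-segment results) and `profile` (data frame: axial position from the
#'   piston face vs cumulative pressure).
#' @export
system_flow <- function(system, fluid, inlet_velocity,
                        model = c("power_law", "newtonian_K",
                                  "newtonian_avg_shear")) {
  stopifnot(inherits(system, "extrusion_system"),
            inherits(fluid, "power_law_fluid"))
  model <- match.arg(model)
  Q <- inlet_velocity * pi * system$piston_radius^2
  v_out <- outlet_velocity(system, inlet_velocity)
  gamma_ref <- average_shear_rate(2 * outlet_radius(system), v_out)
  segs <- system$segments
  res <- lapply(segs, function(s) {
    R_min <- min(s$radius_in, s$radius_out)
    ws <- wall_shear(fluid, R_min, Q)  # worst (narrowest) station of the segment
    dp <- segment_pressure_drop(fluid, s, Q, model = model,
                                reference_shear_rate = gamma_ref)
    data.frame(kind = s$kind, length = s$length, radius_out = s$radius_out,
               pressure_drop = dp, wall_shear_rate = ws$wall_shear_rate,
               wall_shear_stress = ws$wall_shear_stress,
               mean_velocity = Q / (pi * R_min^2),
               plug_fraction = plug_fraction(fluid))
  })
  res <- do.call(rbind, res)
  z_ends <- cumsum(res$length)
  total <- sum(res$pressure_drop)
  # pressure referenced to zero at the outlet; drops accumulate upstream
  cum_p <- c(total, total - cumsum(res$pressure_drop))
  profile <- data.frame(axial_position = c(0, z_ends), pressure = cum_p)
  structure(list(model = model, flow_rate = Q, outlet_velocity = v_out,
                 reference_shear_rate = gamma_ref, total_pressure = total,
                 segments = res, profile = profile),
            class = "system_flow_profile")
}

#' @export
print.system_flow_profile <- function(x, ...) {
  cat(sprintf("System flow (%s): Q = %.3g m^3/s, outlet velocity %.3g m/s\n",
              x$model, x$flow_rate, x$outlet_velocity))
  cat(sprintf("  total pressure drop: %.4g kPa\n", x$total_pressure / 1e3))
  cat(sprintf("  max wall shear stress: %.3g Pa\n",
              max(x$segments$wall_shear_stress)))
  invisible(x)
}

#' Relative modeling error between rheological models
#'
#' Signed percentage difference of a simplified model's pressure against the
#' power-law reference: 100 * (p_model - p_reference) / p_reference.
#'
#' @param p_model Pressure from the simplified model, Pa.
#' @param p_reference Power-law reference pressure, Pa, > 0.
#' @return Signed percentage.
#' @export
modeling_error <- function(p_model, p_reference) {
  if (any(p_reference <= 0)) stop("reference pressure must be positive")
  100 * (p_model - p_reference) / p_reference
}

#' Flow rate from a pressure gradient by radial quadrature (oracle)
#'
#' Independent check of the closed-form pressure-drop relation: given an axial
#' pressure gradient G, the shear stress profile in a pipe is tau(r) = G r / 2,
#' the shear-rate field gamma(r) = (tau/K)^(1/n), and the flow rate follows by
#' adaptive numerical quadrature of Q = pi * int_0^R r^2 gamma(r) dr
#' (integration by parts of the velocity integral with u(R) = 0). Inverts the
#' closed-form dp(Q) relation to well below 0.1% relative error.
#'
#' @param fluid A [power_law_fluid].
#' @param radius Pipe radius, m, > 0.
#' @param pressure_gradient Axial pressure-gradient magnitude, Pa/m, >= 0.
#' @return Volumetric flow rate, m^3/s.
#' @export
radial_quadrature_oracle <- function(fluid, radius, pressure_gradient) {
  stopifnot(inherits(fluid, "power_law_fluid"), radius > 0,
            pressure_gradient >= 0)
  if (pressure_gradient == 0) return(0)
  K <- fluid$K
  n <- fluid$n
  gamma_of_r <- function(r) (pressure_gradient * r / (2 * K))^(1 / n)
  q <- stats::integrate(function(r) r^2 * gamma_of_r(r), 0, radius,
                        rel.tol = 1e-10, abs.tol = 0)
  pi * q$value
}

#' Export a system flow profile to CSV
#'
#' Writes the axial cumulative-pressure profile and, optionally, a radial
#' velocity profile at the needle outlet.
#'
#' @param flow A `system_flow_profile` from [system_flow()].
#' @param path Output CSV path for the axial profile.
#' @return `path`, invisibly.
#' @export
write_flow_profile <- function(flow, path) {
  stopifnot(inherits(flow, "system_flow_profile"))
  utils::write.csv(flow$profile, path, row.names = FALSE)
  invisible(path)
}
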