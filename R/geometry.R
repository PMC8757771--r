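#' Axisymmetric extrusion-train segment
#'
#' One piece of the extrusion train (piston barrel, conical taper, or needle),
#' described as an axisymmetric cylinder or cone. All lengths in metres.
#'
#' @param kind `"cylinder"` or `"cone"`.
#' @param length Segment length along the flow axis, m, > 0.
#' @param radius_in Inner (upstream) radius, m, > 0.
#' @param radius_out Outlet (downstream) radius, m, > 0. For a cylinder it
#'   defaults to `radius_in` and must equal it.
#' @return An object of class `extrusion_segment`.
#' @export
extrusion_segment <- function(kind = c("cylinder", "cone"), length,
                              radius_in, radius_out = radius_in) {
  kind <- match.arg(kind)
  stopifnot(is.finite(length), length > 0,
            is.finite(radius_in), radius_in > 0,
            is.finite(radius_out), radius_out > 0)
  if (kind == "cylinder" && radius_in != radius_out) {
    stop("a cylinder must have radius_in == radius_out")
  }
  structure(list(kind = kind, length = length,
                 radius_in = radius_in, radius_out = radius_out),
            class = "extrusion_segment")
}

#' Extrusion system: ordered train from piston face to needle tip
#'
#' @param segments List of [extrusion_segment]s ordered from the piston face to
#'   the needle tip. Adjacent segments must be radius-continuous.
#' @return An object of class `extrusion_system`.
#' @seealso [default_extrusion_system()]
#' @export
extrusion_system <- function(segments) {
  if (length(segments) < 1L) stop("extrusion system needs at least one segment")
  for (s in segments) stopifnot(inherits(s, "extrusion_segment"))
  if (length(segments) > 1L) {
    for (i in seq_len(length(segments) - 1L)) {
      if (abs(segments[[i]]$radius_out - segments[[i + 1L]]$radius_in) >
          1e-12 * segments[[i]]$radius_out) {
        stop(sprintf("segments %d and %d are not radius-continuous", i, i + 1L))
      }
    }
  }
  structure(list(segments = segments,
                 piston_radius = segments[[1L]]$radius_in),
            class = "extrusion_system")
}

#' @export
print.extrusion_system <- function(x, ...) {
  cat(sprintf("Extrusion system: %d segments, piston radius %.3g mm, outlet radius %.3g mm\n",
              length(x$segments), 1e3 * x$piston_radius, 1e3 * outlet_radius(x)))
  for (s in x$segments) {
    cat(sprintf("  %-8s L = %6.2f mm, R = %.3g -> %.3g mm\n", s$kind,
                1e3 * s$length, 1e3 * s$radius_in, 1e3 * s$radius_out))
  }
  invisible(x)
}

#' Outlet (needle-tip) radius of an extrusion system
#' @param system An [extrusion_system].
#' @return Radius in metres.
#' @export
outlet_radius <- function(system) {
  stopifnot(inherits(system, "extrusion_system"))
  system$segments[[length(system$segments)]]$radius_out
}

#' Default syringe + needle extrusion train
#'
#' A 5-ml syringe (12 mm bore, 60 mm barrel) with a 10 mm conical taper down
#' to the needle, and a 16 mm cylindrical needle. The needle radius is the
#' only free parameter; 0.2 mm (0.4 mm nozzle) by default.
#'
#' @param needle_radius Needle inner radius, m.
#' @param barrel_radius Syringe bore radius, m.
#' @param barrel_length Barrel length, m.
#' @param taper_length Conical taper length, m.
#' @param needle_length Needle length, m.
#' @return An [extrusion_system].
#' @export
default_extrusion_system <- function(needle_radius = 0.2e-3,
                                     barrel_radius = 6e-3,
                                     barrel_length = 60e-3,
                                     taper_length = 10e-3,
                                     needle_length = 16e-3) {
  extrusion_system(list(
    extrusion_segment("cylinder", barrel_length, barrel_radius),
    extrusion_segment("cone", taper_length, barrel_radius, needle_radius),
    extrusion_segment("cylinder", needle_length, needle_radius)))
}

#' Printer hardware: lead-screw piston drive
#'
#' @param max_torque Motor stall torque, N.m, > 0.
#' @param pitch Lead-screw pitch, m, > 0.
#' @param efficiency Screw transmission efficiency in (0, 1\].
#' @param duty_fraction Fraction of the stall force usable in practice,
#'   in (0, 1\]. Default 0.8.
#' @return An object of class `printer_hardware`.
#' @export
printer_hardware <- function(max_torque = 0.40, pitch = 0.8e-3,
                             efficiency = 0.5, duty_fraction = 0.8) {
  stopifnot(is.finite(max_torque), max_torque > 0,
            is.finite(pitch), pitch > 0,
            is.finite(efficiency), efficiency > 0, efficiency <= 1,
            is.finite(duty_fraction), duty_fraction > 0, duty_fraction <= 1)
  structure(list(max_torque = max_torque, pitch = pitch,
                 efficiency = efficiency, duty_fraction = duty_fraction),
            class = "printer_hardware")
}

#' Outlet velocity by volume conservation
#'
#' The piston imposes a volumetric flow rate; the mean outlet velocity follows
#' from continuity: v_out = v_in * (piston area / outlet area).
#'
#' @param system An [extrusion_system].
#' @param inlet_velocity Piston (inlet) velocity, m/s, > 0.
#' @return Mean velocity at the needle tip, m/s.
#' @examples
#' sys <- default_extrusion_system(needle_radius = 0.2e-3)
#' outlet_velocity(sys, 1e-5)   # 9e-3 m/s: area ratio (6 / 0.2)^2 = 900
#' @export
outlet_velocity <- function(system, inlet_velocity) {
  stopifnot(inherits(system, "extrusion_system"),
            is.finite(inlet_velocity), inlet_velocity > 0)
  inlet_velocity * (system$piston_radius / outlet_radius(system))^2
}

#' Average (apparent) shear rate in a circular needle
#'
#' The Newtonian apparent wall shear rate 8V/D, used as the reference shear
#' rate of the constant-viscosity approximation (model 2).
#'
#' @param needle_diameter Needle inner diameter, m, > 0.
#' @param mean_velocity Mean velocity in the needle, m/s, > 0.
#' @return Shear rate, 1/s.
#' @export
average_shear_rate <- function(needle_diameter, mean_velocity) {
  stopifnot(is.finite(needle_diameter), needle_diameter > 0,
            is.finite(mean_velocity), mean_velocity > 0)
  8 * mean_velocity / needle_diameter
}

#' Maximum axial piston force of the lead-screw drive
#'
#' The standard screw conversion from torque to axial force is
#' F = efficiency * 2 * pi * T / pitch (one screw turn advances the nut by one
#' pitch, so the work balance carries a 2*pi). A `"literal"` convention
#' without the 2*pi factor (F = efficiency * T / pitch) is also exposed for
#' comparison with simpler force budgets.
#'
#' @param hw A [printer_hardware].
#' @param convention `"screw"` (default, with 2*pi) or `"literal"`.
#' @return Axial force, N.
#' @examples
#' max_piston_force(printer_hardware())           # 1570.8 N
#' max_piston_force(printer_hardware(), "literal") # 250 N
#' @export
max_piston_force <- function(hw, convention = c("screw", "literal")) {
  stopifnot(inherits(hw, "printer_hardware"))
  convention <- match.arg(convention)
  fac <- if (convention == "screw") 2 * pi else 1
  hw$efficiency * fac * hw$max_torque / hw$pitch
}

#' Available extrusion pressure
#'
#' Usable piston force (duty_fraction of the stall force) divided by the
#' piston area: the maximum pressure drop the drive can sustain.
#'
#' @param hw A [printer_hardware].
#' @param system An [extrusion_system].
#' @param convention Screw conversion, see [max_piston_force()].
#' @return Pressure, Pa.
#' @export
available_pressure <- function(hw, system, convention = c("screw", "literal")) {
  stopifnot(inherits(system, "extrusion_system"))
  force <- hw$duty_fraction * max_piston_force(hw, convention)
  force / (pi * system$piston_radius^2)
}
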