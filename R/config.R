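# Unit-tagged quantity parsing for config files. Numeric values are taken as
# SI; strings carry an explicit unit tag ("0.4 mm", "40 N cm", "7.5 mm/s").

si_quantity <- function(x, kind = c("length", "torque", "speed", "plain"),
                        what = "value") {
  kind <- match.arg(kind)
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L) {
    stop(sprintf("cannot parse %s: %s", what, deparse(x)))
  }
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(.*?)\\s*$", x))[[1]]
  if (length(m) != 3L || m[2] == "") stop(sprintf("cannot parse %s: '%s'", what, x))
  val <- as.numeric(m[2])
  unit <- gsub("\\s+", " ", m[3])
  scale <- switch(kind,
    length = switch(unit, "m" = 1, "mm" = 1e-3, "cm" = 1e-2, "um" = 1e-6, NA),
    torque = switch(unit, "N m" = 1, "N cm" = 1e-2, "N mm" = 1e-3, NA),
    speed  = switch(unit, "m/s" = 1, "mm/s" = 1e-3, "cm/s" = 1e-2, NA),
    plain  = if (unit == "") 1 else NA)
  if (unit == "") return(val)  # bare number (possibly YAML-stringified): SI
  if (is.na(scale)) stop(sprintf("unknown unit '%s' for %s", unit, what))
  val * scale
}

#' Wood-pile scaffold unit cell
#'
#' Cross-sectional slicing parameters of a layered 0/90 strand lattice: strand
#' (nozzle) width, layer height, centre-to-centre inter-fiber distance and
#' layer count. Used by the collapse finite-element model.
#'
#' @param strand_width Deposited strand width, m (typically the nozzle size).
#' @param layer_height Slicing layer height, m; must not exceed `strand_width`
#'   (layers overlap vertically).
#' @param inter_fiber_distance Centre-to-centre strand spacing, m; must exceed
#'   `strand_width` so pores remain open.
#' @param n_layers Number of printed layers, >= 1.
#' @param out_of_plane_thickness Plane-strain slab thickness, m. Default 1 mm.
#' @return An object of class `scaffold_cell`.
#' @export
scaffold_cell <- function(strand_width = 0.77e-3, layer_height = 0.55e-3,
                          inter_fiber_distance = 2.57e-3, n_layers = 6L,
                          out_of_plane_thickness = 1e-3) {
  stopifnot(strand_width > 0, layer_height > 0, inter_fiber_distance > 0,
            n_layers >= 1, out_of_plane_thickness > 0)
  if (layer_height > strand_width) {
    stop("layer_height must not exceed strand_width (layers must overlap)")
  }
  if (inter_fiber_distance <= strand_width) {
    stop("inter_fiber_distance must exceed strand_width (open pores)")
  }
  structure(list(strand_width = strand_width, layer_height = layer_height,
                 inter_fiber_distance = inter_fiber_distance,
                 n_layers = as.integer(n_layers),
                 out_of_plane_thickness = out_of_plane_thickness),
            class = "scaffold_cell")
}

#' Read a printability configuration file
#'
#' YAML configuration with sections `hardware`, `segments`, `material`,
#' `scaffold` and optional scalars `inlet_velocity` and `thresholds`. Lengths,
#' torques and speeds may be numeric (SI) or unit-tagged strings such as
#' `"0.4 mm"`, `"40 N cm"`, `"7.5 mm/s"`.
#'
#' @param path Path to the YAML file.
#' @return A list with components `hardware` ([printer_hardware]), `system`
#'   ([extrusion_system]), `material` (list; `fluid` is a [power_law_fluid] if
#'   K/n are given, `kv` a [kelvin_voigt] if E/eta0 are given, `support_kv`
#'   likewise from a `support` block), `scaffold` ([scaffold_cell] or NULL),
#'   `inlet_velocity` (m/s) and `thresholds`.
#' @export
read_print_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  hw <- if (!is.null(cfg$hardware)) {
    h <- cfg$hardware
    printer_hardware(
      max_torque = si_quantity(h$max_torque, "torque", "max_torque"),
      pitch = si_quantity(h$pitch, "length", "pitch"),
      efficiency = si_quantity(h$efficiency %||% 0.5, "plain"),
      duty_fraction = si_quantity(h$duty_fraction %||% 0.8, "plain"))
  } else printer_hardware()
  sys <- if (!is.null(cfg$segments)) {
    segs <- lapply(cfg$segments, function(s) {
      r_in <- si_quantity(s$radius_in %||% s$radius, "length", "radius_in")
      r_out <- si_quantity(s$radius_out %||% s$radius, "length", "radius_out")
      extrusion_segment(s$kind %||% "cylinder",
                        length = si_quantity(s$length, "length", "length"),
                        radius_in = r_in, radius_out = r_out)
    })
    extrusion_system(segs)
  } else default_extrusion_system()
  material <- list(fluid = NULL, kv = NULL, support_kv = NULL)
  if (!is.null(cfg$material)) {
    m <- fix_yaml11_keys(cfg$material)
    if (!is.null(m[["K"]]) && !is.null(m[["n"]])) {
      material$fluid <- power_law_fluid(K = as.numeric(m[["K"]]),
                                        n = as.numeric(m[["n"]]),
                                        label = m$label)
    }
    material$kv <- config_kv(m)
    if (!is.null(m$support)) material$support_kv <- config_kv(m$support)
  }
  scaffold <- if (!is.null(cfg$scaffold)) {
    s <- cfg$scaffold
    scaffold_cell(
      strand_width = si_quantity(s$strand_width, "length", "strand_width"),
      layer_height = si_quantity(s$layer_height, "length", "layer_height"),
      inter_fiber_distance = si_quantity(s$inter_fiber_distance, "length",
                                         "inter_fiber_distance"),
      n_layers = as.integer(s$n_layers %||% 6L))
  } else NULL
  thresholds <- list(
    shear_stress = as.numeric(cfg$thresholds$shear_stress %||% 80),
    collapse_strain = as.numeric(cfg$thresholds$collapse_strain %||% 0.05))
  list(hardware = hw, system = sys, material = material, scaffold = scaffold,
       inlet_velocity = if (!is.null(cfg$inlet_velocity))
         si_quantity(cfg$inlet_velocity, "speed", "inlet_velocity") else 1e-5,
       thresholds = thresholds)
}

# YAML 1.1 parses the bare keys n/y/no/yes as booleans; map the resulting
# "TRUE"/"FALSE" names back to the intended rheological keys.
fix_yaml11_keys <- function(m) {
  nm <- names(m)
  nm[nm == "FALSE"] <- "n"
  names(m) <- nm
  m
}

config_kv <- function(m) {
  m <- fix_yaml11_keys(m)
  nu <- as.numeric(m[["nu"]] %||% 0.49)
  rho <- as.numeric(m[["rho"]] %||% 1000)
  if (!is.null(m[["E"]]) && !is.null(m[["eta0"]])) {
    kelvin_voigt(E = as.numeric(m[["E"]]), eta0 = as.numeric(m[["eta0"]]),
                 nu = nu, rho = rho, label = m$label)
  } else if (!is.null(m[["G0"]]) && !is.null(m[["eta0"]])) {
    kelvin_voigt_from_moduli(G0 = as.numeric(m[["G0"]]),
                             eta0 = as.numeric(m[["eta0"]]),
                             nu = nu, rho = rho, label = m$label)
  } else NULL
}

#' Echo a parsed configuration as JSON (provenance record)
#'
#' @param config A list as returned by [read_print_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
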