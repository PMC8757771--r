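# Seeded generators emulating the statistical structure of the measured data
# (Herschel-Bulkley-like flow sweeps, line-width tables) plus the reference
# parameter fixtures, so the whole pipeline runs without any measured input.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# lognormal multiplier with unit mean and coefficient of variation cv
lognormal_noise <- function(k, cv) {
  if (cv == 0) return(rep(1, k))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic flow-sweep curve
#'
#' Emulates a rheometer flow sweep of a yield-stress, shear-thinning gel:
#' stress tau = tau_y + K * rate^n on a log-spaced rate grid, viscosity
#' tau / rate, corrupted by multiplicative lognormal noise of the given
#' coefficient of variation. Deterministic for a fixed seed.
#'
#' @param tau_y Yield stress, Pa, >= 0.
#' @param K Consistency index, Pa.s^n, > 0.
#' @param n Behavior index, > 0.
#' @param rate_range Shear-rate span, 1/s; default 0.01-2000, the usual
#'   flow-sweep window for these gels.
#' @param n_points Number of log-spaced points. Default 50.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#'   Default 0.02 (2%).
#' @param seed Integer seed.
#' @return A [flow_curve].
#' @examples
#' fc <- gen_flow_curve(K = 5.78, n = 0.12, noise_cv = 0, seed = 1)
#' fit_power_law(fc)
#' @export
gen_flow_curve <- function(tau_y = 0, K, n, rate_range = c(0.01, 2000),
                           n_points = 50L, noise_cv = 0.02, seed = 1L) {
  stopifnot(tau_y >= 0, K > 0, n > 0, noise_cv >= 0, n_points >= 2L,
            rate_range[1] > 0, rate_range[2] > rate_range[1])
  rate <- 10^seq(log10(rate_range[1]), log10(rate_range[2]),
                 length.out = n_points)
  stress <- tau_y + K * rate^n
  noise <- with_seed(seed, lognormal_noise(n_points, noise_cv))
  flow_curve(rate, shear_stress = stress * noise)
}

#' Generate a synthetic printed-line-width table
#'
#' Full factorial design over nozzle diameters and print speeds with the
#' requested replicate count. Widths follow the volumetric-slicing null model:
#' proportional to the nozzle diameter, independent of speed, with
#' multiplicative lognormal measurement noise.
#'
#' @param nozzle_diameters Nozzle diameters, m. Default the 0.34 / 0.40 /
#'   0.47 mm set of the line-characterization design.
#' @param print_speeds Print speeds (units free; carried through). Default
#'   7.5 / 10 / 20 mm/s.
#' @param replicates Images measured per condition. Default 15.
#' @param width_multiplier Width / nozzle ratio. Default 1.1.
#' @param noise_cv Coefficient of variation of the width measurement.
#'   Default 0.05.
#' @param seed Integer seed.
#' @return Data frame with columns `nozzle_diameter`, `print_speed`,
#'   `measured_width` (one row per replicate).
#' @export
gen_line_width_table <- function(nozzle_diameters = c(0.34e-3, 0.40e-3, 0.47e-3),
                                 print_speeds = c(7.5e-3, 10e-3, 20e-3),
                                 replicates = 15L, width_multiplier = 1.1,
                                 noise_cv = 0.05, seed = 1L) {
  stopifnot(all(nozzle_diameters > 0), replicates >= 1L,
            width_multiplier > 0, noise_cv >= 0)
  design <- expand.grid(nozzle_diameter = nozzle_diameters,
                        print_speed = print_speeds,
                        replicate = seq_len(replicates))
  noise <- with_seed(seed, lognormal_noise(nrow(design), noise_cv))
  design$measured_width <- width_multiplier * design$nozzle_diameter * noise
  design[c("nozzle_diameter", "print_speed", "measured_width")]
}

#' Reference parameter fixtures for the peptide-gel printing study
#'
#' The single in-package source of the published characterization constants:
#' the six fitted power-law gels (two concentrations x three pH values), the
#' seven Kelvin-Voigt lumped parameter sets (six gels plus the PVA-PVP
#' sacrificial support bath), the default syringe-and-needle extrusion train,
#' the lead-screw printer hardware, the scaffold slicing cell and the print
#' settings used for line characterization and complex-structure printing.
#' Each gel record carries its concentration / pH provenance label.
#'
#' @return A list with components `gels` (named list of [power_law_fluid]),
#'   `kv` (named list of [kelvin_voigt]; `support` is the PVA-PVP bath),
#'   `system` ([extrusion_system]), `needle_radii` (m), `hardware`
#'   ([printer_hardware]), `cell` ([scaffold_cell]) and `print_settings`.
#' @examples
#' fx <- f9_fixtures()
#' fx$gels[["C30_pH4.9"]]
#' @export
f9_fixtures <- function() {
  gel_tab <- data.frame(
    label = c("C20_pH3.7", "C20_pH4.8", "C20_pH4.9",
              "C30_pH3.7", "C30_pH4.8", "C30_pH4.9"),
    K = c(5.78, 13.46, 16.83, 13.91, 21.18, 41.98),
    n = c(0.12, 0.05, 0.02, 0.04, 0.02, 0.02))
  gels <- lapply(seq_len(nrow(gel_tab)), function(i) {
    power_law_fluid(K = gel_tab$K[i], n = gel_tab$n[i], label = gel_tab$label[i])
  })
  names(gels) <- gel_tab$label

  kv_tab <- data.frame(
    label = c(gel_tab$label, "support"),
    eta0 = c(231.4, 895, 1124, 981.4, 1848.4, 5237.4, 1500),
    G0 = c(15, 55.5, 130, 64.5, 125, 369, 500),
    E = c(30, 111, 260, 129, 250, 738, 1000))
  kv <- lapply(seq_len(nrow(kv_tab)), function(i) {
    kelvin_voigt(E = kv_tab$E[i], eta0 = kv_tab$eta0[i], nu = 0.49,
                 rho = 1000, G0 = kv_tab$G0[i], label = kv_tab$label[i])
  })
  names(kv) <- kv_tab$label

  list(
    gels = gels,
    kv = kv,
    system = default_extrusion_system(needle_radius = 0.2e-3),
    needle_radii = c(0.13e-3, 0.17e-3, 0.2e-3, 0.235e-3),
    hardware = printer_hardware(max_torque = 0.40, pitch = 0.8e-3,
                                efficiency = 0.5, duty_fraction = 0.8),
    cell = scaffold_cell(strand_width = 0.77e-3, layer_height = 0.55e-3,
                         inter_fiber_distance = 2.57e-3, n_layers = 6L),
    print_settings = list(
      inlet_velocity = 1e-5,
      line_design = list(nozzle_diameters = c(0.34e-3, 0.40e-3, 0.47e-3),
                         print_speeds = c(7.5e-3, 10e-3, 20e-3),
                         replicates = 15L),
      flow_multiplier = 1.5,
      ear_models = data.frame(
        model = c("model1", "model2", "model3"),
        nozzle = c(0.77e-3, 0.47e-3, 0.77e-3),
        layer_height = c(0.55e-3, 0.35e-3, 0.55e-3),
        n_layers = c(22L, 34L, 22L),
        fill_density = c(0.30, 0.25, 0.30),
        perimeters = c(1L, 1L, 0L))))
}

#' Export the fixture bundle as JSON
#'
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fixtures_json <- function(path) {
  fx <- f9_fixtures()
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(fx), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
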