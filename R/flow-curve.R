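#' Construct a flow curve
#'
#' A flow curve holds paired shear-rate / apparent-viscosity measurements from
#' a rotational rheometer flow sweep, the raw material for power-law and
#' Herschel-Bulkley fitting.
#'
#' @param shear_rate Numeric vector of shear rates (1/s), strictly positive and
#'   strictly increasing.
#' @param viscosity Numeric vector of apparent viscosities (Pa.s), positive,
#'   same length as `shear_rate`. May be omitted if `shear_stress` is given.
#' @param shear_stress Optional numeric vector of shear stresses (Pa). If
#'   `viscosity` is missing it is derived as `shear_stress / shear_rate`.
#' @param temperature Optional temperature metadata (degrees C).
#'
#' @return An object of class `flow_curve`: a data frame with columns
#'   `shear_rate`, `viscosity` and `shear_stress`.
#' @examples
#' fc <- flow_curve(c(0.1, 1, 10, 100), 5.78 * c(0.1, 1, 10, 100)^(0.12 - 1))
#' fit_power_law(fc)
#' @export
flow_curve <- function(shear_rate, viscosity = NULL, shear_stress = NULL,
                       temperature = NA_real_) {
  shear_rate <- as.numeric(shear_rate)
  if (length(shear_rate) == 0L) stop("flow curve needs at least one point")
  if (any(!is.finite(shear_rate)) || any(shear_rate <= 0)) {
    stop("shear_rate must be finite and strictly positive")
  }
  if (is.unsorted(shear_rate, strictly = TRUE)) {
    stop("shear_rate must be strictly increasing")
  }
  if (is.null(viscosity)) {
    if (is.null(shear_stress)) stop("supply viscosity or shear_stress")
    shear_stress <- as.numeric(shear_stress)
    viscosity <- shear_stress / shear_rate
  } else {
    viscosity <- as.numeric(viscosity)
    if (is.null(shear_stress)) shear_stress <- viscosity * shear_rate
  }
  if (length(viscosity) != length(shear_rate) ||
      length(shear_stress) != length(shear_rate)) {
    stop("shear_rate, viscosity and shear_stress must have equal length")
  }
  if (any(!is.finite(viscosity)) || any(viscosity <= 0)) {
    stop("viscosity must be finite and strictly positive")
  }
  out <- data.frame(shear_rate = shear_rate, viscosity = viscosity,
                    shear_stress = shear_stress)
  attr(out, "temperature") <- temperature
  class(out) <- c("flow_curve", "data.frame")
  out
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("Flow curve: %d points, shear rate %.3g-%.3g 1/s\n",
              nrow(x), min(x$shear_rate), max(x$shear_rate)))
  temp <- attr(x, "temperature")
  if (!is.na(temp)) cat(sprintf("  temperature: %g degC\n", temp))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read / write flow-curve CSV files
#'
#' The CSV dialect is a header row with columns `shear_rate` and `viscosity`
#' (optionally `shear_stress`), comma separated, `.` decimal, SI units.
#'
#' @param path File path.
#' @return `read_flow_curve` returns a [flow_curve]; `write_flow_curve`
#'   invisibly returns `path`.
#' @export
read_flow_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("shear_rate", "viscosity") %in% names(df)) &&
      !all(c("shear_rate", "shear_stress") %in% names(df))) {
    stop("flow-curve CSV needs columns shear_rate and viscosity (or shear_stress)")
  }
  flow_curve(df$shear_rate, viscosity = df$viscosity,
             shear_stress = df$shear_stress)
}

#' @rdname read_flow_curve
#' @param curve A [flow_curve].
#' @export
write_flow_curve <- function(curve, path) {
  stopifnot(inherits(curve, "flow_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
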