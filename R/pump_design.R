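#' Size a radial impeller for a duty point
#'
#' Runs the full design calculus for one impeller at one operating point:
#' specific work from the pressure rise, blade-passage flow, required
#' rotational speed under the slip-corrected work expression, Cordier
#' similarity numbers, radial/non-radial classification and the optimal eye
#' radius for the computed speed.
#'
#' @param op an [operating_point()].
#' @param geometry an [impeller_geometry()].
#' @param fluid a [fluid_properties()].
#' @param constants a [design_constants()].
#' @return object of class `pump_design` with fields `specific_work` (m^2/s^2),
#'   `omega` (rad/s), `speed_rpm`, `diameter_number`, `specific_speed`,
#'   `classification`, `eye_radius` (m, the optimum for the computed speed),
#'   `blade_flow` (m^3/s) and the inputs.
#' @examples
#' d <- pump_design(operating_point(5, 350), impeller_geometry())
#' d
#' predict(d, flow_l_min = c(0, 5, 9))
#' @export
pump_design <- function(op = operating_point(),
                        geometry = impeller_geometry(),
                        fluid = fluid_properties(),
                        constants = design_constants()) {
  stopifnot(inherits(op, "operating_point"),
            inherits(geometry, "impeller_geometry"),
            inherits(fluid, "fluid_properties"),
            inherits(constants, "design_constants"))
  Y <- specific_work_from_pressure(op$pressure_rise, fluid$density)
  q_bl <- blade_passage_flow(op$flow_rate, constants)
  omega <- required_speed(Y, geometry, q_bl, constants)
  dM <- diameter_number(2 * geometry$r2, Y, op$flow_rate)
  sM <- specific_speed(omega, Y, op$flow_rate)
  structure(list(
    specific_work = Y,
    blade_flow = q_bl,
    omega = omega,
    speed_rpm = rads_to_rpm(omega),
    diameter_number = dM,
    specific_speed = sM,
    classification = classify_impeller(dM),
    eye_radius = optimal_eye_radius(q_bl, omega, geometry$alpha1_deg),
    operating_point = op, geometry = geometry,
    fluid = fluid, constants = constants
  ), class = "pump_design")
}

#' @export
print.pump_design <- function(x, ...) {
  cat("Radial impeller design\n")
  cat(sprintf("  duty point:       %.2f l/min at %.1f mmHg (%s, rho = %g kg/m^3)\n",
              m3s_to_lmin(x$operating_point$flow_rate),
              pa_to_mmhg(x$operating_point$pressure_rise),
              x$fluid$name, x$fluid$density))
  cat(sprintf("  specific work Y:  %.2f m^2/s^2\n", x$specific_work))
  cat(sprintf("  required speed:   %.0f rpm (%.1f rad/s)\n", x$speed_rpm, x$omega))
  cat(sprintf("  diameter number:  %.2f (%s)\n", x$diameter_number,
              x$classification))
  cat(sprintf("  specific speed:   %.3f\n", x$specific_speed))
  cat(sprintf("  optimal eye r1:   %.2f mm\n", x$eye_radius * 1000))
  invisible(x)
}

#' @export
summary.pump_design <- function(object, ...) {
  g <- object$geometry
  out <- list(
    design = object,
    geometry = data.frame(
      r1_mm = g$r1 * 1000, r2_mm = g$r2 * 1000, h_bl_mm = g$h_bl * 1000,
      beta_2B_deg = g$beta_2B_deg, blades = g$z),
    slip = slip_factor(g$beta_2B_deg, object$constants, g$z))
  class(out) <- "summary.pump_design"
  out
}

#' @export
print.summary.pump_design <- function(x, ...) {
  print(x$design)
  cat("  geometry:\n")
  print(x$geometry, row.names = FALSE)
  cat(sprintf("  slip factor mu:   %.4f (%s)\n", x$slip,
              x$design$constants$slip_model))
  invisible(x)
}

#' Theoretical characteristic of a sized design
#'
#' @param object a [pump_design()].
#' @param flow_l_min delivered flows in l/min at which to evaluate the
#'   theoretical pressure rise.
#' @param ... unused.
#' @return data.frame from [theoretical_characteristic()].
#' @export
predict.pump_design <- function(object, flow_l_min = seq(0, 9, by = 0.5), ...) {
  theoretical_characteristic(object$omega, object$geometry, object$constants,
                             flow_l_min, object$fluid)
}

#' @export
plot.pump_design <- function(x, flow_l_min = seq(0, 9, by = 0.25), ...) {
  ch <- predict(x, flow_l_min)
  graphics::plot(ch$flow_l_min, ch$pressure_mmHg, type = "l",
                 xlab = "Flow (l/min)", ylab = "Pressure rise (mmHg)",
                 main = "Theoretical characteristic", ...)
  graphics::points(m3s_to_lmin(x$operating_point$flow_rate),
                   pa_to_mmhg(x$operating_point$pressure_rise), pch = 4)
  invisible(ch)
}

#' Read a design configuration from YAML
#'
#' Accepts the layout
#' `operating_point: {flow_l_min, pressure_mmHg}`, `fluid: {density_kg_m3}`,
#' `geometry: {...}` (arguments of [impeller_geometry()]) and
#' `constants: {...}` (arguments of [design_constants()]); missing blocks fall
#' back to the package defaults.
#'
#' @param path path to a YAML file.
#' @return list with elements `op`, `geometry`, `fluid`, `constants`, ready
#'   for [pump_design()].
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(f, args) do.call(f, args %||% list())
  list(op = build(operating_point, cfg$operating_point),
       geometry = build(impeller_geometry, cfg$geometry),
       fluid = build(fluid_properties, cfg$fluid),
       constants = build(design_constants, cfg$constants))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
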