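# Turbomachinery design calculus for radial blood-pump impellers: Euler
# specific work with slip, Cordier similarity numbers, required rotational
# speed, inlet (eye) optimization and theoretical characteristics.

# beta is stored in radians; the 90-degree outlet angle is an exact symbolic
# case (the 1/tan term is identically zero), not a large-float approximation.
is_radial_outlet <- function(beta) abs(beta - pi / 2) < 1e-12

#' Specific work from a pressure rise
#'
#' Y = delta_p / rho, the pump energy per unit fluid mass.
#'
#' @param pressure_rise_pa pressure rise in Pa (use [mmhg_to_pa()] at the
#'   boundary).
#' @param density_kg_m3 fluid density in kg/m^3.
#' @return specific work Y in m^2/s^2.
#' @examples
#' specific_work_from_pressure(mmhg_to_pa(350), 1060)  # 44.02
#' @export
specific_work_from_pressure <- function(pressure_rise_pa, density_kg_m3) {
  if (any(density_kg_m3 <= 0)) stop_invalid("density must be positive")
  if (any(pressure_rise_pa < 0)) stop_invalid("pressure rise must be non-negative")
  pressure_rise_pa / density_kg_m3
}

#' Euler specific work from velocity triangles
#'
#' Y_th = u2 * v_theta2 - u1 * v_theta1: the work a blade row transfers per
#' unit mass, from the circumferential momentum change between inlet and
#' outlet.
#'
#' @param outlet,inlet [velocity_triangle()] objects with `u` and `v_theta`
#'   set; `outlet` at station 2, `inlet` at station 1.
#' @return theoretical specific work in m^2/s^2.
#' @export
euler_specific_work <- function(outlet, inlet) {
  stopifnot(inherits(outlet, "velocity_triangle"),
            inherits(inlet, "velocity_triangle"))
  for (tr in list(outlet, inlet))
    if (is.na(tr$u) || is.na(tr$v_theta))
      stop_invalid("both triangles need u and v_theta")
  outlet$u * outlet$v_theta - inlet$u * inlet$v_theta
}

#' Blade-passage flow from net flow
#'
#' Q_bl = Q_net / eta_vol: the flow actually crossing the blade passage,
#' including gap leakage recirculation.
#'
#' @param net_flow_m3s delivered flow in m^3/s.
#' @param constants a [design_constants()].
#' @return blade-passage flow in m^3/s.
#' @export
blade_passage_flow <- function(net_flow_m3s, constants = design_constants()) {
  stopifnot(inherits(constants, "design_constants"))
  if (any(net_flow_m3s < 0)) stop_invalid("net flow must be non-negative")
  net_flow_m3s / constants$eta_vol
}

#' Theoretical specific work of a radial impeller
#'
#' Y_th = (omega r2)^2 - omega Q_bl / (2 pi h_bl tan(beta_2B)), the Euler work
#' under zero inlet swirl with the outlet triangle expressed through geometry.
#' At beta_2B = 90 degrees the flow-dependent term is identically zero.
#'
#' @param omega rotational speed in rad/s.
#' @param geometry an [impeller_geometry()].
#' @param blade_flow_m3s blade-passage flow Q_bl in m^3/s.
#' @return theoretical specific work in m^2/s^2.
#' @export
theoretical_specific_work <- function(omega, geometry, blade_flow_m3s) {
  stopifnot(inherits(geometry, "impeller_geometry"))
  if (omega <= 0) stop_invalid("omega must be positive")
  (omega * geometry$r2)^2 - omega * flow_term(geometry, blade_flow_m3s)

}

# Q-coefficient of the specific-work expressions:
# Q_bl / (2 pi h_bl tan(beta_2B)), exactly 0 for the 90-degree outlet.
flow_term <- function(geometry, blade_flow_m3s) {
  if (is_radial_outlet(geometry$beta_2B)) return(0)
  if (geometry$h_bl <= 0)
    stop_invalid("blade height must be positive for beta_2B < 90 degrees")
  blade_flow_m3s / (2 * pi * geometry$h_bl * tan(geometry$beta_2B))
}

#' Slip factor of a radial impeller
#'
#' The flow leaves the blades at less circumferential velocity than the blade
#' angle implies; the deficit is mu * u2. Two correlations are provided:
#'
#' * `paper_printed`: mu = 1 - f1 (1 - sqrt(sin beta_2B)) kW. Degenerate at
#'   beta_2B = 90 degrees, where it returns mu = 1 (no work transfer).
#' * `bladed_wiesner` (default): the Wiesner/Guelich blade-count form,
#'   (1 - mu) = f1 (1 - sqrt(sin beta_2B) / z^0.7) kW.
#'
#' @param beta_2B_deg blade outlet angle in degrees, in (0, 90].
#' @param constants a [design_constants()]; its `slip_model` selects the
#'   correlation.
#' @param blade_count number of blades z (used by `bladed_wiesner`).
#' @return slip factor mu (dimensionless).
#' @export
slip_factor <- function(beta_2B_deg, constants = design_constants(),
                        blade_count = 6L) {
  stopifnot(inherits(constants, "design_constants"))
  if (any(beta_2B_deg <= 0 | beta_2B_deg > 90))
    stop_invalid("blade outlet angle must lie in (0, 90] degrees")
  s <- sqrt(sin(deg_to_rad(beta_2B_deg)))
  if (constants$slip_model == "paper_printed") {
    1 - constants$f1 * (1 - s) * constants$kW
  } else {
    if (any(blade_count < 2))
      stop_invalid("bladed slip correlation requires blade count >= 2")
    1 - constants$f1 * (1 - s / blade_count^0.7) * constants$kW
  }
}

#' Specific work with slip
#'
#' Y = (1 - mu)(omega r2)^2 - omega Q_bl / (2 pi h_bl tan(beta_2B)): the
#' deliverable specific work after the slip correction. Never exceeds
#' [theoretical_specific_work()] with the same arguments. At a 90-degree
#' outlet angle the result is independent of the blade height.
#'
#' @inheritParams theoretical_specific_work
#' @param constants a [design_constants()].
#' @return specific work Y in m^2/s^2.
#' @export
specific_work_with_slip <- function(omega, geometry, blade_flow_m3s,
                                    constants = design_constants()) {
  mu <- slip_factor(geometry$beta_2B_deg, constants, geometry$z)
  if (omega <= 0) stop_invalid("omega must be positive")
  (1 - mu) * (omega * geometry$r2)^2 - omega * flow_term(geometry, blade_flow_m3s)
}

#' Rotational speed required for a target specific work
#'
#' Inverts the slip-corrected work expression: solves
#' (1 - mu) r2^2 omega^2 - [Q_bl / (2 pi h_bl tan beta)] omega - Y = 0
#' for its unique positive root. Substituting the result back recovers the
#' target to machine precision.
#'
#' @param target_Y required specific work in m^2/s^2.
#' @param geometry an [impeller_geometry()].
#' @param blade_flow_m3s blade-passage flow in m^3/s.
#' @param constants a [design_constants()].
#' @return omega in rad/s.
#' @export
required_speed <- function(target_Y, geometry, blade_flow_m3s,
                           constants = design_constants()) {
  if (target_Y <= 0) stop_invalid("target specific work must be positive")
  mu <- slip_factor(geometry$beta_2B_deg, constants, geometry$z)
  a <- (1 - mu) * geometry$r2^2
  if (a <= 0)
    stop(errorCondition(
      paste0("no positive work coefficient: slip factor mu = ", signif(mu, 6),
             " leaves (1 - mu) <= 0 (the printed slip form is degenerate at",
             " a 90-degree outlet; use the bladed correlation)"),
      class = c("hemopump_no_solution", "error")))
  b <- flow_term(geometry, blade_flow_m3s)
  # a w^2 - b w - Y = 0, a > 0, Y > 0: one positive root
  (b + sqrt(b^2 + 4 * a * target_Y)) / (2 * a)
}

#' Required-speed map over blade angle and blade height
#'
#' Evaluates [required_speed()] (reported in rpm) on a grid of blade outlet
#' angles and blade heights, keeping all other geometry fixed. The optimal
#' (minimum-rpm) and worst (maximum-rpm) cells are reported; ties break
#' towards the smallest angle, then the smallest height.
#'
#' @param beta_grid_deg strictly increasing blade outlet angles in degrees.
#' @param h_bl_grid_mm strictly increasing blade heights in mm.
#' @param target_Y required specific work in m^2/s^2.
#' @param geometry template [impeller_geometry()] supplying r2 and blade
#'   count.
#' @param blade_flow_m3s blade-passage flow in m^3/s.
#' @param constants a [design_constants()].
#' @return object of class `speed_map`: a matrix of speeds in rpm (rows =
#'   angles, columns = heights) with `optimal` and `worst` grid cells as
#'   attributes.
#' @export
speed_map <- function(beta_grid_deg, h_bl_grid_mm, target_Y, geometry,
                      blade_flow_m3s, constants = design_constants()) {
  check_grid <- function(g, what) {
    if (length(g) < 1 || any(diff(g) <= 0))
      stop_invalid(what, " grid must be non-empty and strictly increasing")
  }
  check_grid(beta_grid_deg, "angle")
  check_grid(h_bl_grid_mm, "height")
  m <- matrix(NA_real_, length(beta_grid_deg), length(h_bl_grid_mm),
              dimnames = list(beta_deg = format(beta_grid_deg),
                              h_bl_mm = format(h_bl_grid_mm)))
  for (i in seq_along(beta_grid_deg)) {
    for (j in seq_along(h_bl_grid_mm)) {
      g <- impeller_geometry(
        eye_radius_mm = geometry$r1 * 1000,
        outer_radius_mm = geometry$r2 * 1000,
        blade_height_mm = h_bl_grid_mm[j],
        blade_outlet_angle_deg = beta_grid_deg[i],
        blade_count = geometry$z,
        inlet_flow_angle_deg = geometry$alpha1_deg)
      m[i, j] <- rads_to_rpm(required_speed(target_Y, g, blade_flow_m3s, constants))
    }
  }
  # ties break towards smaller beta then smaller h_bl: column-major order of
  # the (beta, h) grid already enumerates beta fastest, so scan explicitly
  pick <- function(target) {
    idx <- which(m == target, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    c(beta_deg = beta_grid_deg[idx[1]], h_bl_mm = h_bl_grid_mm[idx[2]],
      rpm = target)
  }
  structure(m, class = c("speed_map", "matrix"),
            optimal = pick(min(m)), worst = pick(max(m)))
}

#' @export
print.speed_map <- function(x, ...) {
  cat("Required-speed map (rpm); rows: beta_2B (deg), columns: h_bl (mm)\n")
  print(round(unclass(x), 0), ...)
  opt <- attr(x, "optimal"); wst <- attr(x, "worst")
  cat(sprintf("optimal: %.0f rpm at beta = %g deg, h_bl = %g mm\n",
              opt["rpm"], opt["beta_deg"], opt["h_bl_mm"]))
  cat(sprintf("worst:   %.0f rpm at beta = %g deg, h_bl = %g mm\n",
              wst["rpm"], wst["beta_deg"], wst["h_bl_mm"]))
  invisible(x)
}

#' Cordier diameter number
#'
#' delta_M = d2 sqrt(pi)/2 * (2Y)^(1/4) / Q^(1/2): the dimensionless
#' similarity number locating an impeller diameter on the Cordier diagram.
#'
#' @param d2_m impeller outer diameter in m.
#' @param Y specific work in m^2/s^2.
#' @param Q_m3s flow rate in m^3/s.
#' @return diameter number (dimensionless).
#' @examples
#' diameter_number(0.022, 44.02, lmin_to_m3s(5))  # 6.54
#' @export
diameter_number <- function(d2_m, Y, Q_m3s) {
  if (any(c(d2_m, Y, Q_m3s) <= 0)) stop_invalid("all arguments must be positive")
  d2_m * sqrt(pi) / 2 * (2 * Y)^0.25 / sqrt(Q_m3s)
}

#' Cordier specific speed
#'
#' sigma_M = omega / sqrt(pi) * Q^(1/2) / (2Y)^(3/4).
#'
#' @param omega rotational speed in rad/s.
#' @param Y specific work in m^2/s^2.
#' @param Q_m3s flow rate in m^3/s.
#' @return specific speed (dimensionless).
#' @examples
#' specific_speed(rpm_to_rads(7310), 44.02, lmin_to_m3s(5))  # ~0.137
#' @export
specific_speed <- function(omega, Y, Q_m3s) {
  if (any(c(omega, Y, Q_m3s) <= 0)) stop_invalid("all arguments must be positive")
  omega / sqrt(pi) * sqrt(Q_m3s) / (2 * Y)^0.75
}

#' Classify an impeller from its diameter number
#'
#' Radial impellers are best suited for diameter numbers above 3.5 on the
#' Cordier diagram; the inequality is strict.
#'
#' @param delta_M diameter number.
#' @return `"radial"` or `"non_radial"`.
#' @export
classify_impeller <- function(delta_M) {
  if (any(delta_M <= 0)) stop_invalid("diameter number must be positive")
  ifelse(delta_M > 3.5, "radial", "non_radial")
}

#' Relative velocity at the blade leading edge
#'
#' Inlet velocity triangle: v_m1 = Q_bl / (pi r1^2), u1 = r1 omega,
#' w1 = sqrt(v_m1^2 + (u1 - v_m1 / tan(alpha1))^2). With zero inlet swirl
#' (alpha1 = 90 degrees) the swirl term vanishes exactly.
#'
#' @param r1_m eye radius in m.
#' @param omega rotational speed in rad/s.
#' @param blade_flow_m3s blade-passage flow in m^3/s.
#' @param alpha1_deg inlet flow angle in degrees, in (0, 90].
#' @return the inlet [velocity_triangle()]; its `w` field is the relative
#'   velocity in m/s.
#' @export
inlet_velocity_triangle <- function(r1_m, omega, blade_flow_m3s, alpha1_deg = 90) {
  if (r1_m <= 0) stop_invalid("eye radius must be positive")
  if (!(alpha1_deg > 0 && alpha1_deg <= 90))
    stop_invalid("inlet flow angle must lie in (0, 90] degrees")
  v_m1 <- blade_flow_m3s / (pi * r1_m^2)
  u1 <- r1_m * omega
  v_theta1 <- if (alpha1_deg == 90) 0 else v_m1 / tan(deg_to_rad(alpha1_deg))
  velocity_triangle(u = u1, v_theta = v_theta1, v_m = v_m1, station = 1)
}

#' @rdname inlet_velocity_triangle
#' @return `inlet_relative_velocity()` returns the scalar w1 (m/s).
#' @export
inlet_relative_velocity <- function(r1_m, omega, blade_flow_m3s, alpha1_deg = 90) {
  inlet_velocity_triangle(r1_m, omega, blade_flow_m3s, alpha1_deg)$w
}

#' Optimal eye radius (closed form)
#'
#' The eye radius minimizing the relative velocity between fluid and blade
#' leading edge:
#' r1 = cbrt( Q_bl / (4 pi omega) * ( sqrt(2 (17 + cos 2 alpha1)) / sin alpha1
#'   - 2 / tan alpha1 ) ).
#' The 90-degree (zero inlet swirl) case reduces to
#' r1 = cbrt( Q_bl sqrt(32) / (4 pi omega) ).
#'
#' @param blade_flow_m3s blade-passage flow in m^3/s.
#' @param omega rotational speed in rad/s.
#' @param alpha1_deg inlet flow angle in degrees, in (0, 90].
#' @return eye radius in m.
#' @examples
#' optimal_eye_radius(lmin_to_m3s(5) / 0.4, rpm_to_rads(7310))  # ~0.005 m
#' @export
optimal_eye_radius <- function(blade_flow_m3s, omega, alpha1_deg = 90) {
  if (blade_flow_m3s <= 0 || omega <= 0)
    stop_invalid("flow and speed must be positive")
  if (!(alpha1_deg > 0 && alpha1_deg <= 90))
    stop_invalid("inlet flow angle must lie in (0, 90] degrees")
  a <- deg_to_rad(alpha1_deg)
  swirl <- if (alpha1_deg == 90) 0 else 2 / tan(a)
  (blade_flow_m3s / (4 * omega * pi) *
     (sqrt(2 * (17 + cos(2 * a))) / sin(a) - swirl))^(1 / 3)
}

#' Optimal eye radius (numeric minimizer)
#'
#' Independent numerical check of [optimal_eye_radius()]: golden-section
#' minimization of [inlet_relative_velocity()] over r1.
#'
#' @inheritParams optimal_eye_radius
#' @param bracket search interval for r1 in m; must contain the minimum in
#'   its interior.
#' @param tol absolute tolerance on r1 in m.
#' @return eye radius in m.
#' @export
optimal_eye_radius_numeric <- function(blade_flow_m3s, omega, alpha1_deg = 90,
                                       bracket = c(1e-4, 5e-2), tol = 1e-10) {
  if (blade_flow_m3s <= 0 || omega <= 0)
    stop_invalid("flow and speed must be positive")
  opt <- stats::optimize(function(r1)
    inlet_relative_velocity(r1, omega, blade_flow_m3s, alpha1_deg),
    interval = bracket, tol = tol)
  edge <- min(opt$minimum - bracket[1], bracket[2] - opt$minimum)
  if (edge < 100 * tol + 1e-6 * diff(bracket))
    stop(errorCondition(
      "minimizer lies at the bracket edge; widen the bracket",
      class = c("hemopump_widen_bracket", "error")))
  opt$minimum
}

#' Theoretical pressure-flow characteristic
#'
#' Evaluates delta_p(Q) = rho * Y(Q) with the slip-corrected specific work at
#' fixed speed across a grid of delivered flows. For outlet angles at or
#' below 90 degrees the curve is non-increasing in Q; a 90-degree outlet
#' gives a flat characteristic.
#'
#' @param omega rotational speed in rad/s.
#' @param geometry an [impeller_geometry()].
#' @param constants a [design_constants()].
#' @param Q_grid_lmin delivered (net) flows in l/min.
#' @param fluid a [fluid_properties()].
#' @return data.frame with columns `flow_l_min` and `pressure_mmHg` (plus SI
#'   columns `flow_m3s`, `pressure_pa`).
#' @export
theoretical_characteristic <- function(omega, geometry,
                                       constants = design_constants(),
                                       Q_grid_lmin = seq(0, 9, by = 0.5),
                                       fluid = fluid_properties()) {
  if (any(Q_grid_lmin < 0)) stop_invalid("flows must be non-negative")
  q_si <- lmin_to_m3s(Q_grid_lmin)
  y <- vapply(q_si, function(q)
    specific_work_with_slip(omega, geometry, blade_passage_flow(q, constants),
                            constants),
    numeric(1))
  dp <- fluid$density * y
  data.frame(flow_l_min = Q_grid_lmin, pressure_mmHg = pa_to_mmhg(dp),
             flow_m3s = q_si, pressure_pa = dp)
}

#' Hydraulic efficiency from a power breakdown
#'
#' eta = P_hyd / (P_in - P_iron - P_ohm - P_ctrl). Values above 1 are
#' physically impossible and trigger a warning (measurement noise) but are
#' returned unchanged.
#'
#' @param powers a [power_breakdown()].
#' @return hydraulic efficiency (dimensionless).
#' @export
hydraulic_efficiency <- function(powers) {
  stopifnot(inherits(powers, "power_breakdown"))
  denom <- powers$p_input - powers$p_iron - powers$p_ohmic - powers$p_control
  if (denom <= 0)
    stop_invalid("input power must exceed the electrical losses")
  eta <- powers$p_hydraulic / denom
  if (eta > 1)
    warning("efficiency above 1; check the power measurements",
            call. = FALSE)
  eta
}
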