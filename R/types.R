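# Constructors for the domain objects of the design calculus and the assay
# pipeline. Each validates its invariants and converts boundary units to SI
# once; downstream functions can assume canonical units.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("hemopump_invalid_input", "error")))
}

#' Fluid properties
#'
#' @param density_kg_m3 fluid density in kg/m^3 (blood at 30 % haematocrit is
#'   typically taken as 1060).
#' @param name free-text label.
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(density_kg_m3 = 1060, name = "blood") {
  if (!is.numeric(density_kg_m3) || length(density_kg_m3) != 1 || density_kg_m3 <= 0)
    stop_invalid("density must be a single positive number (kg/m^3)")
  structure(list(density = density_kg_m3, name = name),
            class = "fluid_properties")
}

#' Pump operating point
#'
#' The duty point the impeller must meet. Accepted in clinical units at the
#' boundary (l/min, mmHg) and stored in SI.
#'
#' @param flow_l_min volumetric flow rate in l/min.
#' @param pressure_mmHg pressure rise across the pump in mmHg.
#' @return object of class `operating_point` with fields `flow_rate` (m^3/s)
#'   and `pressure_rise` (Pa).
#' @examples
#' operating_point(5, 350)  # nominal CPB/ECMO duty point
#' @export
operating_point <- function(flow_l_min = 5, pressure_mmHg = 350) {
  if (!is.numeric(flow_l_min) || flow_l_min <= 0)
    stop_invalid("flow must be positive")
  if (!is.numeric(pressure_mmHg) || pressure_mmHg <= 0)
    stop_invalid("pressure rise must be positive")
  structure(list(flow_rate = lmin_to_m3s(flow_l_min),
                 pressure_rise = mmhg_to_pa(pressure_mmHg)),
            class = "operating_point")
}

#' Impeller geometry
#'
#' Geometry of one impeller variant. Lengths are accepted in millimetres and
#' angles in degrees at the boundary; stored in metres and radians.
#'
#' @param eye_radius_mm inlet (eye) radius r1.
#' @param outer_radius_mm blade outer radius r2.
#' @param blade_height_mm blade height h_bl.
#' @param blade_outlet_angle_deg blade outlet angle beta_2B in (0, 90].
#' @param hub_height_mm optional hub height h_h.
#' @param radial_gap_mm optional radial fluid gap delta_fl.
#' @param top_gap_mm optional gap between shroud and housing delta_sh.
#' @param blade_count number of blades z (>= 2).
#' @param inlet_flow_angle_deg inlet flow angle alpha_1; 90 means zero inlet
#'   swirl.
#' @return object of class `impeller_geometry` (SI/radian fields `r1`, `r2`,
#'   `h_bl`, `beta_2B`, `z`, `alpha1`, ...).
#' @export
impeller_geometry <- function(eye_radius_mm = 5,
                              outer_radius_mm = 11,
                              blade_height_mm = 6,
                              blade_outlet_angle_deg = 90,
                              hub_height_mm = NULL,
                              radial_gap_mm = NULL,
                              top_gap_mm = NULL,
                              blade_count = 6L,
                              inlet_flow_angle_deg = 90) {
  r1 <- eye_radius_mm / 1000
  r2 <- outer_radius_mm / 1000
  if (!(r1 > 0 && r1 < r2))
    stop_invalid("eye radius must satisfy 0 < r1 < r2")
  if (!(blade_outlet_angle_deg > 0 && blade_outlet_angle_deg <= 90))
    stop_invalid("blade outlet angle must lie in (0, 90] degrees")
  if (blade_height_mm <= 0)
    stop_invalid("blade height must be positive")
  if (blade_count < 2)
    stop_invalid("blade count must be at least 2")
  if (!(inlet_flow_angle_deg > 0 && inlet_flow_angle_deg <= 90))
    stop_invalid("inlet flow angle must lie in (0, 90] degrees")
  structure(list(
    r1 = r1, r2 = r2,
    h_bl = blade_height_mm / 1000,
    beta_2B = deg_to_rad(blade_outlet_angle_deg),
    beta_2B_deg = blade_outlet_angle_deg,
    h_h = if (is.null(hub_height_mm)) NULL else hub_height_mm / 1000,
    delta_fl = if (is.null(radial_gap_mm)) NULL else radial_gap_mm / 1000,
    delta_sh = if (is.null(top_gap_mm)) NULL else top_gap_mm / 1000,
    z = as.integer(blade_count),
    alpha1 = deg_to_rad(inlet_flow_angle_deg),
    alpha1_deg = inlet_flow_angle_deg
  ), class = "impeller_geometry")
}

#' Design constants
#'
#' Empirical constants of the design calculus: the assumed volumetric
#' efficiency and the slip-factor correlation parameters.
#'
#' The `paper_printed` slip mode is the bladeless correlation
#' mu = 1 - f1 (1 - sqrt(sin beta)) kW, which is degenerate at beta = 90
#' degrees (mu = 1, no work transfer). The default `bladed_wiesner` mode is
#' the Wiesner/Guelich form with blade count z,
#' (1 - mu) = f1 (1 - sqrt(sin beta) / z^0.7) kW, which remains finite at 90
#' degrees and is used throughout unless stated otherwise.
#'
#' @param volumetric_efficiency fraction of blade-passage flow delivered to
#'   the outlet (default 0.4; small gap-dominated pumps leak heavily).
#' @param slip_f1 correlation constant f1 (default 0.98 for radial designs).
#' @param slip_kW correlation constant kW (default 1).
#' @param slip_model one of `"bladed_wiesner"` (default) or `"paper_printed"`.
#' @return object of class `design_constants`.
#' @export
design_constants <- function(volumetric_efficiency = 0.4,
                             slip_f1 = 0.98,
                             slip_kW = 1,
                             slip_model = c("bladed_wiesner", "paper_printed")) {
  slip_model <- match.arg(slip_model)
  if (!(volumetric_efficiency > 0 && volumetric_efficiency <= 1))
    stop_invalid("volumetric efficiency must lie in (0, 1]")
  if (!(slip_f1 > 0 && slip_f1 <= 1))
    stop_invalid("slip constant f1 must lie in (0, 1]")
  structure(list(eta_vol = volumetric_efficiency,
                 f1 = slip_f1, kW = slip_kW,
                 slip_model = slip_model),
            class = "design_constants")
}

#' Velocity triangle at a blade station
#'
#' Holds the blade speed u, circumferential fluid velocity v_theta, meridional
#' velocity v_m and relative velocity w at the blade inlet (station 1) or
#' outlet (station 2). When `w` is omitted it is completed from
#' w^2 = v_m^2 + (u - v_theta)^2; when supplied it is validated against that
#' identity.
#'
#' @param u blade speed (m/s).
#' @param v_theta circumferential fluid velocity (m/s).
#' @param v_m meridional velocity (m/s).
#' @param w relative velocity (m/s), optional.
#' @param station 1 (inlet) or 2 (outlet).
#' @return object of class `velocity_triangle`.
#' @export
velocity_triangle <- function(u, v_theta, v_m = NA_real_, w = NULL, station = 1) {
  if (!station %in% c(1, 2)) stop_invalid("station must be 1 (inlet) or 2 (outlet)")
  w_implied <- if (is.na(v_m)) NULL else sqrt(v_m^2 + (u - v_theta)^2)
  if (is.null(w)) {
    w <- if (is.null(w_implied)) NA_real_ else w_implied
  } else if (!is.null(w_implied)) {
    rel <- abs(w^2 - w_implied^2) / max(w_implied^2, .Machine$double.eps)
    if (rel > 1e-9)
      stop_invalid("w is inconsistent with w^2 = v_m^2 + (u - v_theta)^2")
  }
  structure(list(u = u, v_theta = v_theta, v_m = v_m, w = w, station = station),
            class = "velocity_triangle")
}

#' Power breakdown of a pump measurement
#'
#' @param p_hydraulic hydraulic power delivered to the fluid (W).
#' @param p_input electrical input power (W).
#' @param p_iron stator iron losses (W).
#' @param p_ohmic conduction losses (W).
#' @param p_control losses of the bearing/drive control circuit (W).
#' @return object of class `power_breakdown`.
#' @export
power_breakdown <- function(p_hydraulic, p_input,
                            p_iron = 0, p_ohmic = 0, p_control = 0) {
  vals <- c(p_hydraulic, p_input, p_iron, p_ohmic, p_control)
  if (any(vals < 0)) stop_invalid("all powers must be non-negative")
  structure(list(p_hydraulic = p_hydraulic, p_input = p_input,
                 p_iron = p_iron, p_ohmic = p_ohmic, p_control = p_control),
            class = "power_breakdown")
}

#' Hemolysis test-circuit configuration
#'
#' Circuit conditions entering the normalized index of hemolysis. Defaults are
#' the standard extracorporeal test conditions (700 ml circuit, 5 l/min,
#' 350 mmHg, 30 % haematocrit).
#'
#' @param volume_l total circuit volume V in litres.
#' @param flow_l_min circuit flow rate Q in l/min.
#' @param hct_pct haematocrit in percent, strictly between 0 and 100.
#' @param pressure_mmHg pressure rise across the pump in mmHg (metadata plus
#'   ASTM window check).
#' @param temperature_c blood temperature, metadata only.
#' @return object of class `circuit_config`.
#' @export
circuit_config <- function(volume_l = 0.7, flow_l_min = 5, hct_pct = 30,
                           pressure_mmHg = 350, temperature_c = 30) {
  if (volume_l <= 0 || flow_l_min <= 0)
    stop_invalid("circuit volume and flow must be positive")
  if (!(hct_pct > 0 && hct_pct < 100))
    stop_invalid("haematocrit must lie strictly between 0 and 100 percent")
  structure(list(volume = volume_l, flow = flow_l_min, hct = hct_pct,
                 pressure = pressure_mmHg, temperature = temperature_c),
            class = "circuit_config")
}

#' Check a circuit against the ASTM operating window
#'
#' The standard hemolysis test window is Q = 5 +/- 0.25 l/min and
#' delta p = 350 +/- 10 mmHg.
#'
#' @param circuit a [circuit_config()].
#' @return logical; `TRUE` when flow and pressure lie inside the window.
#' @export
astm_within_window <- function(circuit) {
  stopifnot(inherits(circuit, "circuit_config"))
  abs(circuit$flow - 5) <= 0.25 && abs(circuit$pressure - 350) <= 10
}
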