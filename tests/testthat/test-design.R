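# Design calculus: specific work, slip, required speed, Cordier numbers,
# inlet optimization, theoretical characteristics.

nominal_Q_bl <- blade_passage_flow(lmin_to_m3s(5))  # eta_vol = 0.4

test_that("specific work from pressure is delta_p over rho", {
  expect_equal(specific_work_from_pressure(mmhg_to_pa(350), 1060), 44.02,
               tolerance = 5e-4)
  expect_identical(specific_work_from_pressure(0, 1060), 0)
  expect_equal(specific_work_from_pressure(mmhg_to_pa(100), 1060),
               100 * 133.322 / 1060, tolerance = 1e-12)
  expect_error(specific_work_from_pressure(100, 0), class = "hemopump_invalid_input")
})

test_that("Euler specific work follows the velocity triangles", {
  tri <- function(u, vt) velocity_triangle(u = u, v_theta = vt)
  expect_equal(euler_specific_work(tri(8, 6), tri(3, 0)), 48)
  expect_equal(euler_specific_work(tri(5, 2), tri(5, 2)), 0)
  expect_equal(euler_specific_work(tri(7.93, 7.93), tri(3.8, 1)),
               7.93^2 - 3.8, tolerance = 1e-12)  # 59.09 to 2 d.p.
  expect_error(euler_specific_work(tri(8, NA), tri(3, 0)),
               class = "hemopump_invalid_input")
})

test_that("velocity triangles complete and validate w", {
  tr <- velocity_triangle(u = 4, v_theta = 1, v_m = 4)
  expect_equal(tr$w, 5)
  expect_error(velocity_triangle(u = 4, v_theta = 1, v_m = 4, w = 5.1),
               class = "hemopump_invalid_input")
})

test_that("blade passage flow scales net flow by the volumetric efficiency", {
  expect_equal(m3s_to_lmin(nominal_Q_bl), 12.5)
  expect_equal(nominal_Q_bl, 2.0833e-4, tolerance = 1e-4)
  expect_equal(blade_passage_flow(3e-4, design_constants(volumetric_efficiency = 1)),
               3e-4)
  expect_equal(m3s_to_lmin(blade_passage_flow(lmin_to_m3s(9))), 22.5)
})

test_that("theoretical specific work matches the Euler geometry expression", {
  g60 <- impeller_geometry(outer_radius_mm = 11, blade_height_mm = 6,
                           blade_outlet_angle_deg = 60)
  g90 <- impeller_geometry(outer_radius_mm = 11, blade_outlet_angle_deg = 90)
  expect_equal(theoretical_specific_work(765.5, g60, 0), (765.5 * 0.011)^2)
  # 90-degree outlet: the tan term is identically zero at any flow
  expect_equal(theoretical_specific_work(765.5, g90, 2.0833e-4),
               (765.5 * 0.011)^2)
  expect_equal(theoretical_specific_work(765.5, g60, 2.0833e-4),
               (765.5 * 0.011)^2 -
                 765.5 * 2.0833e-4 / (2 * pi * 0.006 * tan(pi / 3)),
               tolerance = 1e-12)
  expect_equal(theoretical_specific_work(765.5, g60, 2.0833e-4), 68.46,
               tolerance = 1e-4)
})

test_that("slip factor correlations match hand-computed values", {
  printed <- design_constants(slip_model = "paper_printed")
  expect_equal(slip_factor(90, printed), 1)       # degenerate printed form
  expect_equal(slip_factor(22.5, printed), 1 - 0.98 * (1 - sqrt(sin(pi / 8))),
               tolerance = 1e-12)
  expect_equal(slip_factor(22.5, printed), 0.6262, tolerance = 1e-4)
  bladed <- design_constants()  # bladed_wiesner default
  expect_equal(1 - slip_factor(90, bladed, blade_count = 6),
               0.98 * (1 - 6^-0.7), tolerance = 1e-12)
  expect_equal(1 - slip_factor(90, bladed, blade_count = 6), 0.7004,
               tolerance = 1e-4)
  expect_error(slip_factor(90, bladed, blade_count = 1),
               class = "hemopump_invalid_input")
  expect_error(slip_factor(95, bladed), class = "hemopump_invalid_input")
})

test_that("slip only removes work: Y <= Y_th on random parameter draws", {
  set.seed(7)
  for (i in 1:100) {
    g <- impeller_geometry(outer_radius_mm = runif(1, 8, 20),
                           blade_height_mm = runif(1, 3, 9),
                           blade_outlet_angle_deg = runif(1, 15, 90),
                           blade_count = sample(3:9, 1))
    omega <- runif(1, 200, 1500)
    q <- runif(1, 0, 4e-4)
    expect_lte(specific_work_with_slip(omega, g, q),
               theoretical_specific_work(omega, g, q) + 1e-12)
  }
})

test_that("a 90-degree outlet makes the specific work independent of blade height", {
  g5 <- impeller_geometry(blade_height_mm = 5, blade_outlet_angle_deg = 90)
  g7 <- impeller_geometry(blade_height_mm = 7, blade_outlet_angle_deg = 90)
  expect_identical(specific_work_with_slip(720.7, g5, nominal_Q_bl),
                   specific_work_with_slip(720.7, g7, nominal_Q_bl))
})

test_that("required speed inverts the slip-corrected work expression", {
  g90 <- impeller_geometry(outer_radius_mm = 11, blade_outlet_angle_deg = 90,
                           blade_count = 6)
  # closed form at 90 degrees: omega = sqrt(Y / ((1 - mu) r2^2))
  mu <- slip_factor(90, design_constants(), 6)
  omega <- required_speed(44.02, g90, nominal_Q_bl)
  expect_equal(omega, sqrt(44.02 / ((1 - mu) * 0.011^2)), tolerance = 1e-12)
  expect_equal(omega, 720.7, tolerance = 1e-3)
  expect_equal(specific_work_with_slip(omega, g90, nominal_Q_bl), 44.02,
               tolerance = 1e-9)
  # degenerate printed slip form at 90 degrees is flagged, not clipped
  expect_error(required_speed(44.02, g90, nominal_Q_bl,
                              design_constants(slip_model = "paper_printed")),
               class = "hemopump_no_solution")
})

test_that("required speed round-trips through the work expression on random draws", {
  set.seed(21)
  for (i in 1:100) {
    g <- impeller_geometry(outer_radius_mm = runif(1, 8, 20),
                           blade_height_mm = runif(1, 3, 9),
                           blade_outlet_angle_deg = runif(1, 20, 90),
                           blade_count = sample(4:8, 1))
    Y <- runif(1, 5, 80)
    q <- runif(1, 0, 4e-4)
    omega <- required_speed(Y, g, q)
    expect_equal(specific_work_with_slip(omega, g, q), Y, tolerance = 1e-9)
  }
})

test_that("speed map reproduces required_speed and reports grid extremes", {
  g <- impeller_geometry()
  single <- speed_map(60, 6, 44.02, g, nominal_Q_bl)
  expect_equal(unclass(single)[1, 1],
               rads_to_rpm(required_speed(44.02, impeller_geometry(
                 blade_outlet_angle_deg = 60), nominal_Q_bl)),
               ignore_attr = TRUE)
  m <- speed_map(c(30, 60, 90), c(4, 6, 8), 44.02, g, nominal_Q_bl)
  expect_equal(diff(unclass(m)[3, ]), c(0, 0), ignore_attr = TRUE)  # 90-deg row flat
  for (i in 1:2)  # below 90 degrees higher blades need no more speed
    expect_true(all(diff(unclass(m)[i, ]) <= 0))
  expect_equal(unname(attr(m, "optimal")["rpm"]), min(m))
  expect_equal(unname(attr(m, "worst")["rpm"]), max(m))
  # the flat 90-degree grid ties everywhere; ties break to smallest beta, then h
  flat <- speed_map(90, c(4, 6, 8), 44.02, g, nominal_Q_bl)
  expect_equal(unname(attr(flat, "optimal")[c("beta_deg", "h_bl_mm")]), c(90, 4))
  expect_error(speed_map(c(60, 30), c(4, 6), 44.02, g, nominal_Q_bl),
               class = "hemopump_invalid_input")
})

test_that("Cordier similarity numbers match the printed design point", {
  Q <- lmin_to_m3s(5)
  expect_equal(diameter_number(0.022, 44.02, Q), 6.54, tolerance = 5e-4)
  expect_equal(diameter_number(0.044, 44.02, Q),
               2 * diameter_number(0.022, 44.02, Q), tolerance = 1e-12)
  expect_equal(diameter_number(0.011, 44.02, Q), 6.54 / 2, tolerance = 5e-3)
  expect_equal(round(specific_speed(rpm_to_rads(7310), 44.02, Q), 3), 0.137)
  expect_equal(specific_speed(rpm_to_rads(3655), 44.02, Q),
               specific_speed(rpm_to_rads(7310), 44.02, Q) / 2,
               tolerance = 1e-12)
  expect_equal(specific_speed(rpm_to_rads(3655), 44.02, Q), 0.0686,
               tolerance = 5e-4)
})

test_that("impellers classify as radial strictly above diameter number 3.5", {
  expect_identical(classify_impeller(6.54), "radial")
  expect_identical(classify_impeller(3.5), "non_radial")
  expect_identical(classify_impeller(3.27), "non_radial")
})

test_that("inlet relative velocity follows the inlet triangle", {
  expect_equal(inlet_relative_velocity(0.005, 765.5, 2.0833e-4, 90),
               sqrt((2.0833e-4 / (pi * 0.005^2))^2 + (0.005 * 765.5)^2),
               tolerance = 1e-12)
  expect_equal(inlet_relative_velocity(0.005, 765.5, 2.0833e-4, 90), 4.657,
               tolerance = 1e-3)
  expect_equal(inlet_relative_velocity(0.005, 765.5, 0, 90), 0.005 * 765.5)
  tr <- inlet_velocity_triangle(0.005, 765.5, 2.0833e-4, 90)
  expect_equal(tr$v_theta, 0)  # zero inlet swirl
  expect_error(inlet_relative_velocity(0, 765.5, 2.0833e-4),
               class = "hemopump_invalid_input")
})

test_that("closed-form eye radius matches the published design and is scale-free", {
  r1 <- optimal_eye_radius(nominal_Q_bl, rpm_to_rads(7310), 90)
  expect_equal(round(r1 * 1000), 5)
  expect_equal(r1, 4.97e-3, tolerance = 1e-3)
  expect_equal(optimal_eye_radius(2 * nominal_Q_bl, 2 * rpm_to_rads(7310), 90),
               r1, tolerance = 1e-12)
  expect_error(optimal_eye_radius(nominal_Q_bl, rpm_to_rads(7310), 0),
               class = "hemopump_invalid_input")
})

test_that("closed-form eye radius equals the numeric minimizer on random draws", {
  set.seed(33)
  for (i in 1:100) {
    q <- runif(1, 5e-5, 5e-4)
    omega <- runif(1, 300, 1500)
    a1 <- runif(1, 30, 90)
    closed <- optimal_eye_radius(q, omega, a1)
    numeric <- optimal_eye_radius_numeric(q, omega, a1)
    expect_equal(numeric, closed, tolerance = 1e-6)
    # local optimality of the closed form
    w <- function(r) inlet_relative_velocity(r, omega, q, a1)
    expect_lte(w(closed), w(closed * (1 + 1e-4)))
    expect_lte(w(closed), w(closed * (1 - 1e-4)))
  }
})

test_that("numeric eye-radius search flags a bracket that misses the minimum", {
  expect_error(optimal_eye_radius_numeric(nominal_Q_bl, rpm_to_rads(7310), 90,
                                          bracket = c(0.02, 0.05)),
               class = "hemopump_widen_bracket")
})

test_that("theoretical characteristic has the expected shape", {
  const <- design_constants()
  g90 <- impeller_geometry(blade_outlet_angle_deg = 90)
  g60 <- impeller_geometry(blade_outlet_angle_deg = 60)
  ch90 <- theoretical_characteristic(720.7, g90, const, Q_grid_lmin = 0:9)
  mu <- slip_factor(90, const, g90$z)
  expect_equal(ch90$pressure_pa[1], 1060 * (1 - mu) * (720.7 * g90$r2)^2,
               tolerance = 1e-12)
  expect_true(all(abs(diff(ch90$pressure_pa)) < 1e-9))  # flat at 90 degrees
  ch60 <- theoretical_characteristic(765.5, g60, const, Q_grid_lmin = 0:9)
  expect_true(all(diff(ch60$pressure_pa) < 0))          # falls with flow
})

test_that("hydraulic efficiency is hydraulic power over net electrical power", {
  expect_equal(hydraulic_efficiency(power_breakdown(10, 30, 2, 2, 1)), 0.4)
  expect_equal(hydraulic_efficiency(power_breakdown(12, 30)), 0.4)
  # nominal duty point: P_hyd = Q * dp = 3.89 W; a 9.7 W net input gives the
  # 40 % efficiency the base design reaches
  p_hyd <- lmin_to_m3s(5) * mmhg_to_pa(350)
  expect_equal(p_hyd, 3.889, tolerance = 1e-3)
  expect_equal(hydraulic_efficiency(power_breakdown(p_hyd, 9.7)), 0.401,
               tolerance = 1e-3)
  expect_error(hydraulic_efficiency(power_breakdown(10, 5, 3, 3, 1)),
               class = "hemopump_invalid_input")
  expect_warning(hydraulic_efficiency(power_breakdown(10, 9)), "above 1")
})

test_that("pump_design assembles a consistent report", {
  d <- pump_design(operating_point(5, 350), impeller_geometry())
  expect_s3_class(d, "pump_design")
  expect_equal(d$specific_work, 44.02, tolerance = 5e-4)
  expect_equal(d$diameter_number, 6.54, tolerance = 5e-4)
  expect_identical(d$classification, "radial")
  expect_equal(specific_work_with_slip(d$omega, d$geometry, d$blade_flow),
               d$specific_work, tolerance = 1e-9)
  ch <- predict(d, flow_l_min = c(0, 5))
  expect_equal(ch$pressure_mmHg[1], ch$pressure_mmHg[2])  # 90-degree outlet
  expect_output(print(summary(d)), "slip factor")
})

test_that("design configs read from YAML drive the same calculus", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "operating_point: {flow_l_min: 5, pressure_mmHg: 350}",
    "fluid: {density_kg_m3: 1060}",
    "geometry: {outer_radius_mm: 11, blade_outlet_angle_deg: 90, blade_count: 6}",
    "constants: {volumetric_efficiency: 0.4}"), cfg_path)
  cfg <- read_design_config(cfg_path)
  d <- pump_design(cfg$op, cfg$geometry, cfg$fluid, cfg$constants)
  expect_equal(d$specific_work, 44.02, tolerance = 5e-4)
  expect_equal(d$omega, 720.7, tolerance = 1e-3)
})
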