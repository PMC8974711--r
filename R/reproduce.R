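# End-to-end convenience entry points: recompute the published design numbers
# from the shipped fixtures, and run the full simulate -> analyze -> compare
# pipeline on a campaign-shaped synthetic study.

#' Recompute the published design and benchmark numbers
#'
#' Deterministically recomputes, from the package's own functions and the
#' shipped fixture tables, the headline quantities of the design calculus and
#' the campaign analysis: the specific work at the nominal duty point, the
#' diameter number of the 22 mm impeller, the specific speed at 7310 rpm, the
#' optimal eye radius, the Pearson correlation between normalized NIH and
#' hydraulic efficiency across the eight variants, and the benchmark mean-NIH
#' ratios against the two commercial pumps. Each row carries the published
#' value, the tolerance implied by its printed precision, and a pass flag.
#' The run involves no random number generation and is byte-stable.
#'
#' @return data.frame with columns `quantity`, `computed`, `published`,
#'   `tolerance`, `pass`.
#' @export
reproduce_paper <- function() {
  op <- operating_point(5, 350)
  fluid <- fluid_properties(1060)
  Y <- specific_work_from_pressure(op$pressure_rise, fluid$density)
  dM <- diameter_number(0.022, Y, op$flow_rate)
  sM <- specific_speed(rpm_to_rads(7310), Y, op$flow_rate)
  r1_mm <- 1000 * optimal_eye_radius(blade_passage_flow(op$flow_rate),
                                     rpm_to_rads(7310), 90)
  t2 <- paper_table("table2")
  rho <- pearson_r(t2$mean_nih_norm, t2$efficiency_pct)
  t3 <- paper_table("table3")
  gs <- function(row) group_summary(row$pump, row$nih_mg_dl, row$std_mg_dl, row$n)
  ratio_flo <- benchmark_ratio(gs(t3[t3$pump == "FloPump 32", ]),
                               gs(t3[t3$pump == "B", ]))
  ratio_bpx <- benchmark_ratio(gs(t3[t3$pump == "BPX-80", ]),
                               gs(t3[t3$pump == "B", ]))
  rows <- list(
    list("specific work Y (m^2/s^2)",        Y,         44.02, 0.005),
    list("diameter number (22 mm impeller)", dM,        6.54,  0.005),
    list("specific speed at 7310 rpm",       sM,        0.137, 0.0005),
    list("optimal eye radius (mm)",          r1_mm,     5,     0.5),
    list("Pearson r, NIH/NIH_ref vs eta",    rho,       -0.5,  0.05),
    list("mean NIH ratio FloPump 32 / B",    ratio_flo, 2.7,   0.05),
    list("mean NIH ratio BPX-80 / B",        ratio_bpx, 5.4,   0.05))
  out <- data.frame(
    quantity = vapply(rows, `[[`, character(1), 1),
    computed = vapply(rows, `[[`, numeric(1), 2),
    published = vapply(rows, `[[`, numeric(1), 3),
    tolerance = vapply(rows, `[[`, numeric(1), 4),
    stringsAsFactors = FALSE)
  out$pass <- abs(out$computed - out$published) <= out$tolerance
  out
}

#' Simulate, analyze and compare a campaign-shaped study
#'
#' Generates a synthetic study with the published campaign's layout
#' ([paper_study_design()]), runs the full NIH pipeline ([nih_study()]),
#' compares every variant against the base design ([compare_pumps()]) and
#' reports how well the configured true rate ratios are recovered.
#'
#' @param seed integer seed for the simulation.
#' @param sessions number of sessions (default 18, the published run counts).
#' @param baseline pump compared against (default `"B"`).
#' @return list of class `hemopump_demo` with components `study` (the
#'   [nih_study()] fit), `comparison` (Fig-6-style table), `recovery`
#'   (per-pump estimated vs true ratio with standard errors) and `design`.
#' @export
end_to_end_demo <- function(seed, sessions = 18, baseline = "B") {
  design <- paper_study_design(sessions = sessions, seed = seed)
  sim <- simulate_study(design)
  fit <- nih_study(sim$samples, circuit = design$circuit)
  comparison <- compare_pumps(fit, baseline = baseline)
  if (sessions == 1)
    warning("a single session gives no between-session confidence intervals",
            call. = FALSE)
  est <- coef(fit)
  se <- fit$pumps$sd_nih_norm / sqrt(fit$pumps$n)
  names(se) <- fit$pumps$pump_id
  truth <- sim$truth$rate_ratios[names(est)]
  recovery <- data.frame(pump_id = names(est), true_ratio = unname(truth),
                         estimated = unname(est), stderr = unname(se[names(est)]),
                         z = unname((est - truth) / se[names(est)]),
                         stringsAsFactors = FALSE)
  structure(list(study = fit, comparison = comparison, recovery = recovery,
                 design = design, seed = seed),
            class = "hemopump_demo")
}

#' @export
print.hemopump_demo <- function(x, ...) {
  cat(sprintf("End-to-end synthetic campaign (seed %d, %d sessions)\n\n",
              x$seed, x$design$sessions))
  cat("Comparison vs baseline (normalized NIH):\n")
  df <- x$comparison
  df[-1] <- lapply(df[-1], signif, digits = 3)
  print(df, row.names = FALSE)
  cat("\nGround-truth recovery (rate ratios):\n")
  rec <- x$recovery
  rec[-1] <- lapply(rec[-1], signif, digits = 3)
  print(rec, row.names = FALSE)
  invisible(x)
}
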