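# In vitro hemolysis assay pipeline: absorbance calibration, plasma-free-
# haemoglobin (pfHb) slope regression, the normalized index of hemolysis
# (NIH) and normalization to a session reference pump.

#' Fit a pfHb calibration curve
#'
#' Ordinary least-squares line pfHb = slope * absorbance + intercept, fitted
#' to standards of known concentration (e.g. dried bovine erythrocytes read
#' at 540 nm in Drabkin's reagent). The intercept is left free so a residual
#' blank offset cannot bias the slope.
#'
#' @param known_pfhb known concentrations of the standards (mg/dl).
#' @param absorbance measured absorbances of the standards.
#' @return object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `n_standards` and the underlying [stats::lm()]
#'   fit.
#' @export
fit_calibration <- function(known_pfhb, absorbance) {
  if (length(known_pfhb) != length(absorbance))
    stop_invalid("standards need matching concentration and absorbance vectors")
  if (length(absorbance) < 2 || length(unique(absorbance)) < 2)
    stop(errorCondition("calibration needs >= 2 distinct absorbance values",
                        class = c("hemopump_fit_error", "error")))
  if (any(known_pfhb < 0)) stop_invalid("standard concentrations must be >= 0")
  fit <- stats::lm(known_pfhb ~ absorbance)
  # r^2 computed directly (mss / (mss + rss), as summary.lm does) so exact
  # standards do not trigger the "essentially perfect fit" warning
  mss <- sum((stats::fitted(fit) - mean(stats::fitted(fit)))^2)
  rss <- sum(stats::residuals(fit)^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (mss + rss == 0) NaN else mss / (mss + rss),
                 n_standards = length(absorbance),
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: pfHb = %.4g * A540 + %.4g (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_standards))
  invisible(x)
}

#' Convert absorbance to pfHb concentration
#'
#' Evaluates a fitted [fit_calibration()] line. Negative predictions (blank
#' noise near zero haemolysis) are clipped to 0 and flagged via the
#' `"clipped"` attribute.
#'
#' @param absorbance absorbance values at 540 nm.
#' @param curve a `calibration_curve`.
#' @return pfHb concentrations in mg/dl, with a logical attribute `clipped`
#'   marking clipped entries.
#' @export
absorbance_to_pfhb <- function(absorbance, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  pfhb <- curve$slope * absorbance + curve$intercept
  clipped <- pfhb < 0
  pfhb[clipped] <- 0
  structure(pfhb, clipped = clipped)
}

#' pfHb growth rate of one pump run
#'
#' Ordinary least-squares slope of pfHb against elapsed time in hours,
#' intercept free, the t = 0 baseline sample included. The standard error is
#' the usual residual-based slope standard error (0 when only two samples
#' determine the line exactly).
#'
#' @param time_h sampling times in hours, strictly increasing.
#' @param pfhb pfHb concentrations in mg/dl.
#' @return list with `slope` (mg/dl per hour), `slope_per_min`, `stderr`,
#'   `intercept` and `n`.
#' @export
pfhb_slope <- function(time_h, pfhb) {
  if (length(time_h) != length(pfhb) || length(time_h) < 2)
    stop_invalid("a run needs >= 2 matched (time, pfHb) samples")
  if (anyDuplicated(time_h))
    stop_invalid("duplicate sampling times in one run")
  fit <- stats::lm(pfhb ~ time_h)
  co <- stats::coef(fit)
  n <- length(time_h)
  # standard error computed directly so exact (noise-free) runs do not
  # trigger the "essentially perfect fit" warning from summary.lm
  se <- if (n == 2) 0 else {
    s2 <- sum(stats::residuals(fit)^2) / (n - 2)
    sqrt(s2 / sum((time_h - mean(time_h))^2))
  }
  list(slope = unname(co["time_h"]), slope_per_min = unname(co["time_h"]) / 60,
       stderr = se, intercept = unname(co["(Intercept)"]), n = n)
}

#' Normalized index of hemolysis
#'
#' NIH = (dpfHb/dt) * (V / Q) * (100 - Hct) / 100, with the slope in mg/dl
#' per minute, V in litres and Q in l/min, so V/Q is a residence time in
#' minutes and NIH is in mg/dl. Slopes estimated per hour (the sampling
#' interval) are converted internally.
#'
#' @param slope_per_h pfHb growth rate in mg/dl per hour.
#' @param circuit a [circuit_config()] supplying V, Q and Hct.
#' @return NIH in mg/dl. Negative slopes (noise at near-zero hemolysis)
#'   propagate to negative NIH values rather than being clipped, so group
#'   means stay unbiased.
#' @examples
#' nih(5.878, circuit_config())  # ~0.0096 mg/dl
#' @export
nih <- function(slope_per_h, circuit = circuit_config()) {
  stopifnot(inherits(circuit, "circuit_config"))
  (slope_per_h / 60) * (circuit$volume / circuit$flow) *
    (100 - circuit$hct) / 100
}

#' Normalize an NIH value to the session reference
#'
#' Dividing by the NIH of a reference pump run simultaneously on the same
#' blood cancels the multiplicative blood-sensitivity factor of that session.
#'
#' @param nih_value NIH of the test run (mg/dl).
#' @param nih_reference NIH of the session's reference run (mg/dl); must be
#'   positive.
#' @return dimensionless ratio NIH / NIH_ref.
#' @export
normalize_to_reference <- function(nih_value, nih_reference) {
  if (any(nih_reference <= 0))
    stop(errorCondition("reference NIH must be positive for normalization",
                        class = c("hemopump_undefined_ratio", "error")))
  nih_value / nih_reference
}

#' Control-run quality check
#'
#' A control volume at rest monitors the blood itself: its pfHb slope should
#' be indistinguishable from zero. The check fails when the absolute control
#' slope exceeds `threshold`; the default `Inf` records the slope without
#' failing anything (QC is opt-in because the appropriate threshold depends
#' on the assay noise).
#'
#' @param time_h,pfhb the control run's samples.
#' @param threshold maximum tolerated absolute slope in mg/dl per hour.
#' @return list with `pass`, `slope` and `threshold`.
#' @export
control_check <- function(time_h, pfhb, threshold = Inf) {
  s <- pfhb_slope(time_h, pfhb)
  list(pass = abs(s$slope) <= threshold, slope = s$slope,
       threshold = threshold)
}

#' Analyze a hemolysis study
#'
#' The study analyzer: per run, fits the pfHb regression, computes the NIH
#' and normalizes it to the session's reference run; per pump, summarizes
#' mean and standard deviation of raw and normalized NIH over runs. This is
#' the end-to-end pipeline a multi-session in vitro campaign is evaluated
#' with.
#'
#' @param samples data.frame with one row per blood sample and columns
#'   `session_id`, `pump_id`, `role` (`"test"`, `"reference"` or
#'   `"control"`), `time_h` and either `pfhb_mg_dl` or `absorbance`.
#' @param circuit a [circuit_config()]; applies to every run unless the
#'   samples carry their own `volume_l`, `flow_l_min`, `hct_pct` columns.
#' @param calibration optional `calibration_curve`; required when samples
#'   carry `absorbance` instead of `pfhb_mg_dl`.
#' @param control_threshold passed to [control_check()]; a failing control
#'   flags every run of its session.
#' @return object of class `nih_study` with components `runs` (one row per
#'   run: slope, stderr, nih, nih_norm, qc) and `pumps` (per-pump n, means
#'   and standard deviations). Methods: `print`, `summary`, `coef`
#'   (mean normalized NIH per pump), `confint` (per-pump t-intervals on the
#'   normalized NIH) and `plot`.
#' @export
nih_study <- function(samples, circuit = circuit_config(), calibration = NULL,
                      control_threshold = Inf) {
  req <- c("session_id", "pump_id", "role", "time_h")
  if (!all(req %in% names(samples)))
    stop_invalid("samples need columns ", paste(req, collapse = ", "))
  if (!"pfhb_mg_dl" %in% names(samples)) {
    if (!"absorbance" %in% names(samples) || is.null(calibration))
      stop_invalid("samples need pfhb_mg_dl, or absorbance plus a calibration")
    samples$pfhb_mg_dl <- as.numeric(absorbance_to_pfhb(samples$absorbance,
                                                        calibration))
  }
  if (!all(samples$role %in% c("test", "reference", "control")))
    stop_invalid("role must be test, reference or control")

  per_run_circuit <- all(c("volume_l", "flow_l_min", "hct_pct") %in% names(samples))
  key <- interaction(samples$session_id, samples$pump_id, drop = TRUE)
  runs <- do.call(rbind, lapply(split(samples, key), function(d) {
    d <- d[order(d$time_h), ]
    s <- pfhb_slope(d$time_h, d$pfhb_mg_dl)
    circ <- if (per_run_circuit)
      circuit_config(d$volume_l[1], d$flow_l_min[1], d$hct_pct[1])
    else circuit
    data.frame(session_id = d$session_id[1], pump_id = d$pump_id[1],
               role = d$role[1], n_samples = s$n,
               slope = s$slope, slope_stderr = s$stderr,
               nih = nih(s$slope, circ),
               stringsAsFactors = FALSE)
  }))
  rownames(runs) <- NULL

  # session reference normalization + control QC
  runs$nih_norm <- NA_real_
  runs$qc <- ""
  for (sid in unique(runs$session_id)) {
    in_s <- runs$session_id == sid
    ref <- which(in_s & runs$role == "reference")
    if (length(ref) != 1)
      stop_invalid("session '", sid, "' must contain exactly one reference run (found ",
                   length(ref), ")")
    ref_nih <- runs$nih[ref]
    test_like <- in_s & runs$role != "control"
    if (ref_nih > 0) {
      runs$nih_norm[test_like] <- normalize_to_reference(runs$nih[test_like],
                                                         ref_nih)
    } else {
      runs$qc[test_like] <- add_flag(runs$qc[test_like], "nonpositive_reference")
    }
    ctrl <- which(in_s & runs$role == "control")
    for (k in ctrl) {
      d <- samples[samples$session_id == sid &
                     samples$pump_id == runs$pump_id[k], ]
      cc <- control_check(d$time_h, d$pfhb_mg_dl, control_threshold)
      if (!cc$pass) runs$qc[in_s] <- add_flag(runs$qc[in_s], "control_fail")
    }
  }
  runs$qc[runs$slope < 0] <- add_flag(runs$qc[runs$slope < 0], "negative_slope")

  test_runs <- runs[runs$role == "test", ]
  pumps <- do.call(rbind, lapply(split(test_runs, test_runs$pump_id), function(d) {
    data.frame(pump_id = d$pump_id[1], n = nrow(d),
               mean_nih = mean(d$nih), sd_nih = stats::sd(d$nih),
               mean_nih_norm = mean(d$nih_norm),
               sd_nih_norm = stats::sd(d$nih_norm),
               stringsAsFactors = FALSE)
  }))
  rownames(pumps) <- NULL

  structure(list(runs = runs, pumps = pumps, circuit = circuit,
                 control_threshold = control_threshold,
                 call = match.call()),
            class = "nih_study")
}

add_flag <- function(qc, flag) ifelse(qc == "", flag, paste(qc, flag, sep = ","))

#' @export
print.nih_study <- function(x, digits = 4, ...) {
  cat(sprintf("Hemolysis study: %d runs in %d sessions, %d test pumps\n",
              nrow(x$runs), length(unique(x$runs$session_id)), nrow(x$pumps)))
  df <- x$pumps
  df[-1] <- lapply(df[-1], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.nih_study <- function(object, conf_level = 0.95, ...) {
  test_runs <- object$runs[object$runs$role == "test", ]
  ci <- do.call(rbind, lapply(split(test_runs, test_runs$pump_id), function(d) {
    if (nrow(d) >= 2) t_interval(d$nih_norm, conf_level)
    else c(lower = NA_real_, mean = mean(d$nih_norm), upper = NA_real_)
  }))
  out <- list(study = object,
              ci = data.frame(pump_id = rownames(ci), ci,
                              row.names = NULL, stringsAsFactors = FALSE),
              conf_level = conf_level,
              qc_flagged = sum(object$runs$qc != ""))
  class(out) <- "summary.nih_study"
  out
}

#' @export
print.summary.nih_study <- function(x, ...) {
  print(x$study)
  cat(sprintf("\nNormalized NIH, %d%% t-intervals per pump:\n",
              round(100 * x$conf_level)))
  df <- x$ci
  df[-1] <- lapply(df[-1], signif, digits = 4)
  print(df, row.names = FALSE)
  if (x$qc_flagged > 0)
    cat(sprintf("%d run(s) carry QC flags\n", x$qc_flagged))
  invisible(x)
}

#' @export
coef.nih_study <- function(object, ...) {
  stats::setNames(object$pumps$mean_nih_norm, object$pumps$pump_id)
}

#' @export
confint.nih_study <- function(object, parm, level = 0.95, ...) {
  s <- summary(object, conf_level = level)$ci
  if (!missing(parm)) s <- s[s$pump_id %in% parm, ]
  m <- as.matrix(s[, c("lower", "upper")])
  rownames(m) <- s$pump_id
  colnames(m) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  m
}

#' @export
plot.nih_study <- function(x, ...) {
  test_runs <- x$runs[x$runs$role == "test", ]
  graphics::boxplot(nih_norm ~ pump_id, data = test_runs,
                    xlab = "Pump", ylab = "NIH / NIH_ref",
                    main = "Normalized index of hemolysis", ...)
  means <- tapply(test_runs$nih_norm, test_runs$pump_id, mean)
  graphics::points(seq_along(means), means, col = "red", pch = 19)
  invisible(x)
}

#' Compare every pump of a study against a baseline
#'
#' Welch two-sample t-tests on the per-run normalized NIH values of each pump
#' against the baseline pump, with t-intervals per group — the summary table
#' a benchmark figure is drawn from.
#'
#' @param study an [nih_study()] fit.
#' @param baseline pump_id of the baseline group.
#' @param conf_level confidence level of the per-pump t-intervals.
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()];
#'   `"none"` (default) reports raw pairwise p-values.
#' @return data.frame with one row per pump: n, mean and CI of normalized
#'   NIH, and the Welch p-value against the baseline (NA for the baseline
#'   itself).
#' @export
compare_pumps <- function(study, baseline, conf_level = 0.95,
                          p_adjust = "none") {
  stopifnot(inherits(study, "nih_study"))
  test_runs <- study$runs[study$runs$role == "test", ]
  if (!baseline %in% test_runs$pump_id)
    stop_invalid("baseline pump '", baseline, "' not present in the study")
  base_vals <- test_runs$nih_norm[test_runs$pump_id == baseline]
  out <- do.call(rbind, lapply(split(test_runs, test_runs$pump_id), function(d) {
    ci <- if (nrow(d) >= 2) t_interval(d$nih_norm, conf_level)
      else c(lower = NA_real_, mean = mean(d$nih_norm), upper = NA_real_)
    p <- if (d$pump_id[1] == baseline ||
             nrow(d) < 2 || length(base_vals) < 2) NA_real_ else
      welch_test(d$nih_norm, base_vals)$p_value
    data.frame(pump_id = d$pump_id[1], n = nrow(d),
               mean_nih_norm = ci[["mean"]], ci_lower = ci[["lower"]],
               ci_upper = ci[["upper"]], p_vs_baseline = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$p_vs_baseline <- stats::p.adjust(out$p_vs_baseline, method = p_adjust)
  out
}
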