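# Seeded generator of synthetic hemolysis studies with known ground truth.
# The model mirrors the structure the analysis pipeline assumes: linear pfHb
# growth over hourly sampling, a multiplicative lognormal blood-sensitivity
# effect shared by every pump run in the same session (including the
# reference), additive Gaussian measurement noise, and a zero-slope control
# volume at rest.

stop_design <- function(...) {
  stop(errorCondition(paste0(...), class = c("hemopump_design_error", "error")))
}

#' Define a synthetic hemolysis study
#'
#' @param pumps data.frame with columns `pump_id`, `true_rate` (pfHb growth
#'   in mg/dl per hour at session effect 1) and optionally `weight` (relative
#'   number of runs; default 1, i.e. every pump is run equally often).
#' @param reference_rate true rate of the reference pump run in every session.
#' @param sessions number of sessions; each session runs `pumps_per_session`
#'   test pumps plus the reference and a control in parallel on one blood
#'   batch.
#' @param pumps_per_session test pumps per session (default 4).
#' @param duration_h total run duration in hours (default 6).
#' @param sampling_interval_h sampling interval in hours (default 1, the
#'   standard hourly protocol).
#' @param session_effect_sigma lognormal sdlog of the per-session blood
#'   sensitivity multiplier (default 0.8; together with `noise_sigma` this is
#'   calibrated so that the simulated raw-NIH coefficient of variation and
#'   the normalized-NIH standard deviation match the dispersion reported for
#'   the in vitro campaign the generator emulates).
#' @param noise_sigma additive Gaussian measurement noise on pfHb in mg/dl
#'   (default 5).
#' @param baseline_pfhb pfHb at t = 0 in mg/dl (default 10).
#' @param circuit a [circuit_config()] shared by all runs.
#' @param seed integer seed; mandatory, every simulation is reproducible.
#' @return object of class `study_design`.
#' @export
study_design <- function(pumps, reference_rate, sessions,
                         pumps_per_session = 4,
                         duration_h = 6, sampling_interval_h = 1,
                         session_effect_sigma = 0.8, noise_sigma = 5,
                         baseline_pfhb = 10,
                         circuit = circuit_config(), seed) {
  if (missing(seed)) stop_design("a seed is mandatory")
  if (!all(c("pump_id", "true_rate") %in% names(pumps)))
    stop_design("pumps needs columns pump_id and true_rate")
  if (anyDuplicated(pumps$pump_id)) stop_design("duplicate pump ids")
  if (any(pumps$true_rate < 0) || reference_rate < 0)
    stop_design("true rates must be non-negative")
  if (duration_h < sampling_interval_h)
    stop_design("duration must allow at least 2 samples")
  if (is.null(pumps$weight)) pumps$weight <- 1L
  design <- structure(list(
    pumps = pumps, reference_rate = reference_rate,
    sessions = as.integer(sessions),
    pumps_per_session = as.integer(pumps_per_session),
    duration_h = duration_h, sampling_interval_h = sampling_interval_h,
    session_effect_sigma = session_effect_sigma, noise_sigma = noise_sigma,
    baseline_pfhb = baseline_pfhb, circuit = circuit,
    seed = as.integer(seed)), class = "study_design")
  design$rotation <- rotation_schedule(design)  # fails early if infeasible
  design
}

# Deterministic round-robin: each pump appears `weight` times per cycle,
# repeats spread across the cycle so no session sees the same pump twice.
rotation_schedule <- function(design) {
  p <- design$pumps
  period <- sum(p$weight)
  slots_total <- design$sessions * design$pumps_per_session
  rotation <- character(period)
  for (i in seq_len(nrow(p))) {
    w <- p$weight[i]
    for (k in seq_len(w)) {
      pos <- floor(period * (k - 1) / w) + 1
      while (rotation[pos] != "") pos <- pos %% period + 1
      rotation[pos] <- p$pump_id[i]
    }
  }
  slots <- rep(rotation, length.out = slots_total)
  schedule <- split(slots, rep(seq_len(design$sessions),
                               each = design$pumps_per_session))
  if (any(vapply(schedule, anyDuplicated, integer(1)) > 0))
    stop_design("infeasible rotation: a session would run the same pump twice")
  schedule
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Synthetic study design: %d sessions x %d test pumps (+ reference, control)\n",
              x$sessions, x$pumps_per_session))
  cat(sprintf("  %d pumps, %g h at %g h sampling; sdlog(session) = %g, noise sd = %g mg/dl\n",
              nrow(x$pumps), x$duration_h, x$sampling_interval_h,
              x$session_effect_sigma, x$noise_sigma))
  invisible(x)
}

#' Simulate one session
#'
#' Draws the session's blood-sensitivity multiplier s ~ LogNormal(0, sigma_s)
#' and, for each pump run in parallel (tests, reference, control), samples
#' pfHb(t) = baseline + s * rate * t + N(0, sigma_noise) at the design's
#' sampling times. The control has rate 0.
#'
#' @param design a [study_design()].
#' @param session_index 1-based session number; also offsets the RNG
#'   substream so sessions are independently reproducible.
#' @param pump_ids test pumps of this session; defaults to the design's
#'   rotation schedule.
#' @return list with `samples` (data.frame of one row per blood sample) and
#'   `session_effect`.
#' @export
simulate_session <- function(design, session_index, pump_ids = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(pump_ids)) pump_ids <- design$rotation[[session_index]]
  set.seed(design$seed + session_index)
  s <- stats::rlnorm(1, 0, design$session_effect_sigma)
  times <- seq(0, design$duration_h, by = design$sampling_interval_h)
  rates <- c(stats::setNames(design$pumps$true_rate, design$pumps$pump_id)[pump_ids],
             REF = design$reference_rate, CTRL = 0)
  roles <- c(rep("test", length(pump_ids)), "reference", "control")
  effect <- c(rep(s, length(pump_ids) + 1), 1)  # control is at rest
  samples <- do.call(rbind, lapply(seq_along(rates), function(i) {
    data.frame(session_id = sprintf("S%02d", session_index),
               pump_id = names(rates)[i], role = roles[i], time_h = times,
               pfhb_mg_dl = design$baseline_pfhb +
                 effect[i] * rates[[i]] * times +
                 stats::rnorm(length(times), 0, design$noise_sigma),
               stringsAsFactors = FALSE)
  }))
  list(samples = samples, session_effect = s)
}

#' Simulate a full study
#'
#' Runs [simulate_session()] for every session of the design. Deterministic
#' given the design's seed.
#'
#' @param design a [study_design()].
#' @return object of class `simulated_study`: `samples` (data.frame in the
#'   layout [nih_study()] consumes), `truth` (configured rates, rate ratios
#'   vs the reference, and the drawn per-session effects) and the design.
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  sess <- lapply(seq_len(design$sessions), function(i) simulate_session(design, i))
  samples <- do.call(rbind, lapply(sess, `[[`, "samples"))
  rownames(samples) <- NULL
  effects <- vapply(sess, `[[`, numeric(1), "session_effect")
  truth <- list(
    rates = stats::setNames(design$pumps$true_rate, design$pumps$pump_id),
    reference_rate = design$reference_rate,
    rate_ratios = stats::setNames(design$pumps$true_rate / design$reference_rate,
                                  design$pumps$pump_id),
    session_effects = stats::setNames(effects,
                                      sprintf("S%02d", seq_len(design$sessions))))
  structure(list(samples = samples, truth = truth, design = design),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated hemolysis study: %d samples, %d sessions, seed %d\n",
              nrow(x$samples), x$design$sessions, x$design$seed))
  invisible(x)
}

#' The in vitro campaign layout as a synthetic design
#'
#' Eight impeller variants run four at a time alongside a reference pump, the
#' base design with twice the run count of the others (8 runs per variant, 16
#' for the base design at the default 18 sessions). True rates are set so the
#' configured rate ratios equal the normalized-NIH means of the reported
#' campaign, with the reference at 9.404 mg/dl/h.
#'
#' @param sessions number of sessions (default 18, i.e. 72 test-run slots).
#' @param seed integer seed.
#' @param ... overrides passed to [study_design()].
#' @return a [study_design()].
#' @export
paper_study_design <- function(sessions = 18, seed, ...) {
  ratios <- c(B = 0.625, `BH+` = 0.605, `BH-` = 0.948, A60 = 0.978,
              `D-` = 0.500, `RG+` = 0.458, SO = 0.933, `HH-` = 0.850)
  reference_rate <- 9.404
  pumps <- data.frame(pump_id = names(ratios),
                      true_rate = unname(ratios) * reference_rate,
                      weight = c(2L, rep(1L, 7)),
                      stringsAsFactors = FALSE)
  study_design(pumps, reference_rate = reference_rate, sessions = sessions,
               seed = seed, ...)
}

#' Write / read the study sample CSV
#'
#' One row per blood sample with columns `session_id`, `pump_id`, `role`,
#' `time_h`, `pfhb_mg_dl`; reading back reproduces the samples (times to
#' better than 1e-9 h).
#'
#' @param study a `simulated_study` or a samples data.frame.
#' @param path output CSV path.
#' @return `write_study_csv()` returns `path` invisibly; `read_study_csv()`
#'   returns the samples data.frame.
#' @export
write_study_csv <- function(study, path) {
  samples <- if (inherits(study, "simulated_study")) study$samples else study
  out <- samples
  for (col in c("time_h", "pfhb_mg_dl"))
    if (col %in% names(out)) out[[col]] <- sprintf("%.12g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(session_id = "character",
                                   pump_id = "character", role = "character")),
    error = function(e) stop_invalid("cannot parse study CSV: ",
                                     conditionMessage(e)))
  req <- c("session_id", "pump_id", "role", "time_h", "pfhb_mg_dl")
  missing_cols <- setdiff(req, names(df))
  if (nrow(df) > 0 && length(missing_cols) > 0)
    stop_invalid("study CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!df$role %in% c("test", "reference", "control"))
  if (length(bad) > 0)
    stop_invalid("invalid role at data line ", bad[1])
  df
}

#' Write the ground truth of a simulated study as JSON-like text
#'
#' @param study a `simulated_study`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_truth <- function(study, path) {
  stopifnot(inherits(study, "simulated_study"))
  tr <- study$truth
  fmt_map <- function(x) paste0(
    "{", paste(sprintf('"%s": %.12g', names(x), x), collapse = ", "), "}")
  writeLines(paste0(
    '{"rates": ', fmt_map(tr$rates),
    ', "reference_rate": ', sprintf("%.12g", tr$reference_rate),
    ', "rate_ratios": ', fmt_map(tr$rate_ratios),
    ', "session_effects": ', fmt_map(tr$session_effects), "}"), path)
  invisible(path)
}
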