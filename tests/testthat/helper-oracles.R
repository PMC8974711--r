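# Independent oracles kept free of the code paths they check.

# Pearson correlation straight from the product-moment definition
pearson_by_definition <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# noise-free pfHb series for one run
exact_series <- function(slope, times = 0:6, baseline = 10) {
  baseline + slope * times
}

# minimal single-session study frame
session_frame <- function(session_id, pump_id, role, slope,
                          times = 0:6, baseline = 10) {
  data.frame(session_id = session_id, pump_id = pump_id, role = role,
             time_h = times, pfhb_mg_dl = exact_series(slope, times, baseline),
             stringsAsFactors = FALSE)
}
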