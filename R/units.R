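# Unit conversions used at the package boundary. All internal computation is
# in SI (Pa, m^3/s, rad/s, m, radians); printed pump literature mixes mmHg,
# l/min, rpm, mm and degrees, so each quantity is converted exactly once.

#' Unit conversions for pump quantities
#'
#' Exact, invertible conversions between the units conventional in the blood
#' pump literature and SI. The millimetre-of-mercury is fixed at
#' 133.322 Pa/mmHg.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' mmhg_to_pa(350)        # nominal ECLS pressure rise in Pa
#' lmin_to_m3s(5)         # nominal flow in m^3/s
#' rpm_to_rads(7310)      # design speed in rad/s
#' @name units
NULL

# Pa per mmHg, fixed convention
MMHG_PA <- 133.322

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' @rdname units
#' @export
lmin_to_m3s <- function(x) x / 60000

#' @rdname units
#' @export
m3s_to_lmin <- function(x) x * 60000

#' @rdname units
#' @export
rpm_to_rads <- function(x) x * pi / 30

#' @rdname units
#' @export
rads_to_rpm <- function(x) x * 30 / pi

#' @rdname units
#' @export
deg_to_rad <- function(x) x * pi / 180

#' @rdname units
#' @export
rad_to_deg <- function(x) x * 180 / pi
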