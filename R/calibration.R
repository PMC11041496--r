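# Flow-band statistics (mean and SD of achieved flow, L/min) measured for
# each bobbin band on the two supported spirometers. Note the "best" band
# is the slowest: the bobbin labels coach slow inhalation, so achieved flow
# decreases good -> better -> best.
.flow_bands <- list(
  VOLDYNE_5000 = data.frame(label = c("good", "better", "best"),
                            level = 1:3,
                            mean_lpm = c(57.75, 44.31, 26.36),
                            sd_lpm = c(7.74, 5.49, 5.56)),
  VOLDYNE_2500 = data.frame(label = c("good", "better", "best"),
                            level = 1:3,
                            mean_lpm = c(28.45, 18.70, 12.24),
                            sd_lpm = c(3.34, 1.92, 2.36))
)

#' Device profile for a supported incentive spirometer
#'
#' Maps discrete sensor levels to nominal physical quantities for a given
#' spirometer model. Volume sensors sit at every marking of the device
#' scale: 500 mL spacing on the Voldyne 5000 (sensor k at k x 500 mL,
#' 500--5000 mL), 250 mL nominal spacing on the Voldyne 2500 (whose
#' markings the sensors align to only approximately; per-level offsets can
#' express the misalignment and default to 0). Flow levels 1--3 correspond
#' to the "good", "better" and "best" bobbin bands, with the measured
#' per-band flow mean and SD (L/min) stored as generative parameters.
#'
#' @param name `"VOLDYNE_5000"` or `"VOLDYNE_2500"`.
#' @param level_offsets_mL optional numeric vector of length 10 of per-level
#'   additive offsets from the nominal spacing, in mL.
#' @return An object of class `device_profile` with fields `name`,
#'   `volume_step_mL`, `level_offsets_mL`, and `flow_bands` (data.frame
#'   with columns `label`, `level`, `mean_lpm`, `sd_lpm`).
#' @examples
#' device_profile("VOLDYNE_5000")
#' @export
device_profile <- function(name = c("VOLDYNE_5000", "VOLDYNE_2500"),
                           level_offsets_mL = rep(0, 10)) {
  name <- match.arg(name)
  stopifnot(length(level_offsets_mL) == 10L, all(is.finite(level_offsets_mL)))
  structure(list(name = name,
                 volume_step_mL = if (name == "VOLDYNE_5000") 500 else 250,
                 level_offsets_mL = as.numeric(level_offsets_mL),
                 flow_bands = .flow_bands[[name]]),
            class = "device_profile")
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile> %s: %g mL volume-level spacing\n",
              x$name, x$volume_step_mL))
  cat("flow bands (L/min):\n")
  print(x$flow_bands, row.names = FALSE)
  invisible(x)
}

#' Convert a volume sensor level to its nominal volume
#'
#' @param profile a [device_profile()].
#' @param level integer volume level 0--10; level 0 (piston below the
#'   lowest sensor) maps to 0 mL.
#' @return Nominal volume in mL: `level * volume_step_mL` plus the
#'   profile's per-level offset.
#' @examples
#' level_to_volume(device_profile("VOLDYNE_5000"), 3)  # 1500
#' level_to_volume(device_profile("VOLDYNE_2500"), 4)  # 1000
#' @export
level_to_volume <- function(profile, level) {
  stopifnot(inherits(profile, "device_profile"))
  if (any(level != floor(level) | level < 0 | level > VOLUME_LEVEL_MAX))
    stop("volume level out of range 0-", VOLUME_LEVEL_MAX)
  off <- ifelse(level == 0, 0, profile$level_offsets_mL[pmax(level, 1)])
  as.numeric(level) * profile$volume_step_mL + off
}

#' Saturated water vapor pressure
#'
#' Antoine-type closed form for the saturation vapor pressure of water,
#' `exp(20.386 - 5132 / (T + 273.15))` mmHg. At body temperature (37 C) it
#' gives 46.49 mmHg, the quantity conventionally rounded to 47 mmHg in
#' respiratory gas corrections.
#'
#' @param temp_C temperature in degrees Celsius.
#' @return Vapor pressure in mmHg.
#' @examples
#' saturated_vapor_pressure(37)
#' @export
saturated_vapor_pressure <- function(temp_C) {
  exp(20.386 - 5132 / (temp_C + 273.15))
}

#' Ambient measurement conditions for BTPS correction
#'
#' @param ambient_temp_C ambient (spirometer) gas temperature, degrees C;
#'   must be positive and at most `body_temp_C`.
#' @param pressure_mmHg barometric pressure; must exceed the ambient
#'   saturation vapor pressure.
#' @param body_temp_C body temperature, default 37.
#' @param body_svp_mmHg saturation vapor pressure at body temperature used
#'   in the correction denominator. Default `NULL` evaluates
#'   [saturated_vapor_pressure()] at `body_temp_C` (46.49 mmHg at 37 C), so
#'   that the correction is exactly the identity when ambient conditions
#'   equal body conditions; set to 47 to use the rounded clinical constant
#'   instead.
#' @return An object of class `btps_conditions`.
#' @examples
#' btps_conditions(20, 760)
#' @export
btps_conditions <- function(ambient_temp_C, pressure_mmHg, body_temp_C = 37,
                            body_svp_mmHg = NULL) {
  if (!(ambient_temp_C > 0 && ambient_temp_C <= body_temp_C))
    stop("ambient_temp_C must lie in (0, body_temp_C]")
  if (pressure_mmHg <= saturated_vapor_pressure(ambient_temp_C))
    stop("pressure must exceed the ambient saturation vapor pressure")
  if (is.null(body_svp_mmHg))
    body_svp_mmHg <- saturated_vapor_pressure(body_temp_C)
  structure(list(ambient_temp_C = ambient_temp_C,
                 pressure_mmHg = pressure_mmHg,
                 body_temp_C = body_temp_C,
                 body_svp_mmHg = body_svp_mmHg),
            class = "btps_conditions")
}

#' BTPS volume correction factor
#'
#' Converts a gas volume measured at ambient temperature, ambient pressure,
#' saturated (ATPS) to body temperature, pressure, saturated (BTPS):
#'
#' \deqn{f = \frac{T_{body} + 273.15}{T_{amb} + 273.15} \cdot
#'           \frac{P_B - P_{H_2O}(T_{amb})}{P_B - P_{H_2O}(T_{body})}}
#'
#' with \eqn{P_{H_2O}} from [saturated_vapor_pressure()]. The factor is 1
#' exactly when ambient conditions equal body conditions, exceeds 1 for
#' cooler ambient gas, and strictly decreases toward 1 as the ambient
#' temperature rises to body temperature at fixed pressure.
#'
#' @param cond a [btps_conditions()].
#' @return Dimensionless multiplicative factor.
#' @examples
#' btps_factor(btps_conditions(37, 760))  # exactly 1
#' btps_factor(btps_conditions(20, 760))  # about 1.1005
#' @export
btps_factor <- function(cond) {
  stopifnot(inherits(cond, "btps_conditions"))
  ph2o <- saturated_vapor_pressure(cond$ambient_temp_C)
  if (cond$pressure_mmHg <= ph2o ||
        cond$pressure_mmHg <= cond$body_svp_mmHg)
    stop("barometric pressure must exceed the water vapor pressure")
  ((cond$body_temp_C + 273.15) / (cond$ambient_temp_C + 273.15)) *
    (cond$pressure_mmHg - ph2o) / (cond$pressure_mmHg - cond$body_svp_mmHg)
}

#' Flowmeter dead-volume calibration
#'
#' The in-line flowmeter registers a fixed apparatus (dead) volume before
#' the spirometer display starts to move; it is modeled as additive and
#' constant across breath sizes and subtracted from every raw reading.
#'
#' @param dead_volume_mL non-negative dead volume, default the measured
#'   183.75 mL.
#' @return An object of class `flowmeter_calibration`.
#' @export
flowmeter_calibration <- function(dead_volume_mL = 183.75) {
  stopifnot(is.finite(dead_volume_mL), dead_volume_mL >= 0)
  structure(list(dead_volume_mL = as.numeric(dead_volume_mL)),
            class = "flowmeter_calibration")
}

#' @export
print.flowmeter_calibration <- function(x, ...) {
  cat(sprintf("<flowmeter_calibration> dead volume %.2f mL\n",
              x$dead_volume_mL))
  invisible(x)
}

#' Subtract the flowmeter dead volume from a raw reading
#'
#' @param raw_mL non-negative raw flowmeter volume(s), mL.
#' @param cal a [flowmeter_calibration()].
#' @return `raw_mL - dead_volume_mL`, floored at 0.
#' @examples
#' subtract_dead_volume(1183.75, flowmeter_calibration())  # 1000
#' @export
subtract_dead_volume <- function(raw_mL, cal = flowmeter_calibration()) {
  stopifnot(inherits(cal, "flowmeter_calibration"), all(raw_mL >= 0))
  pmax(raw_mL - cal$dead_volume_mL, 0)
}

#' Estimate the flowmeter dead volume
#'
#' Calibrates the dead volume by holding the spirometer at a known display
#' level (1000 mL in the reference procedure) and averaging the raw
#' flowmeter readings over repeated breaths: the estimate is
#' `mean(raw) - display`, floored at 0.
#'
#' @param raw_readings_mL raw flowmeter readings in mL, at least one.
#' @param display_volume_mL the spirometer display volume held during
#'   calibration, mL, positive.
#' @return A [flowmeter_calibration()] with the estimated dead volume.
#' @examples
#' calibrate_dead_volume(rep(1183.75, 10), 1000)  # dead volume 183.75
#' @export
calibrate_dead_volume <- function(raw_readings_mL, display_volume_mL) {
  if (length(raw_readings_mL) < 1L) stop("need at least one raw reading")
  stopifnot(display_volume_mL > 0, all(is.finite(raw_readings_mL)))
  flowmeter_calibration(max(mean(raw_readings_mL) - display_volume_mL, 0))
}
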