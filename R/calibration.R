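#' Calibration lines mapping the ratio-of-ratios R to SpO2
#'
#' Pulse oximeters estimate arterial oxygen saturation from the dimensionless
#' ratio of ratios \eqn{R = (AC/DC)_{red} / (AC/DC)_{IR}} through an empirical
#' linear calibration \eqn{SpO_2\% = intercept - slope \cdot R}. Two presets
#' are provided: \code{"classic"} (\eqn{110 - 25R}), the approximation commonly
#' used in the pulse-oximetry literature, and \code{"maxim"} (\eqn{104 - 17R}),
#' the empirical line published by Maxim Integrated for their sensor modules
#' (e.g. the MAX30102).
#'
#' @param name identifier for the line.
#' @param intercept additive constant in percent; must be positive.
#' @param slope percent per unit R; must be positive.
#'
#' @return An object of class \code{calibration_line} with fields
#'   \code{name}, \code{intercept}, \code{slope}.
#' @examples
#' calibration_line("classic", 110, 25)
#' spo2_from_ratio(1, calibration("maxim"))  # 87
#' @export
calibration_line <- function(name, intercept, slope) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(intercept) || length(intercept) != 1L || intercept <= 0)
    stop("calibration intercept must be a single positive number", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("calibration slope must be a single positive number", call. = FALSE)
  structure(list(name = name, intercept = as.numeric(intercept),
                 slope = as.numeric(slope)),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line '%s'>  SpO2%% = %g - %g * R\n",
              x$name, x$intercept, x$slope))
  invisible(x)
}

#' Look up a calibration preset by name
#'
#' @param preset \code{"classic"} (110 - 25R) or \code{"maxim"} (104 - 17R),
#'   or an existing \code{calibration_line} (returned unchanged). The
#'   \code{"maxim"} line is the package default throughout, since it matches
#'   the sensor family the simulated device models.
#' @return A \code{calibration_line}.
#' @export
calibration <- function(preset = c("maxim", "classic")) {
  if (inherits(preset, "calibration_line")) return(preset)
  preset <- match.arg(preset)
  switch(preset,
         classic = calibration_line("classic", 110, 25),
         maxim   = calibration_line("maxim", 104, 17))
}

#' Invert a calibration line: the ratio R that yields a given SpO2
#'
#' @param spo2_percent target saturation in percent.
#' @param cal a \code{calibration_line} or preset name.
#' @return The ratio R such that \code{intercept - slope * R == spo2_percent}.
#'   Errors if the required R is not strictly positive (saturation not
#'   attainable on that line).
#' @examples
#' ratio_for_spo2(85, "classic")  # 1.0
#' @export
ratio_for_spo2 <- function(spo2_percent, cal = calibration()) {
  cal <- calibration(cal)
  stopifnot(is.numeric(spo2_percent), length(spo2_percent) == 1L)
  r <- (cal$intercept - spo2_percent) / cal$slope
  if (!is.finite(r) || r <= 0)
    stop(sprintf(
      "SpO2 of %g%% is not attainable with calibration '%s' (requires R = %g <= 0)",
      spo2_percent, cal$name, r), call. = FALSE)
  r
}

#' Apply a calibration line: SpO2 from the ratio R
#'
#' Computes \code{intercept - slope * R} and clamps the result to the physical
#' range [0, 100]. Clamping is flagged via the \code{"clamped"} attribute (the
#' unclamped value is kept in \code{"raw"}) rather than raised as an error,
#' because small R on the classic line legitimately maps above 100.
#'
#' @param r ratio of ratios, must be >= 0.
#' @param cal a \code{calibration_line} or preset name.
#' @return SpO2 in percent, with attributes \code{clamped} and \code{raw}.
#' @examples
#' spo2_from_ratio(1.0, "classic")  # 85
#' spo2_from_ratio(0.2, "classic")  # 100, clamped (raw 105)
#' @export
spo2_from_ratio <- function(r, cal = calibration()) {
  cal <- calibration(cal)
  stopifnot(is.numeric(r), length(r) == 1L)
  if (!is.finite(r) || r < 0)
    stop("ratio R must be finite and >= 0", call. = FALSE)
  raw <- cal$intercept - cal$slope * r
  val <- min(max(raw, 0), 100)
  structure(val, clamped = !identical(val, raw), raw = raw)
}

#' Oxygen saturation from hemoglobin amounts
#'
#' The defining identity of SpO2: the percentage of oxygenated hemoglobin out
#' of total hemoglobin, \eqn{100 \cdot HbO_2 / (HbO_2 + Hb)}.
#'
#' @param hbo2 amount of oxygenated hemoglobin, >= 0.
#' @param hb amount of deoxygenated hemoglobin, >= 0.
#' @return Saturation in percent.
#' @export
spo2_definition <- function(hbo2, hb) {
  stopifnot(is.numeric(hbo2), is.numeric(hb))
  if (any(hbo2 < 0) || any(hb < 0))
    stop("hemoglobin amounts must be non-negative", call. = FALSE)
  if (any(hbo2 + hb == 0))
    stop("total hemoglobin is zero; saturation undefined", call. = FALSE)
  100 * hbo2 / (hbo2 + hb)
}
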