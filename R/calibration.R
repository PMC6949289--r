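#' Force sensor calibration
#'
#' The isometric force transducers output 0--5 V proportional to the exerted
#' force over a bidirectional +/- 100 N range, so the transfer function is the
#' affine map `force = volts * 40 - 100` (N).  `volts_to_newtons()` applies
#' it; `newtons_to_volts()` inverts it.  Values outside the sensor span are
#' converted anyway (the map is affine) but raise a warning, since they cannot
#' come from a healthy 0--5 V sensor.
#'
#' @param v analog sensor reading in volts.
#' @param n force in newtons.
#' @param gain slope of the transfer function in N/V.
#' @param offset intercept in N.
#' @param span numeric length-2, the valid sensor output range in volts.
#' @return force in newtons, or volts for the inverse.
#' @examples
#' volts_to_newtons(c(0, 2.5, 5))   # -100, 0, +100 N
#' newtons_to_volts(volts_to_newtons(1.23))
#' @export
volts_to_newtons <- function(v, gain = 40, offset = -100, span = c(0, 5)) {
  if (any(v < span[1] - 1e-9 | v > span[2] + 1e-9, na.rm = TRUE))
    warning("sensor reading outside the ", span[1], "-", span[2], " V span",
            call. = FALSE)
  v * gain + offset
}

#' @rdname volts_to_newtons
#' @export
newtons_to_volts <- function(n, gain = 40, offset = -100, span = c(0, 5)) {
  v <- (n - offset) / gain
  if (any(v < span[1] - 1e-9 | v > span[2] + 1e-9, na.rm = TRUE))
    warning("force outside the range representable on the ", span[1], "-",
            span[2], " V sensor span", call. = FALSE)
  v
}
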