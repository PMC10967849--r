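#' Canonical sensor and channel layout
#'
#' The pipeline uses five IMUs (waist, left/right thigh, left/right foot),
#' each contributing three gyroscope axes (rad/s) and three accelerometer
#' axes (m/s^2), for 30 channels in a fixed documented order. Magnetometer
#' axes are not used.
#'
#' @return `gait_channels()` returns the 30 channel names in canonical order,
#'   `<sensor>_<gx|gy|gz|ax|ay|az>`.
#' @export
#' @examples
#' gait_channels()[1:6]
gait_channels <- function() {
  as.vector(t(outer(gait_sensors(), c("gx", "gy", "gz", "ax", "ay", "az"),
                    paste, sep = "_")))
}

#' @rdname gait_channels
#' @return `gait_sensors()` returns the five sensor names.
#' @export
gait_sensors <- function() {
  c("waist", "thigh_l", "thigh_r", "foot_l", "foot_r")
}

#' Motion states and gait-phase classes
#'
#' Ten motion states are recognized: standing (SD), level walking (LW),
#' going up/down stairs (US/DS), up/down slopes (USL/DSL), turning left/right
#' (TL/TR) and left/right steering (LS/RS). Within a level-walking gait cycle
#' six gait events are tracked; the inter-event segment is labeled by its
#' starting event, giving six phase classes in cyclic order.
#'
#' @return Character vector of state codes, or of the six phase classes in
#'   their cyclic order.
#' @export
#' @examples
#' motion_states()
#' phase_classes()
motion_states <- function() {
  c("SD", "LW", "US", "DS", "USL", "DSL", "TL", "TR", "LS", "RS")
}

#' @rdname motion_states
#' @export
phase_classes <- function() {
  c("L-HS", "R-TO", "R-HMax", "R-HS", "L-TO", "L-HMax")
}

# event kinds and sides used by gait_event()
event_kinds <- function() c("HS", "TO", "HMax")
event_sides <- function() c("L", "R")

phase_of <- function(side, kind) paste(side, kind, sep = "-")
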