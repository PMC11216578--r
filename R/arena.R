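#' Arena geometry and closed-loop trigger configuration
#'
#' Describes the square test arena: a 32 cm box with a square shelter against
#' one wall, a circular trigger ("threat") zone boundary 10 cm from the
#' shelter centre, and the centre / edge annuli used for occupancy metrics.
#' Coordinates have the origin at the arena centre, in cm, with y increasing
#' away from the shelter wall.
#'
#' @param arena_side Side length of the square arena (cm).
#' @param shelter_center Shelter centre, length-2 numeric (cm).
#' @param shelter_side Side of the square shelter (cm).
#' @param trigger_radius Distance from the shelter centre beyond which the
#'   closed loop triggers a stimulus (cm).
#' @param refractory Minimum interval between triggered stimuli (s).
#' @param center_radius Radius of the central occupancy disc (cm).
#' @param edge_radius Radius beyond which a position counts as "edge" (cm).
#' @param frame_rate Tracking frame rate (Hz).
#' @param exit_hysteresis Dilation (cm) of the shelter boundary a centroid
#'   must cross outward before an episode counts as a full-body exit;
#'   re-entry is scored at the undilated boundary.
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(arena_side = 32,
                         shelter_center = c(0, -(32 / 2 - 9 / 2)),
                         shelter_side = 9,
                         trigger_radius = 10,
                         refractory = 30,
                         center_radius = 7,
                         edge_radius = 14,
                         frame_rate = 60,
                         exit_hysteresis = 2) {
  check_finite(list(arena_side, shelter_center, shelter_side, trigger_radius,
                    refractory, center_radius, edge_radius, frame_rate),
               "arena_config")
  stop_if(frame_rate <= 0, "frame_rate must be > 0")
  stop_if(!(center_radius > 0 && center_radius < edge_radius &&
              edge_radius < arena_side),
          "need 0 < center_radius < edge_radius < arena_side")
  stop_if(trigger_radius <= shelter_side / 2,
          "trigger_radius must exceed half the shelter side")
  stop_if(trigger_radius >= arena_side / 2 + shelter_side,
          "trigger_radius too large for this arena")
  half <- arena_side / 2
  stop_if(any(abs(shelter_center) > half), "shelter outside arena")
  structure(list(arena_side = arena_side, shelter_center = shelter_center,
                 shelter_side = shelter_side, trigger_radius = trigger_radius,
                 refractory = refractory, center_radius = center_radius,
                 edge_radius = edge_radius, frame_rate = frame_rate,
                 exit_hysteresis = exit_hysteresis),
            class = "arena_config")
}

# distance from points to the shelter centre
shelter_distance <- function(x, y, config) {
  sqrt((x - config$shelter_center[1])^2 + (y - config$shelter_center[2])^2)
}

# inside the (optionally dilated) square shelter footprint
in_shelter <- function(x, y, config, dilate = 0) {
  half <- config$shelter_side / 2 + dilate
  abs(x - config$shelter_center[1]) <= half &
    abs(y - config$shelter_center[2]) <= half
}
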