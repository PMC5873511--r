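# Evasive steering from the differential excitation of the left- and
# right-preferring layers. An object crossing or looming on one side
# excites the layer preferring motion toward that side; the evasive
# maneuver points away from it.

#' Evasive steering decision
#'
#' The difference between the zone-restricted excitations of the right- and
#' left-preferring layers must strictly exceed `threshold` to indicate a
#' steering direction: stronger excitation of the right-preferring layer
#' calls for steering to the LEFT, and vice versa. The force is the raw
#' absolute excitation difference (dimensionless; downstream users apply
#' their own gain).
#'
#' @param exc_left,exc_right [layer_excitation] results of the left- and
#'   right-preferring layers.
#' @param threshold excitation difference that must be strictly exceeded
#'   (default 6).
#' @return list with `direction` (`"none"`, `"left"` or `"right"`) and
#'   `force` (absolute excitation difference).
#' @export
steering_vector <- function(exc_left, exc_right, threshold = 6) {
  diff <- exc_right$e_layer - exc_left$e_layer
  direction <- if (diff > threshold) {
    "left"
  } else if (-diff > threshold) {
    "right"
  } else {
    "none"
  }
  list(direction = direction, force = abs(diff))
}
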