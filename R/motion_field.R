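# Local motion vectors at 45-degree precision from the four
# direction-selective layers, whole-field coherence detection (camera shake
# / self-motion), and ground-shadow classification and suppression.

DIRECTION_SET <- seq(0, 315, by = 45)

#' Local motion vectors from the four direction-selective layers
#'
#' Per element, the number of excited inhibitory elements (i-potential
#' strictly above `i_level`) is counted for each layer within a circle of
#' radius `radius` (the focal element included). A vector is assigned only
#' where the total count over all four layers strictly exceeds
#' `min_excited`. If one layer's count exceeds every other layer's count by
#' strictly more than `margin`, its preferred direction wins; if exactly two
#' layers exceed both remaining layers by that margin and their preferred
#' directions are 90 degrees apart, the bisecting diagonal is assigned. Two
#' dominating layers 180 degrees apart are contradictory: no vector.
#'
#' @param layers named list of the four [inhibitory_layer]s.
#' @param radius counting-circle radius in elements (default 3).
#' @param min_excited total excited count that must be strictly exceeded
#'   (default 9).
#' @param margin dominance margin that must be strictly exceeded (default 4).
#' @param i_level i-potential level that must be strictly exceeded for an
#'   element to count as excited (default 0.1).
#' @return a `motion_field` list: `direction` (matrix of degrees in
#'   {0, 45, ..., 315}, `NA` where undetermined; 0 = rightward, 90 = up,
#'   270 = toward the lower frame border) and `counts` (per-layer count
#'   matrices).
#' @export
local_motion_vectors <- function(layers, radius = 3, min_excited = 9,
                                 margin = 4, i_level = 0.1) {
  counts <- lapply(layers, function(l) disk_count(l$i_potentials > i_level, radius))
  cr <- counts$right; cu <- counts$up; cl <- counts$left; cd <- counts$down
  total <- cr + cu + cl + cd
  active <- total > min_excited

  cnt <- list(right = cr, up = cu, left = cl, down = cd)
  dom <- list(
    right = cr > cu + margin & cr > cl + margin & cr > cd + margin,
    up    = cu > cr + margin & cu > cl + margin & cu > cd + margin,
    left  = cl > cr + margin & cl > cu + margin & cl > cd + margin,
    down  = cd > cr + margin & cd > cu + margin & cd > cl + margin
  )

  dir <- matrix(NA_real_, nrow(cr), ncol(cr))
  dir[active & dom$right] <- 0
  dir[active & dom$up]    <- 90
  dir[active & dom$left]  <- 180
  dir[active & dom$down]  <- 270
  # two adjacent layers each exceed both remaining layers, neither singly
  # dominant -> bisecting diagonal
  pair <- function(a, b) {
    rest <- setdiff(names(cnt), c(a, b))
    active & !dom[[a]] & !dom[[b]] &
      cnt[[a]] > cnt[[rest[1]]] + margin & cnt[[a]] > cnt[[rest[2]]] + margin &
      cnt[[b]] > cnt[[rest[1]]] + margin & cnt[[b]] > cnt[[rest[2]]] + margin
  }
  dir[pair("right", "up")]   <- 45
  dir[pair("up", "left")]    <- 135
  dir[pair("left", "down")]  <- 225
  dir[pair("down", "right")] <- 315

  structure(list(direction = dir, counts = counts), class = "motion_field")
}

#' Whole-field coherent-motion check
#'
#' For each of the 8 quantized directions, the fraction of vector-bearing
#' elements (frame-wide) whose direction lies within +/-45 degrees of it is
#' computed; the flag fires when the maximum fraction strictly exceeds
#' `limit`. Coherent whole-field motion indicates self-motion or camera
#' shake, during which risk estimation is suspended. A field without any
#' vectors never fires.
#'
#' @param field a [local_motion_vectors] result.
#' @param limit fraction that must be strictly exceeded (default 0.5).
#' @return list with `flag` and `coherence_fraction` (the maximum fraction;
#'   0 when no vectors exist).
#' @export
coherence_check <- function(field, limit = 0.5) {
  dirs <- field$direction[!is.na(field$direction)]
  if (length(dirs) == 0) {
    return(list(flag = FALSE, coherence_fraction = 0))
  }
  fracs <- vapply(DIRECTION_SET, function(d) {
    delta <- abs(((dirs - d + 180) %% 360) - 180)
    mean(delta <= 45)
  }, numeric(1))
  top <- max(fracs)
  list(flag = top > limit, coherence_fraction = top)
}

#' Classify and suppress ground-shadow elements
#'
#' Ground shadows race toward the lower frame border as the vehicle
#' approaches them, producing downward motion vectors in the lower half of
#' the danger zone. If strictly more than `fraction` of all elements in the
#' lower half of the zone (members strictly below the zone center's row)
#' carry a vector pointing toward the lower border within +/-45 degrees
#' (directions 225, 270, 315), each such element is flagged as a shadow
#' element and its e-potential and all four i-potentials are set to 0
#' before risk and steering are computed.
#'
#' @param field a [local_motion_vectors] result.
#' @param zone a [build_zone] result.
#' @param e e-potential matrix.
#' @param layers named list of the four [inhibitory_layer]s.
#' @param fraction lower-half fraction that must be strictly exceeded
#'   (default 0.2).
#' @return list with `shadow_mask` (logical matrix), `e` (modified), and
#'   `layers` (modified).
#' @export
shadow_suppression <- function(field, zone, e, layers, fraction = 0.2) {
  lower <- zone$lower_half
  downward <- !is.na(field$direction) & field$direction %in% c(225, 270, 315)
  candidates <- lower & downward
  n_lower <- sum(lower)
  mask <- matrix(FALSE, nrow(e), ncol(e))
  if (n_lower > 0 && sum(candidates) / n_lower > fraction) {
    mask <- candidates
    e[mask] <- 0
    for (d in names(layers)) {
      layers[[d]]$i_potentials[mask] <- 0
    }
  }
  list(shadow_mask = mask, e = e, layers = layers)
}
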