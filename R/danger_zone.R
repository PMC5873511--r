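# The danger zone and the per-frame collision-risk terms.
#
# The danger zone is the circular image region in which frontal collisions
# are most likely; its size and position are set per run (in a vehicle both
# follow from speed and steering). The top and bottom quarters of the frame
# are excluded to avoid bridges/overhead signs and ground shadows/lane
# markings respectively. All risk and steering sums are restricted to the
# zone.

#' Build a danger zone
#'
#' Enumerates the elements inside the circle of radius `radius` about
#' `center`, excluding the horizontal top and bottom exclusion bands
#' (fractions of the full frame height). Membership is computed once and
#' reused for every frame.
#'
#' @param frame_shape `c(nrow, ncol)` of the frames.
#' @param center zone center `c(col, row)` in elements (1-based); defaults
#'   to the frame center.
#' @param radius zone radius in elements.
#' @param top_exclusion,bottom_exclusion excluded fractions of the frame
#'   height at the top and bottom borders.
#' @return a `danger_zone` list: `mask` (logical matrix), `dist` (Euclidean
#'   distance of every element to the zone center), `s` (member count),
#'   `center`, `radius`, `lower_half` (logical matrix: members strictly
#'   below the zone center's row).
#' @export
build_zone <- function(frame_shape, center = NULL, radius,
                       top_exclusion = 0.25, bottom_exclusion = 0.25) {
  nr <- frame_shape[1]
  nc <- frame_shape[2]
  if (is.null(center)) center <- c((nc + 1) / 2, (nr + 1) / 2)
  cx <- center[1]
  cy <- center[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dist <- sqrt((col - cx)^2 + (row - cy)^2)
  keep_rows <- row > nr * top_exclusion & row <= nr * (1 - bottom_exclusion)
  mask <- dist <= radius & keep_rows
  s <- sum(mask)
  if (s == 0) {
    stop("danger zone is empty: circle does not intersect the non-excluded band")
  }
  structure(
    list(
      mask = mask, dist = dist, s = s,
      center = c(col = cx, row = cy), radius = radius,
      lower_half = mask & row > cy
    ),
    class = "danger_zone"
  )
}

#' @export
print.danger_zone <- function(x, ...) {
  cat(sprintf(
    "<danger_zone> center (%.1f, %.1f), radius %.1f, %d member elements\n",
    x$center[["col"]], x$center[["row"]], x$radius, x$s
  ))
  invisible(x)
}

#' Primary collision-risk term
#'
#' Sum of zone-member e-potentials exceeding the threshold, multiplied by
#' the relative excitation w/s, where w is the number of strongly excited
#' members (e-potential > threshold) and s the zone size.
#'
#' @param e e-potential matrix (thresholded and cluster-filtered).
#' @param zone a [build_zone] result.
#' @param threshold the e-potential threshold.
#' @return list with `r_coll` and `w`.
#' @export
r_coll <- function(e, zone, threshold) {
  qual <- zone$mask & e > threshold
  w <- sum(qual)
  list(r_coll = (w / zone$s) * sum(e[qual]), w = w)
}

#' Center-proximity risk term
#'
#' Excitation close to the zone center is weighted up by summing inverse
#' distances: over members with e-potential above the qualification level
#' and distance d to the zone center with 0 < d < radius/2,
#' `r_dist = gain * sum(1/d)`. Elements exactly at the center are excluded
#' (d = 0). N is the number of qualifying members; it gates whether the
#' term is added to the total risk.
#'
#' @param e e-potential matrix (thresholded and cluster-filtered).
#' @param zone a [build_zone] result.
#' @param threshold the e-potential threshold; qualification uses
#'   `e > max(0.5, threshold)`.
#' @param gain gain controlling the contribution of the term (default 10).
#' @return list with `r_dist` and `n_qualifying`.
#' @export
r_dist <- function(e, zone, threshold, gain = 10) {
  level <- max(0.5, threshold)
  qual <- zone$mask & e > level & zone$dist > 0 & zone$dist < zone$radius / 2
  n <- sum(qual)
  list(r_dist = gain * sum(1 / zone$dist[qual]), n_qualifying = n)
}

#' Overstimulation check
#'
#' Whole-field stimulation (self-motion, camera shake) floods the zone with
#' excitation; risk estimation is then unreliable and must be suspended.
#' Fires when strictly more than `limit` of the zone members have
#' e-potentials above 0.5.
#'
#' @param e e-potential matrix.
#' @param zone a [build_zone] result.
#' @param limit fraction of zone members that must be exceeded (default 0.40).
#' @return logical flag.
#' @export
overstimulation_check <- function(e, zone, limit = 0.40) {
  sum(e[zone$mask] > 0.5) / zone$s > limit
}

#' Combine the risk terms into the per-frame risk result
#'
#' `total = r_coll + r_dist` when strictly more than `n_gate` members
#' qualified for the distance term, else `r_coll` alone. When a suspension
#' flag is set the total is forced to 0 and the reason recorded.
#'
#' @param rc result of [r_coll].
#' @param rd result of [r_dist].
#' @param overstimulated logical flag from [overstimulation_check].
#' @param coherent_motion logical flag from [coherence_check].
#' @param n_gate qualification count that must be strictly exceeded for the
#'   distance term to be added (default 15).
#' @return list with `r_coll`, `r_dist`, `n_qualifying`, `w`, `total_risk`,
#'   `suspended`, `suspension_reason`.
#' @export
combine_risk <- function(rc, rd, overstimulated = FALSE,
                         coherent_motion = FALSE, n_gate = 15) {
  total <- if (rd$n_qualifying > n_gate) rc$r_coll + rd$r_dist else rc$r_coll
  suspended <- overstimulated || coherent_motion
  reason <- if (overstimulated) {
    "overstimulation"
  } else if (coherent_motion) {
    "coherent_motion"
  } else {
    "none"
  }
  if (suspended) total <- 0
  list(
    r_coll = rc$r_coll, r_dist = rd$r_dist,
    n_qualifying = rd$n_qualifying, w = rc$w,
    total_risk = total, suspended = suspended, suspension_reason = reason
  )
}
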