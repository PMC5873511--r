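# Four direction-selective layers built on delayed, distance-weighted,
# decaying lateral inhibition — the algorithmic counterpart of locust
# elementary motion detectors (EMDs). Each layer receives the excitatory
# layer's e-potentials and subtracts inhibition that was generated one
# processing step earlier by the 11 elements of a hemicircle on the layer's
# null side. For preferred-direction motion the inhibitors were not yet
# excited when the focal element fires, so the response survives; for
# null-direction motion the delayed inhibition arrives together with the
# excitation and cancels it.
#
# Preferred directions and their inhibitor half-planes (screen coordinates,
# rows grow downward):
#   right: inhibitors at dx >= 1   up:   inhibitors at dy <= -1 (above)
#   left:  inhibitors at dx <= -1  down: inhibitors at dy >= 1 (below)

LAYER_DIRECTIONS <- c("right", "up", "left", "down")
LAYER_ANGLES <- c(right = 0, up = 90, left = 180, down = 270)

#' Hemicircle inhibitor offsets for a direction-selective layer
#'
#' All lattice offsets at Euclidean distance <= `radius` lying strictly in
#' the half-plane on the layer's null side: for the rightward-preferring
#' layer these are the offsets with `dx >= 1`; the other three layers are
#' exact successive 90-degree rotations of that list (order preserved, so
#' corresponding floating-point sums are performed in identical order under
#' rotation of the input). At radius 3 each hemicircle contains exactly 11
#' elements.
#'
#' @param direction one of `"right"`, `"up"`, `"left"`, `"down"`.
#' @param radius hemicircle radius in elements (default 3).
#' @return data.frame with columns `dx`, `dy`, `d`.
#' @export
hemicircle_offsets <- function(direction = c("right", "up", "left", "down"),
                               radius = 3) {
  direction <- match.arg(direction)
  base <- disk_offsets(radius, include_center = FALSE)
  base <- base[base$dx >= 1, ]
  base <- base[order(base$dx, base$dy), ]
  rownames(base) <- NULL
  turns <- match(direction, LAYER_DIRECTIONS) - 1
  off <- base
  if (turns > 0) {
    for (t in seq_len(turns)) {
      rot <- rotate_offset_ccw(off$dx, off$dy)
      off$dx <- rot$dx
      off$dy <- rot$dy
    }
  }
  off
}

#' Initialise one inhibitory layer
#'
#' @param dim frame shape `c(nrow, ncol)`.
#' @param direction the layer's preferred direction.
#' @param inhibition_weight weighting factor applied to the distance-weighted
#'   sum (default 0.35).
#' @param reset_threshold margin by which fresh inhibition must exceed the
#'   decayed stored value to restart the decay clock (default 1.5).
#' @param radius hemicircle radius in elements (default 3).
#' @param decay_step inhibition lost per processing step per counter unit
#'   (default 2).
#' @return an `inhibitory_layer` list.
#' @export
inhibitory_layer <- function(dim, direction, inhibition_weight = 0.35,
                             reset_threshold = 1.5, radius = 3,
                             decay_step = 2) {
  z <- matrix(0, dim[1], dim[2])
  structure(
    list(
      direction = direction,
      offsets = hemicircle_offsets(direction, radius),
      i_potentials = z,
      stored_inhibition = z,
      decay_counter = z,
      inhibition_weight = inhibition_weight,
      reset_threshold = reset_threshold,
      decay_step = decay_step
    ),
    class = "inhibitory_layer"
  )
}

#' Distance-weighted inhibition from the previous step's e-layer
#'
#' Per element, `I_dist = weight * sum(E_k / d_k)` over the layer's
#' hemicircle offsets, where `E_k` is the e-potential of the offset element
#' in the *previous* processing step's (thresholded, cluster-filtered)
#' excitatory layer and `d_k` the offset's Euclidean length. Offsets falling
#' outside the frame contribute 0. Offsets are accumulated in their stored
#' order, keeping the computation bit-exactly equivariant under 90-degree
#' rotations of the input.
#'
#' @param e_prev e-potential matrix of the previous processing step.
#' @param layer an [inhibitory_layer].
#' @return I_dist matrix.
#' @export
distance_weighted_inhibition <- function(e_prev, layer) {
  off <- layer$offsets
  acc <- matrix(0, nrow(e_prev), ncol(e_prev))
  for (k in seq_len(nrow(off))) {
    acc <- acc + shift_gather(e_prev, off$dx[k], off$dy[k]) / off$d[k]
  }
  layer$inhibition_weight * acc
}

#' Decayed stored inhibition
#'
#' `I_decay = stored_inhibition - decay_step * decay_counter`, clamped at 0.
#' The stored value is the inhibition saved at the last reset; the counter
#' counts processing steps since then.
#'
#' @param layer an [inhibitory_layer].
#' @return I_decay matrix (non-negative).
#' @export
decay_inhibition <- function(layer) {
  pmax(layer$stored_inhibition - layer$decay_step * layer$decay_counter, 0)
}

#' Advance one inhibitory layer by one processing step
#'
#' One-step-delayed lateral inhibition: the fresh `I_dist` is computed from
#' the *previous* step's e-layer, and wherever it exceeds the decayed stored
#' value by more than `reset_threshold` it is saved and the decay counter
#' reset to 0 (elsewhere the counter increments by 1). The decayed stored
#' inhibition — the fresh value itself where a reset just occurred — is then
#' subtracted from the current e-potentials: `i = max(0, E_now - I_decay)`,
#' so inhibition generated by excitation at step t-1 acts at step t and
#' decays over the following steps.
#'
#' @param e_now current step's e-potential matrix (thresholded, filtered).
#' @param e_prev previous step's e-potential matrix.
#' @param layer an [inhibitory_layer].
#' @return updated layer with fresh `i_potentials`.
#' @export
update_i_potentials <- function(e_now, e_prev, layer) {
  i_dist <- distance_weighted_inhibition(e_prev, layer)
  i_decay_old <- decay_inhibition(layer)
  reset <- i_dist > i_decay_old + layer$reset_threshold
  layer$stored_inhibition[reset] <- i_dist[reset]
  counter <- layer$decay_counter + 1
  counter[reset] <- 0
  layer$decay_counter <- counter
  layer$i_potentials <- pmax(e_now - decay_inhibition(layer), 0)
  layer
}

#' Zone-restricted excitation of a layer
#'
#' Sum of the layer's zone-member i-potentials strictly above 0.1, weighted
#' by m/s where m is the number of members with i-potential strictly above
#' 1.0 and s the zone size. This is the quantity compared between the left-
#' and right-preferring layers to derive the steering direction.
#'
#' @param layer an [inhibitory_layer] with current `i_potentials`.
#' @param zone a [build_zone] result.
#' @return list with `e_layer` (the excitation value) and `m`.
#' @export
layer_excitation <- function(layer, zone) {
  i <- layer$i_potentials
  m <- sum(zone$mask & i > 1.0)
  total <- sum(i[zone$mask & i > 0.1])
  list(e_layer = (m / zone$s) * total, m = m)
}

#' Initialise all four direction-selective layers
#'
#' @inheritParams inhibitory_layer
#' @return named list of four [inhibitory_layer] objects
#'   (`right`, `up`, `left`, `down`).
#' @export
direction_layers <- function(dim, inhibition_weight = 0.35,
                             reset_threshold = 1.5, radius = 3,
                             decay_step = 2) {
  stats::setNames(
    lapply(LAYER_DIRECTIONS, function(d) {
      inhibitory_layer(dim, d, inhibition_weight, reset_threshold,
                       radius, decay_step)
    }),
    LAYER_DIRECTIONS
  )
}
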