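# Excitatory layer: per-element e-potentials from second-order frame
# differencing, thresholding, and the cluster rule that removes isolated
# excitation (a primitive form of object recognition rejecting small or
# lengthy objects).

#' Initialise the excitatory-layer state
#'
#' The state retains the previous frame-pair luminance difference (zeros
#' before the second frame pair exists) so that the second-order difference
#' can be formed, plus the e-potential threshold.
#'
#' @param dim frame shape `c(nrow, ncol)`.
#' @param e_threshold threshold a raw e-potential must exceed (strictly) to
#'   contribute.
#' @return an `excitatory_state` list.
#' @export
excitatory_state <- function(dim, e_threshold) {
  structure(
    list(
      e_potentials = matrix(0, dim[1], dim[2]),
      prev_pair_diff = matrix(0, dim[1], dim[2]),
      e_threshold = e_threshold
    ),
    class = "excitatory_state"
  )
}

#' Absolute frame-pair difference
#'
#' Element-wise `|frame_n - frame_n_minus_1|`: the per-element luminance
#' change between consecutive frames.
#'
#' @param frame_n,frame_n_minus_1 grey-value matrices of equal shape.
#' @return non-negative difference matrix.
#' @export
pair_difference <- function(frame_n, frame_n_minus_1) {
  if (!identical(dim(frame_n), dim(frame_n_minus_1))) {
    stop("frame shape mismatch in pair_difference")
  }
  abs(unclass(frame_n) - unclass(frame_n_minus_1))
}

#' Update e-potentials by second-order differencing
#'
#' The e-potential is the absolute difference between the current frame-pair
#' luminance change and the previous one. This cancels any luminance change
#' that is constant over time (e.g. uniform illumination drift) and
#' sensitises the detector to accelerating image motion. The supplied pair
#' difference replaces the stored one.
#'
#' @param state an [excitatory_state].
#' @param pair_diff current frame-pair difference (from [pair_difference]).
#' @return updated state with fresh raw `e_potentials`.
#' @export
update_e_potentials <- function(state, pair_diff) {
  state$e_potentials <- abs(pair_diff - state$prev_pair_diff)
  state$prev_pair_diff <- pair_diff
  state
}

#' Threshold the e-potentials
#'
#' E-potentials must strictly exceed the threshold to be retained; all
#' others are set to 0.
#'
#' @param state an [excitatory_state] with current `e_potentials`.
#' @return state with sub-threshold e-potentials zeroed.
#' @export
apply_threshold <- function(state) {
  e <- state$e_potentials
  e[e <= state$e_threshold] <- 0
  state$e_potentials <- e
  state
}

#' Remove isolated excitation (cluster rule)
#'
#' For every excited element (e-potential > 0 after thresholding), the
#' number of excited elements within a Euclidean radius of `radius` elements
#' is counted, the focal element included. If that count is not higher than
#' `min_count` the focal e-potential is set to 0. Counting always uses the
#' pre-filter layer, so the result does not depend on sweep order (no
#' cascade), and neighborhoods are clipped at the frame border.
#'
#' @param state an [excitatory_state], already thresholded.
#' @param radius counting-circle radius in elements.
#' @param min_count count that must be strictly exceeded for the focal
#'   element to survive.
#' @return state with isolated excitation removed.
#' @export
cluster_filter <- function(state, radius = 3, min_count = 10) {
  e <- state$e_potentials
  excited <- e > 0
  counts <- disk_count(excited, radius)
  e[excited & counts <= min_count] <- 0
  state$e_potentials <- e
  state
}
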