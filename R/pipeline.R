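# Per-frame orchestration of the full detector, per-frame results, and CSV
# output. Canonical per-step order: frame-pair difference -> second-order
# e-potentials -> threshold -> cluster filter -> inhibitory-layer update
# (delayed by one step) -> local motion vectors -> shadow suppression ->
# coherence + overstimulation checks -> risk -> steering.

#' Run configuration
#'
#' Bundles every tunable constant of the detector with its default. An
#' explicit `e_threshold` always takes precedence; `NULL` means "auto":
#' derive it from the contrast of the representative frame via
#' [threshold_from_contrast].
#'
#' @param zone_center zone center `c(col, row)` in elements; `NULL` = frame
#'   center.
#' @param zone_radius zone radius in elements.
#' @param top_exclusion,bottom_exclusion excluded fractions of the frame
#'   height.
#' @param e_threshold e-potential threshold (grey-value units), or `NULL`
#'   for contrast-derived.
#' @param representative_frame index of the frame used for the contrast
#'   model when `e_threshold` is `NULL`.
#' @param dist_gain gain of the center-proximity risk term.
#' @param n_gate qualification count gating the distance term.
#' @param overstim_limit,overstim_level overstimulation rule: fraction of
#'   zone members (strictly exceeded) with e-potentials above `overstim_level`.
#' @param cluster_radius,cluster_min_count cluster rule of [cluster_filter].
#' @param inhibition_weight,reset_threshold,hemicircle_radius,decay_step
#'   lateral-inhibition constants of [inhibitory_layer].
#' @param vector_circle_radius,vector_min_excited,dominance_margin local
#'   motion-vector rule of [local_motion_vectors].
#' @param coherence_limit whole-field coherence fraction (strictly exceeded)
#'   that suspends risk estimation.
#' @param shadow_fraction lower-zone fraction (strictly exceeded) that
#'   triggers shadow suppression.
#' @param shadow_suppression enable the shadow rule.
#' @param steering_threshold excitation difference (strictly exceeded)
#'   required for a steering decision.
#' @param keep_fields retain per-frame masks and vector fields (needed for
#'   [render_overlay]).
#' @return a `cd_config` list.
#' @export
cd_config <- function(zone_center = NULL, zone_radius = 50,
                      top_exclusion = 0.25, bottom_exclusion = 0.25,
                      e_threshold = NULL, representative_frame = 1L,
                      dist_gain = 10, n_gate = 15,
                      overstim_limit = 0.40, overstim_level = 0.5,
                      cluster_radius = 3, cluster_min_count = 10,
                      inhibition_weight = 0.35, reset_threshold = 1.5,
                      hemicircle_radius = 3, decay_step = 2,
                      vector_circle_radius = 3, vector_min_excited = 9,
                      dominance_margin = 4, coherence_limit = 0.5,
                      shadow_fraction = 0.2, shadow_suppression = TRUE,
                      steering_threshold = 6, keep_fields = FALSE) {
  structure(as.list(environment()), class = "cd_config")
}

#' Process a frame sequence with the collision detector
#'
#' Runs the full per-frame pipeline and returns one result row per frame.
#' The first two frames are warm-up: valid e-potentials need two preceding
#' frame pairs, so risk output starts at the third frame (warm-up rows are
#' flagged and report zero risk).
#'
#' @param frames list of grey matrices / [frame_grid]s (a [load_sequence]
#'   result or the `frames` element of a stimulus).
#' @param config a [cd_config].
#' @return a `cd_result`: list with `results` (data.frame, one row per
#'   frame), `config`, `zone`, `e_threshold`, and — when
#'   `config$keep_fields` — `fields` (per-frame excitation/shadow masks and
#'   vector fields).
#' @export
process_sequence <- function(frames, config = cd_config()) {
  stopifnot(inherits(config, "cd_config"))
  if (length(frames) < 3) stop("at least 3 frames are required")
  frames <- lapply(frames, unclass)
  shape <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), shape)) {
      stop(sprintf("frame %d differs in shape; constant shape required", i))
    }
  }
  e_threshold <- config$e_threshold
  if (is.null(e_threshold)) {
    e_threshold <- threshold_from_contrast(
      image_contrast(frames[[config$representative_frame]])
    )
  }
  zone <- build_zone(shape,
    center = config$zone_center, radius = config$zone_radius,
    top_exclusion = config$top_exclusion,
    bottom_exclusion = config$bottom_exclusion
  )

  state <- excitatory_state(shape, e_threshold)
  layers <- direction_layers(shape,
    inhibition_weight = config$inhibition_weight,
    reset_threshold = config$reset_threshold,
    radius = config$hemicircle_radius,
    decay_step = config$decay_step
  )
  e_prev <- matrix(0, shape[1], shape[2])

  n <- length(frames)
  rows <- vector("list", n)
  fields <- if (config$keep_fields) vector("list", n) else NULL

  empty_row <- function(t, warm_up) {
    data.frame(
      frame_index = t, warm_up = warm_up,
      r_coll = 0, r_dist = 0, n_qualifying = 0L, w = 0L,
      total_risk = 0, suspended = FALSE, suspension_reason = "none",
      steering_direction = "none", steering_force = 0,
      coherence_fraction = 0, n_shadow = 0L, n_vectors = 0L,
      e_layer_right = 0, e_layer_left = 0, e_layer_up = 0, e_layer_down = 0,
      stringsAsFactors = FALSE
    )
  }

  for (t in seq_len(n)) {
    if (t >= 2) {
      pd <- pair_difference(frames[[t]], frames[[t - 1]])
      state <- update_e_potentials(state, pd)
    }
    if (t <= 2) {
      # warm-up: no valid second-order difference yet
      rows[[t]] <- empty_row(t, TRUE)
      if (config$keep_fields) {
        fields[[t]] <- list(
          excited = matrix(FALSE, shape[1], shape[2]),
          shadow = matrix(FALSE, shape[1], shape[2]),
          direction = matrix(NA_real_, shape[1], shape[2]),
          steering = "none"
        )
      }
      next
    }
    state <- apply_threshold(state)
    state <- cluster_filter(state, config$cluster_radius,
                            config$cluster_min_count)
    e_now <- state$e_potentials

    for (d in names(layers)) {
      layers[[d]] <- update_i_potentials(e_now, e_prev, layers[[d]])
    }

    field <- local_motion_vectors(layers,
      radius = config$vector_circle_radius,
      min_excited = config$vector_min_excited,
      margin = config$dominance_margin
    )

    shadow_mask <- matrix(FALSE, shape[1], shape[2])
    if (config$shadow_suppression) {
      sup <- shadow_suppression(field, zone, e_now, layers,
                                fraction = config$shadow_fraction)
      shadow_mask <- sup$shadow_mask
      e_now <- sup$e
      layers <- sup$layers
    }

    coh <- coherence_check(field, limit = config$coherence_limit)
    overstim <- overstimulation_check(e_now, zone,
                                      limit = config$overstim_limit)

    rc <- r_coll(e_now, zone, e_threshold)
    rd <- r_dist(e_now, zone, e_threshold, gain = config$dist_gain)
    risk <- combine_risk(rc, rd,
      overstimulated = overstim, coherent_motion = coh$flag,
      n_gate = config$n_gate
    )

    exc <- lapply(layers, layer_excitation, zone = zone)
    steer <- steering_vector(exc$left, exc$right,
                             threshold = config$steering_threshold)
    if (risk$suspended) steer$direction <- "none"

    if (anyNA(e_now) || !is.finite(risk$total_risk)) {
      stop(sprintf("non-finite values at frame %d", t))
    }

    rows[[t]] <- data.frame(
      frame_index = t, warm_up = FALSE,
      r_coll = risk$r_coll, r_dist = risk$r_dist,
      n_qualifying = risk$n_qualifying, w = risk$w,
      total_risk = risk$total_risk,
      suspended = risk$suspended, suspension_reason = risk$suspension_reason,
      steering_direction = steer$direction, steering_force = steer$force,
      coherence_fraction = coh$coherence_fraction,
      n_shadow = sum(shadow_mask),
      n_vectors = sum(!is.na(field$direction)),
      e_layer_right = exc$right$e_layer, e_layer_left = exc$left$e_layer,
      e_layer_up = exc$up$e_layer, e_layer_down = exc$down$e_layer,
      stringsAsFactors = FALSE
    )
    if (config$keep_fields) {
      fields[[t]] <- list(
        excited = e_now > 0,
        shadow = shadow_mask,
        direction = field$direction,
        steering = steer$direction
      )
    }
    # the e-layer feeding next step's delayed inhibition is post-suppression
    e_prev <- e_now
  }

  structure(
    list(
      results = do.call(rbind, rows),
      config = config, zone = zone, e_threshold = e_threshold,
      fields = fields
    ),
    class = "cd_result"
  )
}

#' @export
print.cd_result <- function(x, ...) {
  r <- x$results
  cat(sprintf(
    "<cd_result> %d frames | peak total_risk %.2f (frame %d) | %d suspended | e-threshold %.3f\n",
    nrow(r), max(r$total_risk), r$frame_index[which.max(r$total_risk)],
    sum(r$suspended), x$e_threshold
  ))
  invisible(x)
}

#' Write per-frame results to CSV
#'
#' One row per frame with every FrameResult field; round-trips losslessly
#' through [read_results_csv].
#'
#' @param result a [process_sequence] result (or its `results` data.frame).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_results_csv <- function(result, path) {
  df <- if (inherits(result, "cd_result")) result$results else result
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-frame results CSV
#'
#' @param path CSV path written by [write_results_csv].
#' @return data.frame of per-frame results.
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
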