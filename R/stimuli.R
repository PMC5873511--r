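# Deterministic, seeded synthetic stimuli with ground-truth labels.
#
# These scenes stand in for dashboard-camera footage and exercise every
# pathway of the detector: radial expansion on a collision course
# (looming), safe lateral crossing (translating), whole-field rigid motion
# (camera shake / self-motion), and ground shadows racing toward the lower
# frame border. Frames use the same conventions as real input: grey values
# in [0, 9.9], ~200 x 110 elements, 29 fps metadata. Objects are rasterized
# with fractional edge coverage so sub-element motion produces smooth
# luminance changes.
#
# Default levels: background 6.0 (bright road/sky), objects 1.0 (dark
# vehicle), shadow 1.5 — object/background separations well above every
# configured e-threshold, emulating the high-contrast films the detector
# was designed for.

STIM_SHAPE <- c(110L, 200L)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Fractional coverage of element centers `idx` (spanning [i-0.5, i+0.5]) by
# the interval [lo, hi].
interval_coverage <- function(idx, lo, hi) {
  pmax(0, pmin(hi, idx + 0.5) - pmax(lo, idx - 0.5))
}

# Paint an axis-aligned rectangle [x0,x1] x [y0,y1] (element coordinates,
# y down) onto `frame` at grey `level`, with fractional edge coverage.
paint_rect <- function(frame, x0, x1, y0, y1, level) {
  covx <- interval_coverage(seq_len(ncol(frame)), x0, x1)
  covy <- interval_coverage(seq_len(nrow(frame)), y0, y1)
  cov <- outer(covy, covx)
  frame + (level - frame) * cov
}

# Sparse static clutter: n_patch small rectangles of varied grey on the
# background, emulating road markings and scenery that make whole-field
# motion trackable. Pure-uniform backgrounds defeat motion-coherence
# measurement.
textured_background <- function(shape = STIM_SHAPE, bg_level = 6.0,
                                n_patch = 60, amplitude = 3.0, seed = 1) {
  with_seed(seed, {
    f <- matrix(bg_level, shape[1], shape[2])
    for (i in seq_len(n_patch)) {
      w <- runif(1, 2, 6)
      h <- runif(1, 2, 6)
      x <- runif(1, 1, shape[2] - w)
      y <- runif(1, 1, shape[1] - h)
      lvl <- bg_level + runif(1, -amplitude, amplitude)
      lvl <- min(max(lvl, 0), GREY_MAX)
      f <- paint_rect(f, x, x + w, y, y + h, lvl)
    }
    f
  })
}

as_stimulus <- function(frames, truth, kind, frame_rate = 29) {
  frames <- lapply(seq_along(frames), function(i) {
    frame_grid(pmin(pmax(frames[[i]], 0), GREY_MAX),
      frame_index = i, frame_rate = frame_rate
    )
  })
  structure(list(frames = frames, truth = truth, kind = kind,
                 frame_rate = frame_rate),
            class = "cd_stimulus")
}

#' @export
print.cd_stimulus <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<cd_stimulus> kind '%s', %d frames of %d x %d elements\n",
              x$kind, length(x$frames), d[2], d[1]))
  invisible(x)
}

#' Looming-square stimulus (object on a collision course)
#'
#' A dark square centered on the given point grows across the sequence,
#' emulating the radial expansion of an approaching object's retinal image.
#' Exponential growth (the default) approximates the accelerating expansion
#' of an object approached at constant speed.
#'
#' @param n_frames number of frames.
#' @param shape frame shape `c(nrow, ncol)`.
#' @param center square center `c(col, row)`; defaults to the frame center.
#' @param side_start,side_end square side length (elements) at the first and
#'   last frame.
#' @param growth `"exponential"` or `"linear"` interpolation of the side
#'   length.
#' @param object_level,bg_level grey levels of the square and background.
#' @param noise_sd standard deviation of static seeded background texture
#'   (0 disables).
#' @param seed RNG seed for the texture.
#' @return a `cd_stimulus`: `frames` plus a `truth` data.frame with
#'   `frame_index`, `on_collision_course`, `object_area`.
#' @export
looming_square <- function(n_frames = 60, shape = STIM_SHAPE, center = NULL,
                           side_start = 4, side_end = 88,
                           growth = c("exponential", "linear"),
                           object_level = 1.0, bg_level = 6.0,
                           noise_sd = 0, seed = 1) {
  growth <- match.arg(growth)
  if (is.null(center)) center <- c((shape[2] + 1) / 2, (shape[1] + 1) / 2)
  if (side_end > min(shape) || side_end / 2 + max(abs(center)) > sum(shape)) {
    if (side_end > 2 * min(center[2] - 1, shape[1] - center[2],
                           center[1] - 1, shape[2] - center[1]) + 1) {
      stop("square grows beyond the frame bounds")
    }
  }
  tfrac <- (seq_len(n_frames) - 1) / (n_frames - 1)
  side <- switch(growth,
    linear = side_start + (side_end - side_start) * tfrac,
    exponential = side_start * (side_end / side_start)^tfrac
  )
  base <- if (noise_sd > 0) {
    with_seed(seed, matrix(pmin(pmax(
      bg_level + rnorm(prod(shape), 0, noise_sd), 0), GREY_MAX),
      shape[1], shape[2]))
  } else {
    matrix(bg_level, shape[1], shape[2])
  }
  frames <- lapply(seq_len(n_frames), function(t) {
    h <- side[t] / 2
    paint_rect(base, center[1] - h, center[1] + h,
               center[2] - h, center[2] + h, object_level)
  })
  truth <- data.frame(
    frame_index = seq_len(n_frames),
    on_collision_course = TRUE,
    object_area = side^2
  )
  as_stimulus(frames, truth, "looming")
}

#' Translating-bar stimulus (object passing by safely)
#'
#' A dark bar of fixed size crosses the frame at constant velocity —
#' on-coming traffic passing by, not a collision course.
#'
#' @param n_frames number of frames.
#' @param shape frame shape `c(nrow, ncol)`.
#' @param direction `"right"`, `"left"`, `"up"` or `"down"`.
#' @param speed elements per frame.
#' @param bar_width,bar_length bar extent across and along the frame rows
#'   (for horizontal motion the bar is `bar_width` columns wide and
#'   `bar_length` rows tall; rotated accordingly for vertical motion).
#' @param start offset of the bar's leading edge along the motion axis at
#'   the first frame (elements from the border the bar enters from); 0
#'   starts at the frame border, larger values start the bar already inside
#'   the frame (e.g. inside the danger zone).
#' @param object_level,bg_level grey levels.
#' @return a `cd_stimulus` with truth columns `frame_index`,
#'   `on_collision_course` (all `FALSE`), `direction`.
#' @export
translating_bar <- function(n_frames = 60, shape = STIM_SHAPE,
                            direction = c("right", "left", "up", "down"),
                            speed = 2, bar_width = 12, bar_length = 40,
                            start = 0, object_level = 1.0, bg_level = 6.0) {
  direction <- match.arg(direction)
  cy <- (shape[1] + 1) / 2
  cx <- (shape[2] + 1) / 2
  frames <- lapply(seq_len(n_frames), function(t) {
    f <- matrix(bg_level, shape[1], shape[2])
    pos <- start + speed * (t - 1)
    switch(direction,
      right = paint_rect(f, pos - bar_width, pos,
                         cy - bar_length / 2, cy + bar_length / 2, object_level),
      left = paint_rect(f, shape[2] - pos, shape[2] - pos + bar_width,
                        cy - bar_length / 2, cy + bar_length / 2, object_level),
      down = paint_rect(f, cx - bar_length / 2, cx + bar_length / 2,
                        pos - bar_width, pos, object_level),
      up = paint_rect(f, cx - bar_length / 2, cx + bar_length / 2,
                      shape[1] - pos, shape[1] - pos + bar_width, object_level)
    )
  })
  truth <- data.frame(
    frame_index = seq_len(n_frames),
    on_collision_course = FALSE,
    direction = direction
  )
  as_stimulus(frames, truth, "translate")
}

# Rigid toroidal shift of a matrix by integer (dx, dy): content moves dx
# columns rightward and dy rows downward, wrapping at the borders so the
# whole field stays textured (synthetic convenience; real frames are not
# toroidal).
shift_wrap <- function(m, dx, dy) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  m[ri, ci, drop = FALSE]
}

#' Camera-shake / self-motion stimulus
#'
#' Applies rigid whole-field integer shifts to a base sequence (or to a
#' static textured background). Two modes: `"jitter"` draws a random-walk
#' camera offset with per-frame steps up to `amplitude` elements (camera
#' shake), `"drift"` shifts by a constant `amplitude` elements per frame in
#' `direction` (sustained self-motion / pan). Shifts wrap at the frame
#' border so the field stays fully textured.
#'
#' @param base list of grey matrices, or `NULL` to use a static
#'   [textured_background] repeated `n_frames` times.
#' @param n_frames number of frames when `base` is `NULL`.
#' @param shape frame shape used when `base` is `NULL`.
#' @param amplitude maximum (jitter) or constant (drift) shift in elements
#'   per frame; 0 returns the base sequence unchanged.
#' @param mode `"jitter"` or `"drift"`.
#' @param direction drift direction (`"right"`, `"left"`, `"up"`, `"down"`).
#' @param seed RNG seed (jitter steps and background texture).
#' @return a `cd_stimulus` with truth columns `frame_index`, `dx`, `dy`
#'   (cumulative camera offset).
#' @export
camera_shake <- function(base = NULL, n_frames = 40, shape = STIM_SHAPE,
                         amplitude = 2, mode = c("jitter", "drift"),
                         direction = c("down", "up", "left", "right"),
                         seed = 7) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (is.null(base)) {
    bg <- textured_background(shape, seed = seed)
    base <- rep(list(bg), n_frames)
  } else {
    base <- lapply(base, unclass)
    n_frames <- length(base)
  }
  amplitude <- as.integer(round(amplitude))
  if (mode == "jitter") {
    steps <- with_seed(seed, cbind(
      dx = sample(-amplitude:amplitude, n_frames, replace = TRUE),
      dy = sample(-amplitude:amplitude, n_frames, replace = TRUE)
    ))
    steps[1, ] <- 0L
    offs <- apply(steps, 2, cumsum)
  } else {
    step <- switch(direction,
      right = c(1, 0), left = c(-1, 0), down = c(0, 1), up = c(0, -1)
    ) * amplitude
    offs <- cbind(
      dx = step[1] * (seq_len(n_frames) - 1),
      dy = step[2] * (seq_len(n_frames) - 1)
    )
  }
  frames <- lapply(seq_len(n_frames), function(t) {
    shift_wrap(base[[t]], offs[t, 1], offs[t, 2])
  })
  truth <- data.frame(
    frame_index = seq_len(n_frames),
    dx = offs[, 1], dy = offs[, 2]
  )
  as_stimulus(frames, truth, "shake")
}

#' Ground-shadow stimulus (approaching road shadow with overhead counterflow)
#'
#' A dark horizontal shadow band (the shadow of a bridge lying across the
#' road) sweeps toward the lower frame border through the lower half of the
#' danger zone, widening as it comes — the perspective expansion of an
#' approaching ground feature. Mirrored about the horizon, an identical
#' dark band (the bridge itself, overhead) sweeps upward above the zone, as
#' overhead structures do under forward self-motion. The upward counterflow
#' balances the downward shadow flow, so the whole-field coherence rule
#' (which any single dominant motion direction trips) stays silent and
#' suppressing the shadow is left to the shadow rule. The shadow band moves
#' a whole element per frame: constant sub-element creep produces
#' constant-rate luminance ramps that second-order differencing cancels by
#' design.
#'
#' @param n_frames number of frames; the default geometry keeps all bands
#'   clear of the frame borders for up to 10 frames.
#' @param shape frame shape `c(nrow, ncol)`.
#' @param n_bands number of parallel shadow stripes (bridge deck + railing).
#' @param band_height stripe thickness in elements.
#' @param band_offset vertical distance between stripe top edges.
#' @param width_start,width_end stripe width (elements, centered on the
#'   frame center column) at the first and last frame.
#' @param shadow_speed downward sweep speed, elements per frame (integer).
#' @param start_row row of the leading stripe's top edge at the first frame
#'   (half-integer values align stripe edges with element boundaries, so
#'   each step covers/uncovers whole rows; default places the stripes in
#'   the lower half of a centered danger zone, below its inner r/2 region).
#' @param mirror_row horizontal mirror axis (the horizon) for the overhead
#'   bands; `NULL` disables the counterflow.
#' @param shadow_level,bg_level grey levels of the bands and background.
#' @return a `cd_stimulus` with truth columns `frame_index`,
#'   `shadow_top`, `shadow_bottom` (row extent of the leading stripe).
#' @export
ground_shadow <- function(n_frames = 10, shape = STIM_SHAPE, n_bands = 2,
                          band_height = 5, band_offset = 8,
                          width_start = 28, width_end = 88,
                          shadow_speed = 1, start_row = 65.5,
                          mirror_row = 44, shadow_level = 1.5,
                          bg_level = 6.0) {
  cx <- (shape[2] + 1) / 2
  tfrac <- if (n_frames > 1) (seq_len(n_frames) - 1) / (n_frames - 1) else 0
  width <- width_start + (width_end - width_start) * tfrac
  top <- start_row + shadow_speed * (seq_len(n_frames) - 1)
  frames <- lapply(seq_len(n_frames), function(t) {
    f <- matrix(bg_level, shape[1], shape[2])
    for (b in seq_len(n_bands) - 1) {
      y0 <- top[t] - b * band_offset
      f <- paint_rect(f, cx - width[t] / 2, cx + width[t] / 2,
                      y0, y0 + band_height, shadow_level)
      if (!is.null(mirror_row)) {
        # exact raster mirror of the stripe about the horizon row
        f <- paint_rect(f, cx - width[t] / 2, cx + width[t] / 2,
                        2 * mirror_row - y0 - band_height,
                        2 * mirror_row - y0, shadow_level)
      }
    }
    f
  })
  truth <- data.frame(
    frame_index = seq_len(n_frames),
    shadow_top = top,
    shadow_bottom = top + band_height
  )
  as_stimulus(frames, truth, "shadow")
}

#' Write a stimulus to disk as a PNG sequence with a truth sidecar
#'
#' Frames are written as 8-bit grey PNGs (`frame_0001.png`, ...) and the
#' truth table as `truth.csv` in the same directory.
#'
#' @param stim a `cd_stimulus`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of frame file paths.
#' @export
write_stimulus <- function(stim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stim$frames))
  for (i in seq_along(stim$frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%04d.png", i))
    png::writePNG(unclass(stim$frames[[i]]) / GREY_MAX, paths[i])
  }
  utils::write.csv(stim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(paths)
}
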