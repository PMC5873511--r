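# Diagnostic overlay rendering: the input frames re-emitted as RGB PNGs
# with excited elements tinted red, shadow elements yellow, local motion
# vectors as short green ticks, the danger-zone circle outlined, and a
# steering arrow at the bottom of the frame.

# Draw a line segment (element coordinates) into the three channel
# matrices; naive sampling is plenty at these resolutions.
draw_line <- function(rgb, x0, y0, x1, y1, col) {
  n <- max(2, ceiling(2 * max(abs(x1 - x0), abs(y1 - y0))))
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  ok <- xs >= 1 & xs <= ncol(rgb$r) & ys >= 1 & ys <= nrow(rgb$r)
  idx <- cbind(ys[ok], xs[ok])
  rgb$r[idx] <- col[1]
  rgb$g[idx] <- col[2]
  rgb$b[idx] <- col[3]
  rgb
}

#' Render annotated overlay frames
#'
#' Writes one RGB PNG per frame: grey base image, excited elements tinted
#' red, shadow elements yellow, every `vector_stride`-th local motion vector
#' as a short green tick, the danger-zone outline in blue, and a green
#' steering arrow at the bottom whenever a steering direction was issued.
#' Requires a result produced with `keep_fields = TRUE`.
#'
#' @param frames the frame list that was processed.
#' @param result the matching [process_sequence] result (with `fields`).
#' @param outdir output directory (created if needed).
#' @param vector_stride draw a motion tick every this many elements.
#' @return invisibly, the vector of written paths.
#' @export
render_overlay <- function(frames, result, outdir, vector_stride = 4) {
  if (is.null(result$fields)) {
    stop("overlay rendering needs a result produced with keep_fields = TRUE")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  zone <- result$zone
  ring <- abs(zone$dist - zone$radius) < 0.5
  paths <- character(length(frames))
  for (t in seq_along(frames)) {
    base <- unclass(frames[[t]]) / GREY_MAX
    rgb <- list(r = base, g = base, b = base)
    fl <- result$fields[[t]]
    rgb$r[ring] <- 0.2
    rgb$g[ring] <- 0.4
    rgb$b[ring] <- 1
    dirs <- fl$direction
    if (any(!is.na(dirs))) {
      rr <- seq(1, nrow(dirs), by = vector_stride)
      cc <- seq(1, ncol(dirs), by = vector_stride)
      for (r in rr) for (c in cc) {
        a <- dirs[r, c]
        if (!is.na(a)) {
          rad <- a * pi / 180
          rgb <- draw_line(rgb, c, r, c + 3 * cos(rad), r - 3 * sin(rad),
                           c(0.1, 1, 0.1))
        }
      }
    }
    if (!identical(fl$steering, "none")) {
      yc <- nrow(base) - 6
      xc <- ncol(base) / 2
      sgn <- if (identical(fl$steering, "left")) -1 else 1
      rgb <- draw_line(rgb, xc, yc, xc + sgn * 12, yc, c(0.1, 1, 0.1))
      rgb <- draw_line(rgb, xc + sgn * 12, yc, xc + sgn * 8, yc - 3, c(0.1, 1, 0.1))
      rgb <- draw_line(rgb, xc + sgn * 12, yc, xc + sgn * 8, yc + 3, c(0.1, 1, 0.1))
    }
    # excitation and shadow tints take priority over all other annotation
    excited <- fl$excited & !fl$shadow
    rgb$r[excited] <- 1
    rgb$g[excited] <- 0.1
    rgb$b[excited] <- 0.1
    rgb$r[fl$shadow] <- 1
    rgb$g[fl$shadow] <- 0.9
    rgb$b[fl$shadow] <- 0.1
    arr <- array(c(rgb$r, rgb$g, rgb$b), dim = c(nrow(base), ncol(base), 3))
    paths[t] <- file.path(outdir, sprintf("overlay_%04d.png", t))
    png::writePNG(arr, paths[t])
  }
  invisible(paths)
}
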