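# Lattice helpers shared by the excitation, inhibition and motion-vector
# stages. Frames are matrices indexed [row, col] with row 1 at the top of
# the image; an offset (dx, dy) points dx columns to the right and dy rows
# down.

#' Gather-shift a matrix
#'
#' Returns a matrix `out` with `out[r, c] = m[r + dy, c + dx]`, using 0 for
#' positions outside the frame (frames are not toroidal).
#'
#' @param m numeric matrix.
#' @param dx,dy integer offsets (columns right, rows down).
#' @return matrix of the same shape as `m`.
#' @keywords internal
shift_gather <- function(m, dx, dy) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r1 <- max(1L, 1L - dy)
  r2 <- min(nr, nr - dy)
  c1 <- max(1L, 1L - dx)
  c2 <- min(nc, nc - dx)
  if (r1 <= r2 && c1 <= c2) {
    out[r1:r2, c1:c2] <- m[(r1 + dy):(r2 + dy), (c1 + dx):(c2 + dx)]
  }
  out
}

#' Lattice offsets within a Euclidean disk
#'
#' All integer offsets (dx, dy) with `sqrt(dx^2 + dy^2) <= radius`. At the
#' default radius 3 there are 29 offsets including (0, 0).
#'
#' @param radius disk radius in elements.
#' @param include_center keep the (0, 0) offset?
#' @return data.frame with columns `dx`, `dy`, `d` (Euclidean length).
#' @keywords internal
disk_offsets <- function(radius = 3, include_center = TRUE) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g$d <- sqrt(g$dx^2 + g$dy^2)
  g <- g[g$d <= radius, ]
  if (!include_center) g <- g[!(g$dx == 0 & g$dy == 0), ]
  rownames(g) <- NULL
  g
}

#' Count marked elements within a disk around every element
#'
#' For each element, the number of TRUE entries of `mask` within Euclidean
#' distance `radius` (the focal element included). Neighborhoods are clipped
#' at the frame border.
#'
#' @param mask logical matrix.
#' @param radius disk radius in elements.
#' @return integer-valued matrix of counts.
#' @keywords internal
disk_count <- function(mask, radius = 3) {
  off <- disk_offsets(radius)
  m <- mask * 1
  acc <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(nrow(off))) {
    acc <- acc + shift_gather(m, off$dx[k], off$dy[k])
  }
  acc
}

# Rotate an offset (dx, dy) by 90 degrees counter-clockwise in image terms
# (y grows downward), so the rightward unit offset maps to the upward one.
rotate_offset_ccw <- function(dx, dy) list(dx = dy, dy = -dx)

#' Rotate a matrix 90 degrees counter-clockwise
#'
#' Counter-clockwise in image terms: the right edge of the image becomes the
#' top edge, so rightward motion in the input becomes upward motion in the
#' output.
#'
#' @param m matrix.
#' @return rotated matrix.
#' @export
rot90_ccw <- function(m) {
  t(m)[ncol(m):1, , drop = FALSE]
}
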