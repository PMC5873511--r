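# Frame input: reading image sequences, converting them to the grey-value
# convention used throughout the algorithm, and the contrast-derived
# excitation threshold.
#
# Grey values live in [0, 9.9]. Native 8-bit input in [0, 255] is mapped
# linearly by v * 9.9 / 255 (equivalently, the [0, 1] values returned by the
# PNG/TIFF readers are multiplied by 9.9), with no rounding.

GREY_MAX <- 9.9

#' Construct a frame grid
#'
#' A frame grid is a numeric matrix (rows are image rows, row 1 at the top)
#' with grey values in \[0, 9.9\] and attributes `frame_index` and
#' `frame_rate`.
#'
#' @param values numeric matrix of grey values in \[0, 9.9\].
#' @param frame_index ordinal position of the frame in its sequence (1-based).
#' @param frame_rate frames per second.
#' @return a `frame_grid` (numeric matrix with metadata attributes).
#' @export
frame_grid <- function(values, frame_index = 1L, frame_rate = 29) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(values) == 0) {
    stop("frame values must be a non-empty numeric matrix")
  }
  if (anyNA(values) || min(values) < 0 || max(values) > GREY_MAX) {
    stop(sprintf("grey values must lie in [0, %g]", GREY_MAX))
  }
  structure(values,
    frame_index = as.integer(frame_index),
    frame_rate = frame_rate,
    class = c("frame_grid", "matrix", "array")
  )
}

#' @export
print.frame_grid <- function(x, ...) {
  cat(sprintf(
    "<frame_grid> %d x %d elements, frame %d, grey range [%.3f, %.3f]\n",
    ncol(x), nrow(x), attr(x, "frame_index"), min(x), max(x)
  ))
  invisible(x)
}

# Exact area-average (box-filter) resampling of one axis: returns the
# n_new x n_old weight matrix whose rows are the fractional overlaps of each
# output interval with the input intervals. Rows sum to 1.
area_weights <- function(n_old, n_new) {
  scale <- n_old / n_new
  w <- matrix(0, n_new, n_old)
  for (i in seq_len(n_new)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j1 <- floor(lo) + 1
    j2 <- ceiling(hi)
    for (j in j1:min(j2, n_old)) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) w[i, j] <- overlap / scale
    }
  }
  w
}

#' Area-average resize of a grey matrix
#'
#' Downscales (or upscales) by exact box filtering: every output element is
#' the unweighted mean of the input area it covers, so total image intensity
#' is preserved.
#'
#' @param m numeric matrix.
#' @param new_height,new_width target shape in elements.
#' @return resized numeric matrix.
#' @export
resize_area <- function(m, new_height, new_width) {
  wr <- area_weights(nrow(m), new_height)
  wc <- area_weights(ncol(m), new_width)
  wr %*% m %*% t(wc)
}

# Rec. 601 luma conversion for RGB(A) arrays as returned by png/tiff readers.
to_grey01 <- function(img) {
  if (length(dim(img)) == 2) return(img)
  if (length(dim(img)) == 3) {
    nch <- dim(img)[3]
    if (nch == 1) return(img[, , 1])
    if (nch >= 3) {
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    }
    return(img[, , 1]) # grey + alpha
  }
  stop("unsupported image array layout")
}

read_image_grey01 <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' (PNG or TIFF expected): %s", ext, path))
  )
  to_grey01(img)
}

#' Load a frame sequence
#'
#' Reads a numbered PNG/TIFF image sequence (a directory, or an explicit
#' vector of file paths), converts to single-channel grey by Rec. 601
#' luminance weighting, rescales to `target_width` elements preserving the
#' aspect ratio (area-average resampling), and maps grey values linearly
#' onto \[0, 9.9\]. Files in a directory are taken in lexicographic order,
#' so zero-padded frame numbers sort correctly.
#'
#' @param source directory containing the image sequence, or a character
#'   vector of image paths in frame order.
#' @param target_width output width in elements (`>= 32`); the height
#'   follows from the input aspect ratio. `NULL` keeps the native size.
#' @param frame_rate frames per second recorded in the frame metadata.
#' @return list of [frame_grid] objects in frame order.
#' @export
load_sequence <- function(source, target_width = 200, frame_rate = 29) {
  if (!is.null(target_width) && target_width < 32) {
    stop("target_width must be at least 32 elements")
  }
  if (length(source) == 1 && dir.exists(source)) {
    files <- sort(list.files(source,
      pattern = "\\.(png|tif|tiff)$",
      ignore.case = TRUE, full.names = TRUE
    ))
  } else {
    files <- source
    missing <- files[!file.exists(files)]
    if (length(missing) > 0) {
      stop("unreadable input file(s): ", paste(missing, collapse = ", "))
    }
  }
  if (length(files) == 0) stop("empty sequence: no image frames found")
  frames <- vector("list", length(files))
  shape <- NULL
  for (i in seq_along(files)) {
    g <- read_image_grey01(files[i])
    if (!is.null(target_width) && ncol(g) != target_width) {
      new_h <- max(1L, round(nrow(g) * target_width / ncol(g)))
      g <- resize_area(g, new_h, target_width)
    }
    g <- pmin(pmax(g, 0), 1) * GREY_MAX
    if (is.null(shape)) {
      shape <- dim(g)
    } else if (!identical(dim(g), shape)) {
      stop(sprintf(
        "frame %d has shape %dx%d, expected %dx%d (constant shape required)",
        i, ncol(g), nrow(g), shape[2], shape[1]
      ))
    }
    frames[[i]] <- frame_grid(g, frame_index = i, frame_rate = frame_rate)
  }
  frames
}

#' Image contrast of a frame
#'
#' Michelson contrast `(a - b) / (a + b)` from the highest (`a`) and lowest
#' (`b`) grey value of the frame; 0 for an all-black frame (`a = b = 0`).
#'
#' @param frame numeric matrix of grey values.
#' @return contrast in \[0, 1\].
#' @export
image_contrast <- function(frame) {
  a <- max(frame)
  b <- min(frame)
  if (a + b <= 0) return(0)
  (a - b) / (a + b)
}

#' Excitation threshold from image contrast
#'
#' Empirical linear map from film contrast to the e-potential threshold:
#' `threshold = contrast * 0.71 + 0.378`. Used as the default when no
#' explicit per-run threshold is configured; an explicit configured
#' threshold always takes precedence.
#'
#' @param contrast Michelson contrast in \[0, 1\].
#' @return e-potential threshold (grey-value units).
#' @export
threshold_from_contrast <- function(contrast) {
  stopifnot(contrast >= 0, contrast <= 1)
  contrast * 0.71 + 0.378
}

#' Contrast model of a film
#'
#' Convenience wrapper bundling the representative frame's extreme grey
#' values, the Michelson contrast and the derived e-potential threshold.
#'
#' @param frame representative frame (by convention the first frame of the
#'   film; any frame may be supplied).
#' @return list with elements `a`, `b`, `contrast`, `e_threshold`.
#' @export
contrast_model <- function(frame) {
  ctr <- image_contrast(frame)
  list(
    a = max(frame), b = min(frame),
    contrast = ctr,
    e_threshold = threshold_from_contrast(ctr)
  )
}
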