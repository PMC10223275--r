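# Internal foot coordinates.
#
# Each foot carries an internal frame (x', y') in mm with the ankle at the
# origin: y' is the unit direction from the ankle landmark to the
# second-metatarsal landmark (the long axis of the foot), and x' completes
# the planar frame pointing toward the subject's right when the foot is not
# turned (theta = 0).  The same sign convention is used for both feet, so
# medial is +x' under the left foot and -x' under the right foot.

#' Build the pixel-to-internal-coordinate map of a foot grid
#'
#' @param rows,cols grid dimensions.
#' @param ankle_pixel `(row, col)` of the ankle landmark; fractional pixel
#'   coordinates are allowed.
#' @param axis_pixel `(row, col)` of the second-metatarsal landmark defining
#'   the +y' direction.
#' @param cell_size pixel edge, mm.
#' @param side `"left"` or `"right"`.
#' @return a `foot_geometry` with per-pixel internal coordinates `x`, `y`
#'   (rows x cols matrices, mm).
#' @export
build_geometry <- function(rows, cols, ankle_pixel, axis_pixel,
                           cell_size = 5, side = "left") {
  side <- assert_side(side)
  cell_size <- assert_scalar_num(cell_size, "cell_size", positive = TRUE)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("grid must be at least 1x1", call. = FALSE)
  for (p in list(ankle = ankle_pixel, axis = axis_pixel)) {
    if (length(p) != 2L || anyNA(p))
      stop("landmark pixels must be (row, col) pairs", call. = FALSE)
  }
  in_grid <- function(p) p[1L] >= 0.5 && p[1L] <= rows + 0.5 &&
    p[2L] >= 0.5 && p[2L] <= cols + 0.5
  if (!in_grid(ankle_pixel) || !in_grid(axis_pixel))
    stop("landmark pixel outside the grid", call. = FALSE)
  # pixel-space displacement ankle -> axis: u along columns (subject's
  # right), v along rows (toe row 1 at top, heel at the bottom)
  du <- (axis_pixel[2L] - ankle_pixel[2L]) * cell_size
  dv <- (axis_pixel[1L] - ankle_pixel[1L]) * cell_size
  len <- sqrt(du^2 + dv^2)
  if (len < 1e-9)
    stop("ankle and axis landmarks coincide", call. = FALSE)
  ey <- c(du, dv) / len
  ex <- c(-ey[2L], ey[1L])   # +x' toward the subject's right at theta = 0
  cu <- (col(matrix(0, rows, cols)) - ankle_pixel[2L]) * cell_size
  cv <- (row(matrix(0, rows, cols)) - ankle_pixel[1L]) * cell_size
  structure(list(side = side, rows = rows, cols = cols,
                 ankle_pixel = as.numeric(ankle_pixel),
                 axis_pixel = as.numeric(axis_pixel),
                 cell_size = cell_size,
                 x = cu * ex[1L] + cv * ex[2L],
                 y = cu * ey[1L] + cv * ey[2L]),
            class = "foot_geometry")
}

#' @export
print.foot_geometry <- function(x, ...) {
  cat(sprintf("<foot_geometry> %s foot %dx%d px, %g mm cells; ankle at (%.2f, %.2f)\n",
              x$side, x$rows, x$cols, x$cell_size,
              x$ankle_pixel[1L], x$ankle_pixel[2L]))
  invisible(x)
}

check_geometry_match <- function(recording, geometry) {
  d <- dim(recording$values)
  if (d[1L] != geometry$rows || d[2L] != geometry$cols)
    stop(sprintf("recording grid %dx%d does not match geometry %dx%d",
                 d[1L], d[2L], geometry$rows, geometry$cols), call. = FALSE)
  if (!identical(recording$side, geometry$side))
    stop("recording and geometry are for different feet", call. = FALSE)
  invisible(TRUE)
}

#' Reference total force and ankle moments from full pressure maps
#'
#' For each frame i the total force and the moment components about the
#' ankle along the internal axes are the exact linear forms
#' \deqn{F_i = \sum_k f_{ik}, \quad
#'       M_{x,i} = \sum_k x'_k f_{ik}, \quad
#'       M_{y,i} = \sum_k y'_k f_{ik}.}
#' No normalization is applied; dividing the moments by the force is done in
#' [cop_from_signals()].
#'
#' @param recording a `foot_recording`.
#' @param geometry the matching `foot_geometry`.
#' @return data frame with columns `frame`, `F` (force units), `Mx`, `My`
#'   (force x mm).
#' @export
reference_signals <- function(recording, geometry) {
  check_geometry_match(recording, geometry)
  d <- dim(recording$values)
  P <- matrix(recording$values, d[1L] * d[2L], d[3L])
  data.frame(frame = seq_len(d[3L]),
             F  = colSums(P),
             Mx = as.numeric(crossprod(as.numeric(geometry$x), P)),
             My = as.numeric(crossprod(as.numeric(geometry$y), P)))
}

#' Center of pressure from force and moment signals
#'
#' The CoP in internal coordinates is `(Mx/F, My/F)`.  Frames whose total
#' force falls below `min_force` have no well-defined CoP; with
#' `strict = TRUE` (the default) they raise an error naming the frames,
#' with `strict = FALSE` they yield `NA` and are flagged.
#'
#' @param F,Mx,My numeric vectors of equal length (one entry per frame).
#' @param min_force threshold below which the CoP is undefined (> 0).
#' @param strict error on undefined frames instead of flagging them.
#' @return data frame with columns `x`, `y` (mm) and logical `defined`.
#' @export
cop_from_signals <- function(F, Mx, My, min_force = 1, strict = TRUE) {
  min_force <- assert_scalar_num(min_force, "min_force", positive = TRUE)
  n <- length(F)
  if (length(Mx) != n || length(My) != n)
    stop("F, Mx, My must have equal length", call. = FALSE)
  defined <- is.finite(F) & F >= min_force
  if (strict && !all(defined)) {
    bad <- which(!defined)
    stop(sprintf("CoP undefined (force < %g) in frame(s) %s", min_force,
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  x <- ifelse(defined, Mx / F, NA_real_)
  y <- ifelse(defined, My / F, NA_real_)
  data.frame(x = x, y = y, defined = defined)
}
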