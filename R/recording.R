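# Pressure-map data model and container I/O.
#
# A recording is the time series of per-foot pressure maps on a fixed grid:
# frame i holds the pressure f_ik (N/cm^2) applied to pixel k.  The grid is
# row-major with row 1 at the toes and the heel at the last row; columns
# increase toward the subject's right for BOTH feet (bird's-eye view), so
# medial is +x' on the left foot and -x' on the right foot.

#' Construct a single pressure frame
#'
#' @param values numeric matrix (rows x cols) of pressures, N/cm^2.
#' @param side `"left"` or `"right"`.
#' @param frame_index integer position of the frame within its recording.
#' @param saturated count of pixels whose compression hit the simulator's
#'   clamp (0 for measured/loaded frames).
#' @return a `pressure_frame` object.
#' @export
pressure_frame <- function(values, side, frame_index = NA_integer_,
                           saturated = 0L) {
  side <- assert_side(side)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("pressure values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("pressure values must all be >= 0", call. = FALSE)
  structure(list(values = values, side = side,
                 frame_index = as.integer(frame_index),
                 saturated = as.integer(saturated)),
            class = "pressure_frame")
}

#' Construct a plantar pressure recording
#'
#' @param side `"left"` or `"right"`.
#' @param frames list of numeric matrices (or `pressure_frame`s), or a
#'   rows x cols x M numeric array.  All frames must share dimensions.
#' @param frame_rate sampling rate in Hz (default 50, the usual in-shoe
#'   pressure-map rate).
#' @param cell_size pixel edge length in mm (default 5).
#' @return a `foot_recording` with fields `side`, `values`
#'   (rows x cols x M array), `frame_rate`, `cell_size`.
#' @export
foot_recording <- function(side, frames, frame_rate = 50, cell_size = 5) {
  side <- assert_side(side)
  frame_rate <- assert_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  cell_size <- assert_scalar_num(cell_size, "cell_size", positive = TRUE)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    values <- frames
  } else {
    if (!is.list(frames) || length(frames) == 0L)
      stop("recording must contain >= 1 frame", call. = FALSE)
    mats <- lapply(frames, function(f) {
      if (inherits(f, "pressure_frame")) f$values else f
    })
    d <- dim(mats[[1L]])
    for (i in seq_along(mats)) {
      if (!is.matrix(mats[[i]]) || !identical(dim(mats[[i]]), d))
        stop(sprintf("frame %d does not match the recording grid", i),
             call. = FALSE)
    }
    values <- array(unlist(mats, use.names = FALSE), dim = c(d, length(mats)))
  }
  if (dim(values)[3L] < 1L)
    stop("recording must contain >= 1 frame", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("pressure values must all be finite", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(apply(values < 0, 3L, any))[1L]
    stop(sprintf("negative pressure value in frame %d", bad), call. = FALSE)
  }
  structure(list(side = side, values = values,
                 frame_rate = frame_rate, cell_size = cell_size),
            class = "foot_recording")
}

#' Number of frames in a recording
#' @param recording a `foot_recording`.
#' @return integer frame count M.
#' @export
n_frames <- function(recording) dim(recording$values)[3L]

#' Extract one frame of a recording
#' @param recording a `foot_recording`.
#' @param i frame index (1-based).
#' @return a `pressure_frame`.
#' @export
get_frame <- function(recording, i) {
  M <- n_frames(recording)
  if (i < 1L || i > M) stop(sprintf("frame index %d out of 1..%d", i, M),
                            call. = FALSE)
  pressure_frame(recording$values[, , i, drop = TRUE], recording$side, i)
}

#' @export
print.foot_recording <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<foot_recording> %s foot: %d frames of %dx%d px (%g mm cells) at %g Hz\n",
              x$side, d[3L], d[1L], d[2L], x$cell_size, x$frame_rate))
  invisible(x)
}

# ---------------------------------------------------------------------------
# container format (.ppm.txt): a plain-text header block of "key: value"
# lines (side, rows, cols, cell_size, frame_rate, frames), then one
# whitespace-delimited rows x cols block per frame, frames separated by
# blank lines.  Values are serialized at full binary round-trip precision.

#' Write a recording to the plain-text container format
#'
#' @param recording a `foot_recording`.
#' @param path output file path (conventionally `*.ppm.txt`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "foot_recording"))
  d <- dim(recording$values)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "format: sparsecop-ppm 1",
    paste0("side: ", recording$side),
    paste0("rows: ", d[1L]),
    paste0("cols: ", d[2L]),
    paste0("cell_size: ", fmt_full(recording$cell_size)),
    paste0("frame_rate: ", fmt_full(recording$frame_rate)),
    paste0("frames: ", d[3L])
  ), con)
  for (i in seq_len(d[3L])) {
    writeLines("", con)
    m <- recording$values[, , i, drop = TRUE]
    writeLines(apply(matrix(fmt_full(m), d[1L], d[2L]), 1L, paste,
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a recording from the plain-text container format
#'
#' @param path file written by [write_recording()].
#' @param side optional expected side; a mismatch with the file header is an
#'   error.
#' @return a `foot_recording`.
#' @export
read_recording <- function(path, side = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr_end <- which(!nzchar(trimws(lines)))[1L]
  if (is.na(hdr_end)) hdr_end <- length(lines) + 1L
  hdr_lines <- lines[seq_len(hdr_end - 1L)]
  kv <- regmatches(hdr_lines, regexec("^([A-Za-z_]+):\\s*(.*)$", hdr_lines))
  if (any(lengths(kv) != 3L))
    stop("malformed recording header", call. = FALSE)
  header <- stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  need <- c("side", "rows", "cols", "cell_size", "frame_rate", "frames")
  if (!all(need %in% names(header)))
    stop(sprintf("recording header missing field(s): %s",
                 paste(setdiff(need, names(header)), collapse = ", ")),
         call. = FALSE)
  rows <- as.integer(header[["rows"]]); cols <- as.integer(header[["cols"]])
  M <- as.integer(header[["frames"]])
  if (anyNA(c(rows, cols, M)) || rows < 1L || cols < 1L || M < 1L)
    stop("malformed recording header: bad dimensions", call. = FALSE)
  file_side <- header[["side"]]
  assert_side(file_side)
  if (!is.null(side) && !identical(side, file_side))
    stop(sprintf("recording is for the %s foot, expected %s", file_side, side),
         call. = FALSE)

  body <- lines[seq.int(hdr_end, length(lines))]
  body <- body[nzchar(trimws(body))]
  if (length(body) != rows * M)
    stop(sprintf("expected %d data rows (%d frames of %d rows), found %d",
                 rows * M, M, rows, length(body)), call. = FALSE)
  values <- array(NA_real_, dim = c(rows, cols, M))
  for (i in seq_len(M)) {
    block <- body[(i - 1L) * rows + seq_len(rows)]
    cells <- strsplit(trimws(block), "\\s+")
    if (any(lengths(cells) != cols))
      stop(sprintf("ragged frame %d: expected %d columns", i, cols),
           call. = FALSE)
    m <- matrix(as.numeric(unlist(cells)), rows, cols, byrow = TRUE)
    if (anyNA(m))
      stop(sprintf("non-numeric pressure value in frame %d", i), call. = FALSE)
    if (any(m < 0))
      stop(sprintf("negative pressure value in frame %d", i), call. = FALSE)
    values[, , i] <- m
  }
  foot_recording(file_side, values,
                 frame_rate = as.numeric(header[["frame_rate"]]),
                 cell_size = as.numeric(header[["cell_size"]]))
}
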