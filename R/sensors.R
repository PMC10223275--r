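# Sub-matrix sensors.
#
# A discrete sensor is realized as a square block of pressure-map pixels;
# its signal is the plain sum of the covered pixels.  Two standard sizes
# are supported: "small" 3x3 px (1.5 x 1.5 cm^2 at 5 mm cells) and "large"
# 5x5 px (2.5 x 2.5 cm^2).  Standard layouts of 2..6 sensors follow the
# usual high-pressure anatomical zones: heel, metatarsal heads 1/2/3/5,
# and the arch.

SENSOR_LANDMARKS <- c("heel", "met1", "met2", "met3", "met5", "arch",
                      "custom")

# landmark placement: t = fraction of foot length from the heel end along
# y'; u = medial-positive fraction of the half width along x'.  The
# metatarsal heads carry a slight longitudinal stagger (met2 most distal)
# reflecting the metatarsal arc.
LANDMARK_FRACTIONS <- list(
  heel = c(t = 0.12, u = 0.00),
  met1 = c(t = 0.72, u = 0.55),
  met2 = c(t = 0.78, u = 0.20),
  met3 = c(t = 0.75, u = -0.10),
  met5 = c(t = 0.71, u = -0.60),
  arch = c(t = 0.45, u = -0.50)
)

# Table of standard landmark sets by sensor count
LAYOUT_SETS <- list(
  `2` = c("heel", "met3"),
  `3` = c("heel", "met1", "met5"),
  `4` = c("heel", "met1", "met3", "met5"),
  `5` = c("heel", "met1", "met2", "met3", "met5"),
  `6` = c("heel", "met1", "met2", "met3", "met5", "arch")
)

#' Construct a single sub-matrix sensor
#'
#' @param center_pixel `(row, col)` integer center of the sensor window.
#' @param size_pixels odd window edge length in pixels (3 = small, 5 = large).
#' @param landmark anatomical label, one of
#'   `r paste0('"', SENSOR_LANDMARKS, '"', collapse = ", ")`.
#' @return a `sensor` object.
#' @export
sensor <- function(center_pixel, size_pixels = 3, landmark = "custom") {
  if (!landmark %in% SENSOR_LANDMARKS)
    stop(sprintf("unknown landmark \"%s\"", landmark), call. = FALSE)
  size_pixels <- as.integer(size_pixels)
  if (size_pixels < 1L || size_pixels %% 2L == 0L)
    stop("`size_pixels` must be a positive odd integer", call. = FALSE)
  center_pixel <- as.integer(round(center_pixel))
  if (length(center_pixel) != 2L || anyNA(center_pixel))
    stop("`center_pixel` must be an integer (row, col) pair", call. = FALSE)
  structure(list(landmark = landmark, center_pixel = center_pixel,
                 size_pixels = size_pixels),
            class = "sensor")
}

sensor_window <- function(s) {
  h <- (s$size_pixels - 1L) %/% 2L
  list(rows = (s$center_pixel[1L] - h):(s$center_pixel[1L] + h),
       cols = (s$center_pixel[2L] - h):(s$center_pixel[2L] + h))
}

windows_overlap <- function(a, b) {
  ha <- (a$size_pixels - 1L) %/% 2L
  hb <- (b$size_pixels - 1L) %/% 2L
  abs(a$center_pixel[1L] - b$center_pixel[1L]) <= ha + hb &&
    abs(a$center_pixel[2L] - b$center_pixel[2L]) <= ha + hb
}

#' Construct a sensor layout
#'
#' The sensor order is stable and defines the column order of all signal
#' matrices.  Windows may not overlap: overlapping windows would double
#' count pixels and break the conservation property that the summed sensor
#' readings never exceed the frame's total force.
#'
#' @param side `"left"` or `"right"`.
#' @param sensors list of [sensor()] objects.
#' @return a `sensor_layout` object.
#' @export
sensor_layout <- function(side, sensors) {
  side <- assert_side(side)
  if (!is.list(sensors) || length(sensors) < 1L ||
      !all(vapply(sensors, inherits, TRUE, "sensor")))
    stop("`sensors` must be a non-empty list of sensor objects", call. = FALSE)
  n <- length(sensors)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (windows_overlap(sensors[[i]], sensors[[j]]))
        stop(sprintf("sensor windows %d (%s) and %d (%s) overlap",
                     j, sensors[[j]]$landmark, i, sensors[[i]]$landmark),
             call. = FALSE)
    }
  }
  structure(list(side = side, sensors = sensors), class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %s foot, %d sensor(s):\n", x$side,
              length(x$sensors)))
  for (s in x$sensors)
    cat(sprintf("  %-6s %dx%d px at (%d, %d)\n", s$landmark, s$size_pixels,
                s$size_pixels, s$center_pixel[1L], s$center_pixel[2L]))
  invisible(x)
}

layout_in_grid <- function(layout, rows, cols) {
  for (i in seq_along(layout$sensors)) {
    w <- sensor_window(layout$sensors[[i]])
    if (min(w$rows) < 1L || max(w$rows) > rows ||
        min(w$cols) < 1L || max(w$cols) > cols)
      return(i)
  }
  0L
}

# deterministic overlap resolution: scan ordered pairs, nudging the
# later sensor one pixel away from the earlier along the dominant-offset
# axis (ties move the column).  Errors out rather than looping forever.
resolve_overlaps <- function(sensors, rows, cols) {
  for (pass in seq_len(50L)) {
    moved <- FALSE
    n <- length(sensors)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      if (!windows_overlap(sensors[[i]], sensors[[j]])) next
      a <- sensors[[i]]$center_pixel; b <- sensors[[j]]$center_pixel
      h <- (sensors[[j]]$size_pixels - 1L) %/% 2L
      dr <- b[1L] - a[1L]; dc <- b[2L] - a[2L]
      step_c <- if (dc >= 0L) 1L else -1L
      step_r <- if (dr >= 0L) 1L else -1L
      cand <- if (abs(dc) >= abs(dr)) {
        list(c(0L, step_c), c(step_r, 0L))
      } else {
        list(c(step_r, 0L), c(0L, step_c))
      }
      ok <- FALSE
      for (d in cand) {
        nb <- b + d
        if (nb[1L] - h >= 1L && nb[1L] + h <= rows &&
            nb[2L] - h >= 1L && nb[2L] + h <= cols) {
          sensors[[j]]$center_pixel <- nb
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf("cannot place sensor %d (%s) without overlap inside the grid",
                     j, sensors[[j]]$landmark), call. = FALSE)
      moved <- TRUE
    }
    if (!moved) return(sensors)
  }
  stop("sensor de-overlap did not converge", call. = FALSE)
}

#' Standard anatomical sensor layout
#'
#' Builds the standard landmark set for a given sensor count — 2: heel +
#' 3rd metatarsal; 3: heel + 1st + 5th metatarsals; 4: adds the 3rd; 5:
#' adds the 2nd; 6: adds the arch — with positions computed from
#' foot-length/width fractions, snapped to the nearest pixel center (ties
#' break toward the heel and the medial side).  Snapped windows that would
#' still overlap at the requested size are nudged apart deterministically
#' by whole pixels; CoP estimation is insensitive to the exact sensor
#' positions, so the nudge only preserves the non-overlap invariant.
#'
#' @param n_sensors 2..6 (6 requires the small size on typical grids).
#' @param size_pixels 3 (small) or 5 (large).
#' @param geometry the foot's `foot_geometry` (supplies grid, side and the
#'   heel-to-toe orientation).
#' @return a `sensor_layout`.
#' @export
anatomical_layout <- function(n_sensors, size_pixels = 3, geometry) {
  if (!n_sensors %in% 2:6)
    stop("`n_sensors` must be between 2 and 6", call. = FALSE)
  if (!size_pixels %in% c(3L, 5L))
    stop("`size_pixels` must be 3 (small) or 5 (large)", call. = FALSE)
  size_pixels <- as.integer(size_pixels)
  stopifnot(inherits(geometry, "foot_geometry"))
  rows <- geometry$rows; cols <- geometry$cols
  cc <- (cols + 1) / 2
  s <- if (geometry$side == "left") 1 else -1
  snap_row <- function(rf) {
    # ties toward the heel (larger row index)
    r <- if (abs(rf - round(rf)) == 0.5) ceiling(rf) else round(rf)
    as.integer(r)
  }
  snap_col <- function(cf) {
    # ties toward the medial side
    c0 <- if (abs(cf - round(cf)) == 0.5) {
      if (s > 0) ceiling(cf) else floor(cf)
    } else round(cf)
    as.integer(c0)
  }
  sensors <- lapply(LAYOUT_SETS[[as.character(n_sensors)]], function(lm) {
    fr <- LANDMARK_FRACTIONS[[lm]]
    rf <- rows + 0.5 - fr[["t"]] * rows
    cf <- cc + fr[["u"]] * (cols / 2) * s
    sensor(c(snap_row(rf), snap_col(cf)), size_pixels, lm)
  })
  h <- (size_pixels - 1L) %/% 2L
  for (i in seq_along(sensors)) {
    cp <- sensors[[i]]$center_pixel
    # clamp the snapped center so the window starts inside the grid
    sensors[[i]]$center_pixel <- c(min(max(cp[1L], 1L + h), rows - h),
                                   min(max(cp[2L], 1L + h), cols - h))
    if (rows < size_pixels || cols < size_pixels)
      stop("grid smaller than the sensor window", call. = FALSE)
  }
  sensors <- resolve_overlaps(sensors, rows, cols)
  layout <- sensor_layout(geometry$side, sensors)
  if (layout_in_grid(layout, rows, cols) > 0L)
    stop("sensor window exits the grid", call. = FALSE)
  layout
}

#' Extract sensor signals from a recording
#'
#' Per frame and sensor, the reading is the sum of the size x size pixel
#' block centered on the sensor.
#'
#' @param recording a `foot_recording`.
#' @param layout a `sensor_layout` on the same side and grid.
#' @return numeric matrix, frames x sensors, with landmark column names.
#' @export
extract_signals <- function(recording, layout) {
  stopifnot(inherits(recording, "foot_recording"),
            inherits(layout, "sensor_layout"))
  if (!identical(recording$side, layout$side))
    stop("recording and layout are for different feet", call. = FALSE)
  d <- dim(recording$values)
  bad <- layout_in_grid(layout, d[1L], d[2L])
  if (bad > 0L)
    stop(sprintf("sensor %d window exits the %dx%d recording grid",
                 bad, d[1L], d[2L]), call. = FALSE)
  S <- length(layout$sensors)
  out <- matrix(0, d[3L], S)
  for (j in seq_len(S)) {
    w <- sensor_window(layout$sensors[[j]])
    out[, j] <- apply(recording$values[w$rows, w$cols, , drop = FALSE], 3L,
                      sum)
  }
  colnames(out) <- make.unique(vapply(layout$sensors, `[[`, "", "landmark"))
  out
}

# ---------------------------------------------------------------------------
# layout config I/O (YAML)

#' Write a sensor layout to a YAML config file
#' @param layout a `sensor_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "sensor_layout"))
  obj <- list(side = layout$side,
              sensors = lapply(layout$sensors, function(s) {
                list(landmark = s$landmark,
                     center_pixel = as.integer(s$center_pixel),
                     size_pixels = s$size_pixels)
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a sensor layout from a YAML config file
#'
#' Entries may give an explicit `center_pixel` (landmark defaults to
#' `"custom"`); overlap and malformed entries are validation errors.
#'
#' @param path config path written by [write_layout()] or hand-edited.
#' @return a `sensor_layout`.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  obj <- yaml::read_yaml(path)
  if (is.null(obj$side) || is.null(obj$sensors))
    stop("layout config must have `side` and `sensors`", call. = FALSE)
  sensors <- lapply(obj$sensors, function(e) {
    if (is.null(e$center_pixel))
      stop("each layout entry needs a `center_pixel`", call. = FALSE)
    sensor(unlist(e$center_pixel), e$size_pixels %||% 3L,
           e$landmark %||% "custom")
  })
  sensor_layout(obj$side, sensors)
}
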