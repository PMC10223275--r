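# Robustness evaluation: RMS/SD errors between sparse-sensor estimates and
# full-map references, per foot and for the two-foot CoPT, swept over
# sensor number and size.

#' RMS error and SD of the error between two aligned series
#'
#' Over the scored frames (finite in both series) the error is
#' `e_i = est_i - ref_i`; the function returns
#' `rms = sqrt(mean(e^2))` and the sample standard deviation of `e`.
#' A pure bias therefore shows up in the RMS but not the SD.
#'
#' @param est,ref aligned numeric vectors (NA = unscored frame).
#' @return named numeric vector `c(rms, sd, n)`.
#' @export
rms_sd <- function(est, ref) {
  if (length(est) != length(ref))
    stop("`est` and `ref` must have equal length", call. = FALSE)
  ok <- is.finite(est) & is.finite(ref)
  e <- est[ok] - ref[ok]
  if (length(e) < 2L)
    stop("need at least 2 scored frames", call. = FALSE)
  c(rms = sqrt(mean(e^2)), sd = stats::sd(e), n = length(e))
}

layout_size <- function(layout) layout$sensors[[1L]]$size_pixels

#' Evaluate one sensor layout pair against full-map references
#'
#' Splits each recording into a contiguous calibration window (first
#' `calib_fraction` of frames) and a held-out scoring window, fits the
#' linear-form calibration per foot on the window, and scores the held-out
#' per-foot CoP (ML = x', AP = y', internal coordinates) and the two-foot
#' CoPT (ML = x, AP = y, ground frame) against the full-map references.
#' Frames with reference or predicted force below `min_force` are excluded
#' from scoring and counted.
#'
#' @param rec_L,rec_R per-foot `foot_recording`s (aligned frame for frame).
#' @param geom_L,geom_R matching geometries.
#' @param stance a [stance_config()].
#' @param layout_L,layout_R per-foot `sensor_layout`s.
#' @param calib_fraction fraction of frames used for calibration
#'   (default 0.2; contiguous, no shuffling).
#' @param min_force low-load exclusion threshold.
#' @param ridge optional ridge penalty passed to [fit_calibration()].
#' @param layout_id label copied into the report rows.
#' @return data frame with one row per (side: L, R, total) x (axis: ML,
#'   AP): `layout_id`, `side`, `axis`, `n_sensors`, `sensor_size`,
#'   `rms_mm`, `sd_mm`, `n_frames_scored`, `n_frames_excluded`.
#' @export
evaluate_layout <- function(rec_L, rec_R, geom_L, geom_R, stance,
                            layout_L, layout_R, calib_fraction = 0.2,
                            min_force = 1, ridge = 0, layout_id = NULL) {
  M <- n_frames(rec_L)
  if (n_frames(rec_R) != M)
    stop("left and right recordings must have the same frame count",
         call. = FALSE)
  n_cal <- max(1L, floor(calib_fraction * M))
  if (n_cal >= M) stop("calibration window leaves no frames to score",
                       call. = FALSE)
  cal <- seq_len(n_cal)
  test <- seq.int(n_cal + 1L, M)
  S <- length(layout_L$sensors)
  if (is.null(layout_id))
    layout_id <- sprintf("n%d_size%d", S, layout_size(layout_L))

  per_foot <- function(rec, geom, layout) {
    refs <- reference_signals(rec, geom)
    sig <- extract_signals(rec, layout)
    model <- tryCatch(
      fit_calibration(sig[cal, , drop = FALSE], refs[cal, ],
                      min_force = min_force, ridge = ridge,
                      side = geom$side),
      error = function(e) stop(sprintf("layout %s (%s foot): %s", layout_id,
                                       geom$side, conditionMessage(e)),
                               call. = FALSE))
    pred <- predict(model, sig[test, , drop = FALSE])
    ref_t <- refs[test, ]
    ref_cop <- cop_from_signals(ref_t$F, ref_t$Mx, ref_t$My, min_force,
                                strict = FALSE)
    est_cop <- cop_from_signals(pred$F, pred$Mx, pred$My, min_force,
                                strict = FALSE)
    list(model = model, refs = ref_t, pred = pred,
         ref_cop = ref_cop, est_cop = est_cop)
  }
  L <- per_foot(rec_L, geom_L, layout_L)
  R <- per_foot(rec_R, geom_R, layout_R)

  row_of <- function(side, axis, est, ref) {
    m <- rms_sd(est, ref)
    data.frame(layout_id = layout_id, side = side, axis = axis,
               n_sensors = S, sensor_size = layout_size(layout_L),
               rms_mm = unname(m["rms"]), sd_mm = unname(m["sd"]),
               n_frames_scored = as.integer(m["n"]),
               n_frames_excluded = length(test) - as.integer(m["n"]))
  }
  ref_copt <- copt(L$refs$F, L$refs$Mx, L$refs$My,
                   R$refs$F, R$refs$Mx, R$refs$My, stance,
                   min_force, strict = FALSE)
  est_copt <- copt(L$pred$F, L$pred$Mx, L$pred$My,
                   R$pred$F, R$pred$Mx, R$pred$My, stance,
                   min_force, strict = FALSE)
  rbind(row_of("L", "ML", L$est_cop$x, L$ref_cop$x),
        row_of("L", "AP", L$est_cop$y, L$ref_cop$y),
        row_of("R", "ML", R$est_cop$x, R$ref_cop$x),
        row_of("R", "AP", R$est_cop$y, R$ref_cop$y),
        row_of("total", "ML", est_copt$x, ref_copt$x),
        row_of("total", "AP", est_copt$y, ref_copt$y))
}

#' Sweep sensor number and size
#'
#' Runs [evaluate_layout()] over the standard anatomical layouts: by
#' default 2..6 sensors at the small (3x3 px) size and 2..5 at the large
#' (5x5 px) size, where the six-sensor large set cannot be placed without
#' window overlap on typical grids.  Layouts that cannot be placed are
#' skipped with a warning naming the layout, never silently.
#'
#' @param rec_L,rec_R,geom_L,geom_R,stance as in [evaluate_layout()].
#' @param n_small,n_large sensor counts per size.
#' @param ... further arguments to [evaluate_layout()]
#'   (`calib_fraction`, `min_force`, `ridge`).
#' @return a report data frame (6 rows per feasible layout), deterministic
#'   given the inputs.
#' @export
sweep_layouts <- function(rec_L, rec_R, geom_L, geom_R, stance,
                          n_small = 2:6, n_large = 2:5, ...) {
  grid <- rbind(
    if (length(n_small)) data.frame(n = n_small, size = 3L),
    if (length(n_large)) data.frame(n = n_large, size = 5L)
  )
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; size <- grid$size[i]
    id <- sprintf("n%d_size%d", n, size)
    res <- tryCatch({
      lay_L <- anatomical_layout(n, size, geom_L)
      lay_R <- anatomical_layout(n, size, geom_R)
      evaluate_layout(rec_L, rec_R, geom_L, geom_R, stance, lay_L, lay_R,
                      layout_id = id, ...)
    }, error = function(e) {
      warning(sprintf("skipping layout %s: %s", id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    rows[[i]] <- res
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(layout_id = character(), side = character(),
                      axis = character(), n_sensors = integer(),
                      sensor_size = integer(), rms_mm = numeric(),
                      sd_mm = numeric(), n_frames_scored = integer(),
                      n_frames_excluded = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation report to CSV
#'
#' Stable column order; numeric fields serialized at 9 significant digits
#' so reports round-trip through [read_report()].
#'
#' @param report data frame from [evaluate_layout()]/[sweep_layouts()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  cols <- c("layout_id", "side", "axis", "n_sensors", "sensor_size",
            "rms_mm", "sd_mm", "n_frames_scored", "n_frames_excluded")
  if (nrow(report) == 0L) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  out <- report[, cols]
  out$rms_mm <- sprintf("%.9g", out$rms_mm)
  out$sd_mm <- sprintf("%.9g", out$sd_mm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an evaluation report CSV
#' @param path CSV written by [write_report()].
#' @return the report data frame.
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bar chart of RMS +/- SD by sensor count
#'
#' Companion figure for reports: one panel per axis, bars by sensor count
#' and side with SD whiskers.  Requires ggplot2.
#'
#' @param report data frame from [sweep_layouts()].
#' @param sensor_size which size to plot (3 or 5).
#' @return a ggplot object.
#' @export
plot_report <- function(report, sensor_size = 3) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_report() requires the ggplot2 package", call. = FALSE)
  d <- report[report$sensor_size == sensor_size, ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(n_sensors), y = rms_mm,
                                  fill = side)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(rms_mm - sd_mm, 0),
                                        ymax = rms_mm + sd_mm),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "number of sensors", y = "RMS error (mm)",
                  title = sprintf("CoP error, %dx%d px sensors",
                                  sensor_size, sensor_size)) +
    ggplot2::theme_minimal()
}
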