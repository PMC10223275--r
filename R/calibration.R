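# Linear-form calibration.
#
# The working hypothesis is that the total force and the two ankle-moment
# components of a foot are linear forms of the S sensor readings:
#     F~_i  = sum_j Cf_j  * fc_ij
#     Mx~_i = sum_j Cmx_j * fc_ij
#     My~_i = sum_j Cmy_j * fc_ij
# with three constant coefficient sets learned once per foot from a
# calibration window in which full pressure maps provide the targets.  The
# fits are ordinary least squares through the origin (no intercept: zero
# signals must predict zero force and moments), one independent fit per
# target; with a shared design matrix independent and joint fits coincide.

#' Fit the linear-form calibration of a foot
#'
#' @param signals frames x S numeric matrix of sensor readings (column
#'   order = layout order; see [extract_signals()]).
#' @param references data frame with `F`, `Mx`, `My` from
#'   [reference_signals()], aligned with `signals` rows.
#' @param frame_mask optional logical vector selecting calibration frames;
#'   defaults to frames with reference force `>= min_force` (low-load
#'   frames carry large relative error and are excluded).
#' @param min_force force threshold used for the default mask.
#' @param ridge optional non-negative ridge penalty for near-degenerate
#'   layouts (0 = plain OLS, the default).
#' @param side foot side stored in the model (informational).
#' @return a `calibration_model` with coefficient vectors `Cf`
#'   (dimensionless), `Cmx`, `Cmy` (mm), per-target residual RMS
#'   diagnostics and the number of frames used.
#' @export
fit_calibration <- function(signals, references, frame_mask = NULL,
                            min_force = 1, ridge = 0, side = NULL) {
  signals <- as.matrix(signals)
  S <- ncol(signals)
  if (!all(c("F", "Mx", "My") %in% names(references)))
    stop("`references` must have columns F, Mx, My", call. = FALSE)
  if (nrow(references) != nrow(signals))
    stop("`signals` and `references` must have the same number of frames",
         call. = FALSE)
  if (is.null(frame_mask)) frame_mask <- references$F >= min_force
  if (length(frame_mask) != nrow(signals))
    stop("`frame_mask` length must equal the number of frames", call. = FALSE)
  X <- signals[frame_mask, , drop = FALSE]
  Y <- cbind(F = references$F, Mx = references$Mx,
             My = references$My)[frame_mask, , drop = FALSE]
  if (nrow(X) < S)
    stop(sprintf("too few calibration frames (%d) for %d sensors",
                 nrow(X), S), call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < S) {
    nm <- colnames(X) %||% paste0("s", seq_len(S))
    degenerate <- nm[qrx$pivot[(qrx$rank + 1L):S]]
    stop(sprintf("rank-deficient signal matrix; degenerate sensor(s): %s",
                 paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  coef <- if (ridge > 0) {
    solve(crossprod(X) + diag(ridge, S), crossprod(X, Y))
  } else {
    qr.coef(qrx, Y)
  }
  resid <- Y - X %*% coef
  structure(list(side = side,
                 sensors = colnames(X) %||% paste0("s", seq_len(S)),
                 Cf = unname(coef[, "F"]),
                 Cmx = unname(coef[, "Mx"]),
                 Cmy = unname(coef[, "My"]),
                 residual_rms = sqrt(colMeans(resid^2)),
                 n_frames = nrow(X),
                 ridge = ridge),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s%d sensors (%s), fitted on %d frames\n",
              if (is.null(x$side)) "" else paste0(x$side, " foot, "),
              length(x$Cf), paste(x$sensors, collapse = ", "), x$n_frames))
  cat(sprintf("  residual RMS: F %.4g, Mx %.4g, My %.4g\n",
              x$residual_rms[["F"]], x$residual_rms[["Mx"]],
              x$residual_rms[["My"]]))
  invisible(x)
}

#' Predict force and moments from sensor signals
#'
#' @param object a `calibration_model`.
#' @param signals frames x S matrix in the model's sensor order.
#' @param ... unused.
#' @return data frame with predicted `F`, `Mx`, `My` per frame.
#' @export
predict.calibration_model <- function(object, signals, ...) {
  signals <- as.matrix(signals)
  if (ncol(signals) != length(object$Cf))
    stop(sprintf("signal matrix has %d columns, model expects %d",
                 ncol(signals), length(object$Cf)), call. = FALSE)
  data.frame(F  = as.numeric(signals %*% object$Cf),
             Mx = as.numeric(signals %*% object$Cmx),
             My = as.numeric(signals %*% object$Cmy))
}

#' Per-frame CoP series from a fitted model
#'
#' Applies [cop_from_signals()] to the model predictions; frames whose
#' predicted force falls below `min_force` are flagged undefined (NA
#' coordinates) rather than erroring, so they can be excluded downstream.
#'
#' @param model a `calibration_model`.
#' @param signals frames x S signal matrix.
#' @param min_force CoP-definedness threshold.
#' @return data frame with `frame`, predicted `F`, CoP `x`, `y` (mm) and
#'   logical `defined`.
#' @export
estimate_cop_series <- function(model, signals, min_force = 1) {
  pred <- predict(model, signals)
  cop <- cop_from_signals(pred$F, pred$Mx, pred$My, min_force,
                          strict = FALSE)
  data.frame(frame = seq_len(nrow(pred)), F = pred$F,
             x = cop$x, y = cop$y, defined = cop$defined)
}

# ---------------------------------------------------------------------------
# calibration model I/O

#' Write a calibration model to a YAML file
#' @param model a `calibration_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(side = model$side, sensors = as.list(model$sensors),
              Cf = as.list(fmt_full(model$Cf)),
              Cmx = as.list(fmt_full(model$Cmx)),
              Cmy = as.list(fmt_full(model$Cmy)),
              residual_rms = as.list(fmt_full(model$residual_rms)),
              n_frames = model$n_frames, ridge = model$ridge)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a calibration model written by [write_calibration()]
#' @param path model file path.
#' @return a `calibration_model`.
#' @export
read_calibration <- function(path) {
  obj <- yaml::read_yaml(path)
  rms <- as.numeric(unlist(obj$residual_rms))
  names(rms) <- c("F", "Mx", "My")
  structure(list(side = obj$side, sensors = unlist(obj$sensors),
                 Cf = as.numeric(unlist(obj$Cf)),
                 Cmx = as.numeric(unlist(obj$Cmx)),
                 Cmy = as.numeric(unlist(obj$Cmy)),
                 residual_rms = rms,
                 n_frames = as.integer(obj$n_frames),
                 ridge = as.numeric(obj$ridge)),
            class = "calibration_model")
}
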