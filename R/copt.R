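# Two-foot total center of pressure (CoPT).
#
# Ground frame: origin midway between the ankles, x from the left ankle
# toward the right one (mediolateral), y perpendicular (anteroposterior).
# The ankles sit at -dx/2 (left) and +dx/2 (right); each foot's internal
# frame is rotated by its stance angle theta (> 0 = turned out), which in
# the ground frame is a counterclockwise rotation for the left foot and a
# clockwise rotation for the right foot.  With per-foot forces and ankle
# moments the CoPT is
#   x = [MxL cosTL + MxR cosTR - MyL sinTL + MyR sinTR] / (FL + FR) + p
#   y = [MyL cosTL + MyR cosTR + MxL sinTL - MxR sinTR] / (FL + FR)
#   p = (dx / 2) * (FR - FL) / (FR + FL),
# the force-sharing offset p moving the CoPT toward the loaded foot.

#' Two-foot stance configuration
#'
#' @param delta_x ankle-to-ankle mediolateral distance, mm (default 220, a
#'   natural hip-width stance).
#' @param theta_L,theta_R foot angles in degrees, positive = turned out
#'   (typically below 20 degrees).
#' @return a `stance_config` object.
#' @export
stance_config <- function(delta_x = 220, theta_L = 0, theta_R = 0) {
  delta_x <- assert_scalar_num(delta_x, "delta_x", positive = TRUE)
  theta_L <- assert_scalar_num(theta_L, "theta_L")
  theta_R <- assert_scalar_num(theta_R, "theta_R")
  if (abs(theta_L) >= 90 || abs(theta_R) >= 90)
    stop("stance angles must satisfy |theta| < 90 degrees", call. = FALSE)
  structure(list(delta_x = delta_x, theta_L = theta_L, theta_R = theta_R),
            class = "stance_config")
}

#' Total center of pressure of the body from per-foot signals
#'
#' Combines the per-foot total forces and ankle moments (full-map reference
#' values or sparse-sensor predictions alike) into the two-foot CoPT in the
#' ground frame.  All arguments are vectorized over frames.
#'
#' @param F_L,Mx_L,My_L,F_R,Mx_R,My_R per-foot force and moment series.
#' @param stance a [stance_config()].
#' @param min_force total-force threshold below which the CoPT is
#'   undefined.
#' @param strict error on undefined frames (default) or flag them.
#' @return data frame with `x`, `y` (mm), the force-sharing offset `p`
#'   (mm), total force `F` and logical `defined`.
#' @export
copt <- function(F_L, Mx_L, My_L, F_R, Mx_R, My_R, stance,
                 min_force = 1, strict = TRUE) {
  stopifnot(inherits(stance, "stance_config"))
  tl <- stance$theta_L * pi / 180
  tr <- stance$theta_R * pi / 180
  Ftot <- F_L + F_R
  defined <- is.finite(Ftot) & Ftot >= min_force
  if (strict && !all(defined)) {
    bad <- which(!defined)
    stop(sprintf("CoPT undefined (total force < %g) in frame(s) %s",
                 min_force, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  p <- (stance$delta_x / 2) * (F_R - F_L) / Ftot
  x <- (Mx_L * cos(tl) + Mx_R * cos(tr) - My_L * sin(tl) + My_R * sin(tr)) /
    Ftot + p
  y <- (My_L * cos(tl) + My_R * cos(tr) + Mx_L * sin(tl) - Mx_R * sin(tr)) /
    Ftot
  data.frame(x = ifelse(defined, x, NA_real_),
             y = ifelse(defined, y, NA_real_),
             p = ifelse(defined, p, NA_real_),
             F = Ftot, defined = defined)
}

#' Brute-force CoPT oracle from full pressure maps
#'
#' Independent check of [copt()]: maps every pixel of each foot into the
#' ground frame with the stance's rigid transforms — left foot
#' `(x, y) = (-dx/2 + x' cosTL - y' sinTL, x' sinTL + y' cosTL)`, right
#' foot `(x, y) = (+dx/2 + x' cosTR + y' sinTR, -x' sinTR + y' cosTR)` —
#' and returns the pressure-weighted barycenter.
#'
#' @param frame_L,frame_R per-foot `pressure_frame`s (or plain matrices).
#' @param geometry_L,geometry_R matching geometries.
#' @param stance a [stance_config()].
#' @param min_force definedness threshold on the total force.
#' @return c(x, y) in mm.
#' @export
copt_oracle <- function(frame_L, geometry_L, frame_R, geometry_R, stance,
                        min_force = 1) {
  stopifnot(inherits(stance, "stance_config"))
  vL <- if (inherits(frame_L, "pressure_frame")) frame_L$values else frame_L
  vR <- if (inherits(frame_R, "pressure_frame")) frame_R$values else frame_R
  tl <- stance$theta_L * pi / 180
  tr <- stance$theta_R * pi / 180
  Ftot <- sum(vL) + sum(vR)
  if (Ftot < min_force)
    stop(sprintf("CoPT undefined: total force %g < %g", Ftot, min_force),
         call. = FALSE)
  gxL <- -stance$delta_x / 2 + geometry_L$x * cos(tl) - geometry_L$y * sin(tl)
  gyL <- geometry_L$x * sin(tl) + geometry_L$y * cos(tl)
  gxR <- stance$delta_x / 2 + geometry_R$x * cos(tr) + geometry_R$y * sin(tr)
  gyR <- -geometry_R$x * sin(tr) + geometry_R$y * cos(tr)
  c(x = (sum(gxL * vL) + sum(gxR * vR)) / Ftot,
    y = (sum(gyL * vL) + sum(gyR * vR)) / Ftot)
}
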