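# Forward anatomical foot model and quiet-standing sway simulator.
#
# The model has three elements: the foot seat FS (a plane locating the foot
# in space: ankle height plus two tilts), the internal shape IS (the rigid,
# non-compressible profile of the skeleton and rigid media, expressed as a
# per-pixel clearance above the seat plane), and the elastic medium EM (soft
# tissue of per-pixel thickness and stiffness).  Compressing the elastic
# medium by Zc generates the pressure
#     F = -stiff * ln(1 - Zc / thick),
# which diverges as the tissue bottoms out and vanishes at zero compression.

#' Pressure generated by compressing the elastic medium
#'
#' @param Zc compression, mm; must satisfy `0 <= Zc < thick`.
#' @param thick tissue thickness, mm (> 0).
#' @param stiff tissue stiffness, N/cm^2 (> 0).
#' @return pressure in N/cm^2: `-stiff * log(1 - Zc/thick)`.
#' @seealso [compression_from_pressure()] for the inverse.
#' @export
pressure_from_compression <- function(Zc, thick, stiff) {
  if (any(thick <= 0) || any(stiff <= 0))
    stop("`thick` and `stiff` must be > 0", call. = FALSE)
  if (any(Zc < 0)) stop("compression must be >= 0", call. = FALSE)
  if (any(Zc >= thick))
    stop("infinite compression: Zc must be < thick", call. = FALSE)
  -stiff * log1p(-Zc / thick)
}

#' Compression producing a given pressure
#'
#' Inverse of [pressure_from_compression()]:
#' `Zc = thick * (1 - exp(-F/stiff))`.
#'
#' @param F pressure, N/cm^2 (>= 0).
#' @param thick tissue thickness, mm (> 0).
#' @param stiff tissue stiffness, N/cm^2 (> 0).
#' @return compression in mm.
#' @export
compression_from_pressure <- function(F, thick, stiff) {
  if (any(thick <= 0) || any(stiff <= 0))
    stop("`thick` and `stiff` must be > 0", call. = FALSE)
  if (any(F < 0)) stop("pressure must be >= 0", call. = FALSE)
  thick * -expm1(-F / stiff)
}

#' Mechanical parameters of the anatomical foot model
#'
#' @param internal_shape rows x cols matrix of rigid-shape clearance above
#'   the seat-plane reference, mm (>= 0; large values mean the pixel cannot
#'   contact the ground).
#' @param thickness rows x cols matrix (or scalar) of elastic-medium
#'   thickness, mm (> 0).
#' @param stiffness scalar or rows x cols matrix of stiffness, N/cm^2 (> 0).
#' @return a `foot_model_params` object.
#' @export
foot_model_params <- function(internal_shape, thickness, stiffness) {
  if (!is.matrix(internal_shape))
    stop("`internal_shape` must be a matrix", call. = FALSE)
  d <- dim(internal_shape)
  expand <- function(x, name) {
    if (length(x) == 1L) x <- matrix(x, d[1L], d[2L])
    if (!is.matrix(x) || !identical(dim(x), d))
      stop(sprintf("`%s` must be scalar or match the grid", name),
           call. = FALSE)
    x
  }
  thickness <- expand(thickness, "thickness")
  stiffness <- expand(stiffness, "stiffness")
  if (any(internal_shape < 0)) stop("internal shape clearance must be >= 0",
                                    call. = FALSE)
  if (any(thickness <= 0) || any(stiffness <= 0))
    stop("thickness and stiffness must be > 0", call. = FALSE)
  structure(list(internal_shape = internal_shape, thickness = thickness,
                 stiffness = stiffness),
            class = "foot_model_params")
}

#' Foot seat: the plane locating the foot in space
#'
#' The seat-plane height above ground at internal coordinates (x', y') is
#' `z0 + tilt_x * x' + tilt_y * y'`.
#'
#' @param z0 ankle-reference height, mm.
#' @param tilt_x,tilt_y slopes (mm of height per mm along x'/y').
#' @return a `foot_seat` object.
#' @export
foot_seat <- function(z0, tilt_x = 0, tilt_y = 0) {
  structure(list(z0 = assert_scalar_num(z0, "z0"),
                 tilt_x = assert_scalar_num(tilt_x, "tilt_x"),
                 tilt_y = assert_scalar_num(tilt_y, "tilt_y")),
            class = "foot_seat")
}

check_params_match <- function(params, geometry) {
  if (!identical(dim(params$internal_shape), c(geometry$rows, geometry$cols)))
    stop("model parameters do not match the geometry grid", call. = FALSE)
  invisible(TRUE)
}

#' Simulate one pressure frame from a foot posture
#'
#' Per pixel the clearance between the rigid shape and the ground is
#' `g = seat(x', y') + IS`.  Where `g >= thick` the pixel does not touch the
#' ground and its pressure is 0; otherwise the tissue is compressed by
#' `Zc = thick - g`, clamped at `(1 - 1e-3) * thick` to keep the logarithmic
#' law finite, and the pressure follows [pressure_from_compression()].
#' Pixels that hit the clamp are counted in the frame's `saturated` field.
#'
#' @param params a `foot_model_params`.
#' @param geometry the matching `foot_geometry`.
#' @param seat a `foot_seat`.
#' @param clamp_eps clamp margin (fraction of thickness left uncompressed).
#' @return a `pressure_frame`.
#' @export
simulate_frame <- function(params, geometry, seat, clamp_eps = 1e-3) {
  check_params_match(params, geometry)
  stopifnot(inherits(seat, "foot_seat"))
  g <- seat$z0 + seat$tilt_x * geometry$x + seat$tilt_y * geometry$y +
    params$internal_shape
  Zc <- params$thickness - g
  zmax <- (1 - clamp_eps) * params$thickness
  saturated <- sum(Zc > zmax)
  Zc <- pmin(Zc, zmax)
  f <- matrix(0, geometry$rows, geometry$cols)
  contact <- Zc > 0
  f[contact] <- -params$stiffness[contact] *
    log1p(-Zc[contact] / params$thickness[contact])
  pressure_frame(f, geometry$side, saturated = saturated)
}

total_force_at <- function(params, geometry, z0, tilt_x, tilt_y, clamp_eps) {
  sum(simulate_frame(params, geometry, foot_seat(z0, tilt_x, tilt_y),
                     clamp_eps)$values)
}

#' Seat height realizing a target total force
#'
#' Total simulated force is continuous and monotone non-increasing in the
#' ankle height `z0`, so the height matching a target load is found by
#' bisection to a 0.1% relative force tolerance.
#'
#' @param params a `foot_model_params`.
#' @param geometry the matching `foot_geometry`.
#' @param tilt_x,tilt_y seat-plane slopes.
#' @param target_force desired total force (sum over pixels), >= 0.
#' @param tol relative force tolerance (default 1e-3).
#' @param max_depth how far below first contact the seat may sink, mm.
#' @param clamp_eps passed to [simulate_frame()].
#' @return the ankle height `z0`, mm.
#' @export
solve_seat_height <- function(params, geometry, tilt_x = 0, tilt_y = 0,
                              target_force, tol = 1e-3, max_depth = 40,
                              clamp_eps = 1e-3) {
  check_params_match(params, geometry)
  if (target_force < 0) stop("`target_force` must be >= 0", call. = FALSE)
  # smallest z0 with zero contact everywhere: g >= thick for every pixel
  z_free <- max(params$thickness - params$internal_shape -
                  tilt_x * geometry$x - tilt_y * geometry$y)
  if (target_force == 0) return(z_free)
  lo <- z_free - max_depth
  f_lo <- total_force_at(params, geometry, lo, tilt_x, tilt_y, clamp_eps)
  if (f_lo < target_force)
    stop(sprintf("infeasible load: target %g exceeds attainable %g",
                 target_force, f_lo), call. = FALSE)
  hi <- z_free
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    f_mid <- total_force_at(params, geometry, mid, tilt_x, tilt_y, clamp_eps)
    if (abs(f_mid - target_force) <= tol * target_force) return(mid)
    if (f_mid > target_force) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---------------------------------------------------------------------------
# default synthetic foot

#' Build a plausible default foot (geometry + mechanical parameters)
#'
#' Constructs a synthetic but anatomically plausible foot on a regular grid:
#' zero rigid-shape clearance (contact-prone) under the heel and the
#' metatarsal-head band, a raised longitudinal arch (higher on the medial
#' side than the lateral side), light toe contact, thicker soft tissue under
#' the heel than the forefoot, and uniform stiffness.  Pixels outside the
#' plantar outline are given a large clearance so they never load.  The
#' ankle sits on the midline 15% of the foot length from the heel; the
#' second-metatarsal axis landmark sits on the midline at 78% so the
#' internal y' axis is aligned with the grid.
#'
#' @param foot_length_mm,foot_width_mm overall foot dimensions (defaults
#'   260 x 90 mm, giving a 52 x 18 grid of ~950 pixels at 5 mm cells).
#' @param side `"left"` or `"right"` (the clearance map is mirrored).
#' @param cell_size pixel edge, mm.
#' @param stiffness uniform tissue stiffness, N/cm^2.
#' @return list with elements `geometry` (a `foot_geometry`) and `params`
#'   (a `foot_model_params`).
#' @export
build_default_foot <- function(foot_length_mm = 260, foot_width_mm = 90,
                               side = "left", cell_size = 5, stiffness = 8) {
  side <- assert_side(side)
  cell_size <- assert_scalar_num(cell_size, "cell_size", positive = TRUE)
  rows <- max(1L, round(foot_length_mm / cell_size))
  cols <- max(1L, round(foot_width_mm / cell_size))
  if (rows < 8L || cols < 4L)
    stop("grid too small to contain the anatomical landmarks (< 8x4 pixels)",
         call. = FALSE)
  cc <- (cols + 1) / 2
  ankle <- c(rows + 0.5 - 0.15 * rows, cc)
  axis  <- c(rows + 0.5 - 0.78 * rows, cc)
  geometry <- build_geometry(rows, cols, ankle, axis, cell_size, side)

  # t: fraction of foot length from the heel end (heel 0, toes 1)
  # m: medial-positive transverse coordinate in units of the half width
  r <- row(matrix(0, rows, cols)); cl <- col(matrix(0, rows, cols))
  t <- (rows + 0.5 - r) / rows
  s <- if (side == "left") 1 else -1
  m <- s * (cl - cc) / (cols / 2)

  # plantar outline: medial/lateral extents as fractions of the half width
  e_med <- interp_profile(t, cbind(c(0, .12, .30, .45, .60, .75, .90, 1),
                                   c(.50, .65, .50, .38, .60, .95, .85, .55)))
  e_lat <- interp_profile(t, cbind(c(0, .12, .30, .45, .60, .75, .90, 1),
                                   c(.50, .68, .66, .62, .70, .95, .80, .50)))
  inside <- (m >= -e_lat) & (m <= e_med)

  # rigid internal shape: convex support domes under the calcaneus and the
  # five metatarsal heads (quadratic clearance growth away from each
  # center, giving the peaked footprint-like pressure zones a small central
  # sensor can represent), a low lateral midfoot band connecting heel and
  # forefoot, a light toe pad, and a clearance cap of 8 mm (the medial
  # longitudinal arch crest) everywhere inside the outline
  xmm <- (cl - cc) * cell_size          # transverse mm from the midline
  ymm <- (rows + 0.5 - r) * cell_size   # longitudinal mm from the heel end
  L <- rows * cell_size; W2 <- cols * cell_size / 2
  dome <- function(tc, uc, curv) {
    d2 <- (xmm - uc * W2 * s)^2 + (ymm - tc * L)^2
    curv * d2
  }
  supports <- list(
    dome(0.12, 0.00, 0.010),    # heel / calcaneus
    dome(0.72, 0.55, 0.015),    # 1st metatarsal head
    dome(0.78, 0.20, 0.015),    # 2nd
    dome(0.75, -0.10, 0.015),   # 3rd
    dome(0.73, -0.35, 0.015),   # 4th
    dome(0.71, -0.60, 0.015),   # 5th
    dome(0.92, 0.10, 0.012) + 2.0,  # toe pad (light contact)
    # lateral midfoot band: quadratic growth away from the heel->met5 line,
    # offset so the midfoot carries a realistic ~10% of the load
    0.025 * (xmm - (-0.45 * W2 * s) * pmin(pmax((ymm - 0.12 * L) /
                                                  (0.59 * L), 0), 1))^2 +
      ifelse(ymm > 0.12 * L & ymm < 0.71 * L, 3.5, 25)
  )
  IS <- Reduce(pmin, supports)
  IS <- pmin(IS, 8)               # medial arch crest clearance
  IS[!inside] <- 60
  IS <- matrix(pmax(IS, 0), rows, cols)

  thick <- matrix(interp_profile(t, cbind(c(0, .25, .45, .65, 1),
                                          c(15, 15, 12, 12, 10))),
                  rows, cols)
  params <- foot_model_params(IS, thick, stiffness)
  list(geometry = geometry, params = params)
}

# ---------------------------------------------------------------------------
# sway generation

#' Quiet-standing sway configuration
#'
#' Describes ~30 s of quiet standing with deliberately exaggerated
#' mediolateral and anteroposterior sway, so the postures cover the foot
#' support surface (the condition needed to learn the calibration).
#'
#' @param duration recording length, s.
#' @param frame_rate sampling rate, Hz.
#' @param ml_amplitude,ap_amplitude seat-tilt amplitudes (mm of height per
#'   mm along x'/y').
#' @param ml_period,ap_period sway periods, s.
#' @param target_total_force mean per-foot load, force units (sum of pixel
#'   pressures in N/cm^2; at 5 mm cells, 0.25 cm^2 per pixel, the default
#'   1400 corresponds to 350 N per foot, a 70 kg subject); total body load
#'   is twice this and its split between the feet oscillates with the
#'   mediolateral sway.
#' @param noise_sd multiplicative per-pixel sensor noise SD (0 disables).
#' @param seed integer seed driving all randomness (jitter and noise).
#' @return a `sway_config` object.
#' @export
sway_config <- function(duration = 30, frame_rate = 50,
                        ml_amplitude = 0.05, ap_amplitude = 0.025,
                        ml_period = 4, ap_period = 6,
                        target_total_force = 1400, noise_sd = 0.02,
                        seed = 1L) {
  cfg <- list(duration = assert_scalar_num(duration, "duration", TRUE),
              frame_rate = assert_scalar_num(frame_rate, "frame_rate", TRUE),
              ml_amplitude = assert_scalar_num(ml_amplitude, "ml_amplitude"),
              ap_amplitude = assert_scalar_num(ap_amplitude, "ap_amplitude"),
              ml_period = assert_scalar_num(ml_period, "ml_period", TRUE),
              ap_period = assert_scalar_num(ap_period, "ap_period", TRUE),
              target_total_force = assert_scalar_num(target_total_force,
                                                     "target_total_force", TRUE),
              noise_sd = assert_scalar_num(noise_sd, "noise_sd"),
              seed = as.integer(seed))
  if (cfg$ml_amplitude < 0 || cfg$ap_amplitude < 0 || cfg$noise_sd < 0)
    stop("amplitudes and noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "sway_config")
}

# seeded low-pass jitter: exponentially smoothed white noise rescaled to a
# known SD (tau = smoothing time constant in seconds)
smooth_jitter <- function(M, rate, sd_target, tau = 0.3) {
  if (sd_target <= 0) return(numeric(M))
  a <- exp(-1 / (rate * tau))
  x <- stats::rnorm(M)
  y <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  # stationary SD of the AR(1) output
  y / sqrt((1 - a)^2 / (1 - a^2)) * sd_target
}

#' Generate a two-foot quiet-standing sway recording
#'
#' Seat tilts follow sinusoids at the configured amplitudes and periods plus
#' seeded low-pass jitter; the body-weight share between the feet oscillates
#' with the mediolateral sway; each frame's ankle height is solved by
#' [solve_seat_height()] so per-foot load matches its target; optional
#' multiplicative sensor noise `1 + N(0, noise_sd)` (clipped at 0) is
#' applied per pixel.  Fully deterministic given the seed.
#'
#' @param params_L,params_R per-foot `foot_model_params`.
#' @param geometry_L,geometry_R per-foot `foot_geometry`.
#' @param sway a [sway_config()].
#' @return list with `left` and `right` `foot_recording`s and `truth`, a
#'   per-frame data frame of the simulated seats and load targets.
#' @export
generate_sway_recording <- function(params_L, params_R, geometry_L,
                                    geometry_R, sway) {
  stopifnot(inherits(sway, "sway_config"))
  M <- max(1L, round(sway$duration * sway$frame_rate))
  tt <- (seq_len(M) - 1L) / sway$frame_rate
  with_seed(sway$seed, {
    tilt_x <- sway$ml_amplitude * sin(2 * pi * tt / sway$ml_period) +
      smooth_jitter(M, sway$frame_rate, 0.15 * sway$ml_amplitude)
    tilt_y <- sway$ap_amplitude * sin(2 * pi * tt / sway$ap_period) +
      smooth_jitter(M, sway$frame_rate, 0.15 * sway$ap_amplitude)
    # weight shifts toward the loaded side as the seats tilt
    lean <- if (sway$ml_amplitude > 0)
      pmax(-1, pmin(1, tilt_x / sway$ml_amplitude)) else rep(0, M)
    share_R <- 0.5 - 0.25 * lean
    total <- 2 * sway$target_total_force
    target_R <- total * share_R
    target_L <- total - target_R

    sim_side <- function(params, geometry, targets) {
      vals <- array(0, dim = c(geometry$rows, geometry$cols, M))
      z0 <- numeric(M)
      for (i in seq_len(M)) {
        z0[i] <- solve_seat_height(params, geometry, tilt_x[i], tilt_y[i],
                                   targets[i])
        fr <- simulate_frame(params, geometry,
                             foot_seat(z0[i], tilt_x[i], tilt_y[i]))
        vals[, , i] <- fr$values
      }
      list(values = vals, z0 = z0)
    }
    L <- sim_side(params_L, geometry_L, target_L)
    R <- sim_side(params_R, geometry_R, target_R)
    if (sway$noise_sd > 0) {
      L$values <- L$values * pmax(0, 1 + stats::rnorm(length(L$values),
                                                      0, sway$noise_sd))
      R$values <- R$values * pmax(0, 1 + stats::rnorm(length(R$values),
                                                      0, sway$noise_sd))
    }
    list(left = foot_recording("left", L$values, sway$frame_rate,
                               geometry_L$cell_size),
         right = foot_recording("right", R$values, sway$frame_rate,
                                geometry_R$cell_size),
         truth = data.frame(frame = seq_len(M), time = tt,
                            tilt_x = tilt_x, tilt_y = tilt_y,
                            z0_L = L$z0, z0_R = R$z0,
                            target_F_L = target_L, target_F_R = target_R))
  })
}
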