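test_that("the compression law matches its closed form and limits", {
  expect_identical(pressure_from_compression(0, 10, 10), 0)
  expect_equal(pressure_from_compression(5, 10, 10), 10 * log(2),
               tolerance = 1e-13)
  expect_equal(pressure_from_compression(10 * (1 - exp(-1)), 10, 10), 10,
               tolerance = 1e-12)
  expect_equal(compression_from_pressure(10 * log(2), 10, 10), 5,
               tolerance = 1e-12)
  expect_identical(compression_from_pressure(0, 7, 3), 0)
  expect_error(pressure_from_compression(-1, 10, 10), ">= 0")
  expect_error(pressure_from_compression(10, 10, 10), "infinite compression")
  expect_error(pressure_from_compression(5, 10, -1), "> 0")
  expect_error(compression_from_pressure(-2, 10, 10), ">= 0")
  # strictly increasing, vanishing slope nowhere (finite differences)
  zc <- seq(0.01, 9.9, length.out = 200)
  f <- pressure_from_compression(zc, 10, 4)
  expect_true(all(diff(f) > 0))
})

test_that("compression/pressure round-trips to 1e-12 relative on random triples", {
  set.seed(101)
  n <- 1000
  thick <- runif(n, 2, 30)
  stiff <- runif(n, 1, 25)
  # keep F below ~8x stiffness: past that the tissue is numerically
  # bottomed out (exp(-F/stiff) underflows the double mantissa)
  F <- runif(n, 1e-3, 8) * stiff
  zc <- compression_from_pressure(F, thick, stiff)
  expect_true(all(zc >= 0 & zc < thick))
  back <- pressure_from_compression(zc, thick, stiff)
  expect_lt(max(abs(back - F) / F), 1e-12)
})

test_that("frame simulation follows the clearance model and is monotone", {
  geom <- tiny_geometry(rows = 8, cols = 5)
  IS <- matrix(60, 8, 5); IS[4, 3] <- 0
  params <- foot_model_params(IS, 10, 10)
  # seat high: no contact anywhere
  high <- simulate_frame(params, geom, foot_seat(12))
  expect_true(all(high$values == 0))
  # single contacting pixel at 5 mm compression reduces to the closed form
  fr <- simulate_frame(params, geom, foot_seat(5))
  expect_equal(fr$values[4, 3], 10 * log(2), tolerance = 1e-12)
  expect_equal(sum(fr$values > 0), 1L)
  expect_identical(fr$saturated, 0L)
  # deep drop saturates and reports the clamp count
  deep <- simulate_frame(params, geom, foot_seat(-55))
  expect_gt(deep$saturated, 0L)
  # lowering z0 never decreases any pixel; scaling stiffness never
  # decreases total force (random scenes)
  set.seed(5)
  for (k in 1:5) {
    IS2 <- matrix(runif(40, 0, 12), 8, 5)
    th2 <- matrix(runif(40, 6, 14), 8, 5)
    p2 <- foot_model_params(IS2, th2, 8)
    z <- runif(1, 0, 10)
    a <- simulate_frame(p2, geom, foot_seat(z))$values
    b <- simulate_frame(p2, geom, foot_seat(z - 1))$values
    expect_true(all(b >= a - 1e-12))
    p3 <- foot_model_params(IS2, th2, 16)
    c3 <- simulate_frame(p3, geom, foot_seat(z))$values
    expect_gte(sum(c3), sum(a))
  }
})

test_that("seat-height solving hits the load target and is monotone", {
  foot <- build_default_foot(side = "left")
  z_free <- solve_seat_height(foot$params, foot$geometry, 0, 0, 0)
  free <- simulate_frame(foot$params, foot$geometry, foot_seat(z_free))
  expect_true(all(free$values == 0))
  touch <- simulate_frame(foot$params, foot$geometry, foot_seat(z_free - 0.2))
  expect_gt(sum(touch$values), 0)

  z350 <- solve_seat_height(foot$params, foot$geometry, 0, 0, 350)
  f350 <- sum(simulate_frame(foot$params, foot$geometry,
                             foot_seat(z350))$values)
  expect_lt(abs(f350 - 350), 0.35)
  z700 <- solve_seat_height(foot$params, foot$geometry, 0, 0, 700)
  expect_lt(z700, z350)
  expect_error(solve_seat_height(foot$params, foot$geometry, 0, 0, 1e9),
               "infeasible load")
})

test_that("left and right feet are mirror images under mirrored tilts", {
  L <- build_default_foot(side = "left")
  R <- build_default_foot(side = "right")
  for (tx in c(-0.04, 0.02)) {
    fL <- simulate_frame(L$params, L$geometry, foot_seat(6, -tx, 0.01))
    fR <- simulate_frame(R$params, R$geometry, foot_seat(6, tx, 0.01))
    expect_equal(fR$values, fL$values[, ncol(fL$values):1],
                 tolerance = 1e-12)
  }
})

test_that("sway generation is seeded, sized, and widens mediolateral sway", {
  L <- build_default_foot(side = "left")
  R <- build_default_foot(side = "right")
  cfg <- sway_config(duration = 2, frame_rate = 50, noise_sd = 0.02,
                     seed = 9)
  a <- generate_sway_recording(L$params, R$params, L$geometry, R$geometry,
                               cfg)
  expect_equal(n_frames(a$left), 100L)
  expect_equal(n_frames(a$right), 100L)
  b <- generate_sway_recording(L$params, R$params, L$geometry, R$geometry,
                               cfg)
  expect_identical(a$left$values, b$left$values)
  expect_identical(a$right$values, b$right$values)
  expect_identical(a$truth, b$truth)

  quiet <- sway_config(duration = 4, ml_amplitude = 0, noise_sd = 0,
                       seed = 9)
  swaying <- sway_config(duration = 4, ml_amplitude = 0.05, noise_sd = 0,
                         seed = 9)
  copx_range <- function(cfg) {
    r <- generate_sway_recording(L$params, R$params, L$geometry, R$geometry,
                                 cfg)
    s <- reference_signals(r$left, L$geometry)
    diff(range(cop_from_signals(s$F, s$Mx, s$My, strict = FALSE)$x,
               na.rm = TRUE))
  }
  expect_gt(copx_range(swaying), copx_range(quiet))
})

test_that("the default foot has contact-prone support zones and a raised arch", {
  for (side in c("left", "right")) {
    foot <- build_default_foot(side = side)
    IS <- foot$params$internal_shape
    rows <- foot$geometry$rows; cols <- foot$geometry$cols
    t <- (rows + 0.5 - row(IS)) / rows
    s <- if (side == "left") 1 else -1
    m <- s * (col(IS) - (cols + 1) / 2) / (cols / 2)
    heel <- IS[t < 0.2 & abs(m) < 0.3]
    arch_med <- IS[t > 0.4 & t < 0.5 & m > 0.3 & m < 0.7]
    arch_lat <- IS[t > 0.4 & t < 0.5 & m < -0.3 & m > -0.7]
    expect_lt(min(heel), 0.5)
    expect_gt(min(arch_med), min(heel))
    expect_lt(mean(arch_lat), mean(arch_med))   # lateral arch sits lower
    # heel tissue thicker than forefoot
    expect_gt(mean(foot$params$thickness[t < 0.2]),
              mean(foot$params$thickness[t > 0.7]))
  }
  # mirror symmetry of the clearance maps
  L <- build_default_foot(side = "left")$params$internal_shape
  R <- build_default_foot(side = "right")$params$internal_shape
  expect_equal(R, L[, ncol(L):1], tolerance = 1e-12)
  expect_error(build_default_foot(30, 15, "left"), "too small")
})
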