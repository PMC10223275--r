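test_that("recording container round-trips bit-exactly and keeps header fields", {
  set.seed(3)
  vals <- random_frames(4, 3, 10)
  vals[, , 2] <- 0   # an all-zero frame is legal
  rec <- foot_recording("left", vals, frame_rate = 50, cell_size = 5)
  path <- withr::local_tempfile(fileext = ".ppm.txt")
  write_recording(rec, path)
  back <- read_recording(path, "left")
  expect_identical(back$values, rec$values)
  expect_identical(back$frame_rate, 50)
  expect_identical(back$cell_size, 5)
  expect_identical(back$side, "left")
  expect_equal(n_frames(back), 10L)
})

test_that("malformed recordings are rejected with the offending frame named", {
  expect_error(foot_recording("left", list()), ">= 1 frame")
  expect_error(foot_recording("up", list(matrix(1, 2, 2))), "left.*right")
  expect_error(foot_recording("left", list(matrix(1, 2, 2), matrix(1, 3, 2))),
               "frame 2")
  neg <- array(1, dim = c(2, 2, 3)); neg[1, 1, 2] <- -0.5
  expect_error(foot_recording("left", neg), "negative.*frame 2")

  rec <- foot_recording("right", random_frames(3, 2, 2))
  path <- withr::local_tempfile(fileext = ".ppm.txt")
  write_recording(rec, path)
  expect_error(read_recording(path, "left"), "right foot")
  # layout: 7 header lines, then blank + 3 rows per frame; line 13 is the
  # first row of frame 2 — corrupt it to a negative value, then ragged
  lines <- readLines(path)
  lines[13] <- "-1 2"
  writeLines(lines, path)
  expect_error(read_recording(path), "frame 2")
  lines[13] <- "1 2 3"
  writeLines(lines, path)
  expect_error(read_recording(path), "ragged frame 2")
  expect_error(read_recording(file.path(tempdir(), "nope.ppm.txt")),
               "no such file")
})

test_that("internal coordinates put the ankle at the origin and y' toward the axis", {
  # straight-ahead axis: 10 rows ahead of the ankle at 5 mm cells
  g <- build_geometry(12, 11, c(11, 6), c(1, 6), 5, "left")
  expect_equal(c(g$x[1, 6], g$y[1, 6]), c(0, 50))
  expect_equal(c(g$x[11, 6], g$y[11, 6]), c(0, 0))   # the ankle pixel
  # 2 columns toward the subject's right of the ankle
  expect_equal(c(g$x[11, 8], g$y[11, 8]), c(10, 0))
  # the map is rigid: pairwise distances equal cell-scaled pixel distances,
  # also for an oblique axis direction
  g2 <- build_geometry(12, 11, c(11, 6), c(3, 2), 5, "right")
  idx <- cbind(c(2, 7, 12, 5), c(3, 9, 1, 11))
  for (i in 1:3) {
    a <- idx[i, ]; b <- idx[i + 1, ]
    d_int <- sqrt((g2$x[a[1], a[2]] - g2$x[b[1], b[2]])^2 +
                    (g2$y[a[1], a[2]] - g2$y[b[1], b[2]])^2)
    d_px <- 5 * sqrt(sum((a - b)^2))
    expect_equal(d_int, d_px, tolerance = 1e-12)
  }
  expect_error(build_geometry(12, 11, c(11, 6), c(11, 6), 5, "left"),
               "coincide")
  expect_error(build_geometry(12, 11, c(13, 6), c(1, 6), 5, "left"),
               "outside the grid")
})

test_that("reference signals match a brute-force per-pixel loop and are linear", {
  set.seed(7)
  geom <- tiny_geometry(rows = 20, cols = 13, ankle_row = 15)
  A <- matrix(runif(260, 0, 5), 20, 13)
  B <- matrix(runif(260, 0, 5), 20, 13)
  recA <- foot_recording("left", list(A))
  sig <- reference_signals(recA, geom)
  # independent loop oracle
  Fo <- 0; Mxo <- 0; Myo <- 0
  for (r in 1:20) for (cc in 1:13) {
    Fo <- Fo + A[r, cc]
    Mxo <- Mxo + geom$x[r, cc] * A[r, cc]
    Myo <- Myo + geom$y[r, cc] * A[r, cc]
  }
  expect_equal(sig$F, Fo, tolerance = 1e-12)
  expect_equal(sig$Mx, Mxo, tolerance = 1e-12)
  expect_equal(sig$My, Myo, tolerance = 1e-12)
  # linearity in the frame
  sAB <- reference_signals(foot_recording("left", list(2 * A + 3 * B)), geom)
  sB <- reference_signals(foot_recording("left", list(B)), geom)
  expect_equal(sAB$F, 2 * sig$F + 3 * sB$F, tolerance = 1e-10)
  expect_equal(sAB$Mx, 2 * sig$Mx + 3 * sB$Mx, tolerance = 1e-10)
  expect_equal(sAB$My, 2 * sig$My + 3 * sB$My, tolerance = 1e-10)
  # single loaded pixel: F = 2 at (x', y') = (30, 40)
  one <- matrix(0, 20, 13)
  pick <- which(abs(geom$x - 30) < 1e-9 & abs(geom$y - 40) < 1e-9)
  one[pick] <- 2
  s1 <- reference_signals(foot_recording("left", list(one)), geom)
  expect_equal(c(s1$F, s1$Mx, s1$My), c(2, 60, 80))
  expect_error(reference_signals(recA, tiny_geometry(rows = 5, cols = 5)),
               "does not match")
})

test_that("CoP is the pressure-weighted barycenter, shifts with the origin, and guards low force", {
  set.seed(21)
  geom <- tiny_geometry(rows = 15, cols = 8, ankle_row = 12)
  for (k in 1:20) {
    fr <- matrix(runif(120, 0, 3), 15, 8)
    s <- reference_signals(foot_recording("left", list(fr)), geom)
    cop <- cop_from_signals(s$F, s$Mx, s$My)
    bx <- sum(geom$x * fr) / sum(fr); by <- sum(geom$y * fr) / sum(fr)
    expect_lt(abs(cop$x - bx), 1e-9)
    expect_lt(abs(cop$y - by), 1e-9)
    # inside the bounding box of the loaded pixels
    expect_gte(cop$x, min(geom$x[fr > 0])); expect_lte(cop$x, max(geom$x[fr > 0]))
    expect_gte(cop$y, min(geom$y[fr > 0])); expect_lte(cop$y, max(geom$y[fr > 0]))
  }
  # translation covariance: moving the ankle moves the CoP by the offset
  fr <- matrix(runif(120, 0, 3), 15, 8)
  g2 <- build_geometry(15, 8, c(10, 2), c(1, 2), 5, "left")
  s1 <- reference_signals(foot_recording("left", list(fr)), geom)
  s2 <- reference_signals(foot_recording("left", list(fr)), g2)
  c1 <- cop_from_signals(s1$F, s1$Mx, s1$My)
  c2 <- cop_from_signals(s2$F, s2$Mx, s2$My)
  expect_equal(c2$x - c1$x, g2$x[1, 1] - geom$x[1, 1], tolerance = 1e-9)
  expect_equal(c2$y - c1$y, g2$y[1, 1] - geom$y[1, 1], tolerance = 1e-9)
  # degenerate frames
  expect_error(cop_from_signals(0, 0, 0), "frame\\(s\\) 1")
  flagged <- cop_from_signals(c(5, 0.2), c(10, 1), c(10, 1), strict = FALSE)
  expect_identical(flagged$defined, c(TRUE, FALSE))
  expect_true(is.na(flagged$x[2]))
  # uniform pressure on a symmetric grid centers on the grid centroid
  u <- matrix(1, 15, 8)
  su <- reference_signals(foot_recording("left", list(u)), geom)
  cu <- cop_from_signals(su$F, su$Mx, su$My)
  expect_equal(cu$x, mean(geom$x), tolerance = 1e-9)
  expect_equal(cu$y, mean(geom$y), tolerance = 1e-9)
})
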