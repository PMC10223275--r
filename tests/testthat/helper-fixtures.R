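# Shared fixtures, all generated in code.

# grid-aligned geometry: ankle near the heel on the midline column, axis
# straight ahead, so x' = (col - ankle_col) * cell and
# y' = (ankle_row - row) * cell
tiny_geometry <- function(rows = 10, cols = 6, side = "left", cell = 5,
                          ankle_row = rows - 1) {
  mid <- ceiling(cols / 2)
  build_geometry(rows, cols, c(ankle_row, mid), c(1, mid), cell, side)
}

random_frames <- function(rows, cols, M, scale = 5) {
  array(stats::runif(rows * cols * M, 0, scale), dim = c(rows, cols, M))
}

# recording whose references are EXACT linear forms of the sensor readings:
# all pressure lives inside three disjoint windows, uniform within each
# window per frame, so F/Mx/My are exact weighted sums of the readings
uniform_window_fixture <- function(M = 40, side = "left", seed = 11) {
  set.seed(seed)
  geom <- tiny_geometry(rows = 12, cols = 9, side = side)
  sensors <- list(sensor(c(10, 5), 3, "heel"),
                  sensor(c(3, 2), 3, "custom"),
                  sensor(c(3, 8), 3, "custom"))
  layout <- sensor_layout(side, sensors)
  vals <- array(0, dim = c(12, 9, M))
  for (i in seq_len(M)) {
    for (s in sensors) {
      h <- (s$size_pixels - 1) / 2
      rw <- (s$center_pixel[1] - h):(s$center_pixel[1] + h)
      cl <- (s$center_pixel[2] - h):(s$center_pixel[2] + h)
      vals[rw, cl, i] <- stats::runif(1, 0.5, 4)
    }
  }
  rec <- foot_recording(side, vals)
  list(recording = rec, geometry = geom, layout = layout,
       references = reference_signals(rec, geom),
       signals = extract_signals(rec, layout))
}

# memoised default two-foot study (the heavy 30 s x 50 Hz generation),
# shared across test files within one run
.study_cache <- new.env(parent = emptyenv())
default_study <- function(seed = 42) {
  key <- paste0("s", seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  feet_L <- build_default_foot(side = "left")
  feet_R <- build_default_foot(side = "right")
  rec <- generate_sway_recording(feet_L$params, feet_R$params,
                                 feet_L$geometry, feet_R$geometry,
                                 sway_config(seed = seed))
  out <- list(rec = rec, geom_L = feet_L$geometry, geom_R = feet_R$geometry,
              params_L = feet_L$params, params_R = feet_R$params)
  .study_cache[[key]] <- out
  out
}
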