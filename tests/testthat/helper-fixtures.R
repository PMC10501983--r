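# Shared fixture builders. Everything is generated in code; no stored
# image data.

# radiograph whose rows have constant left/right flank intensities
# around a vertical edge at column `edge_x`; used to drive
# scan_profile with exactly known L and R values
flank_radiograph <- function(left_vals, right_vals, edge_x = 50, width = 100) {
  stopifnot(length(left_vals) == length(right_vals))
  h <- length(left_vals)
  px <- matrix(0, h, width)
  for (i in seq_len(h)) {
    px[i, 1:edge_x] <- left_vals[i]
    px[i, (edge_x + 1):width] <- right_vals[i]
  }
  radiograph(px)
}

# a minimal fitted-edge object for a vertical line at x = edge_x
vertical_edge <- function(edge_x, y_min, y_max) {
  list(group = list(pixels = data.frame(x = edge_x, y = y_min:y_max)),
       line = list(degree = 1L, coeffs = c(edge_x, 0), mse = 0),
       curve = list(degree = 2L, coeffs = c(edge_x, 0, 0), mse = 0),
       side = "left", unit = 1L, y_min = y_min, y_max = y_max)
}

# edge map from 0-based pixel coordinates
edge_map_from_points <- function(x, y, width, height) {
  m <- matrix(0L, height, width)
  m[cbind(y + 1, x + 1)] <- 1L
  edge_map(m)
}

# standard easy phantom plus jitter-free detections
quick_phantom <- function(seed = 1, defect = 0.2, jaw = "lower", ...) {
  sp <- phantom_spec(jaw = jaw, defect_fraction = defect, seed = seed, ...)
  ph <- render_phantom(sp)
  d <- emit_detections(ph$truth, jitter = 0, seed = seed + 1000L)
  list(spec = sp, phantom = ph, detections = d)
}

expect_both_within <- function(pair, truth_edge, tol = 3) {
  expect_identical(pair$status, "both")
  expect_lt(sqrt((pair$first$x - truth_edge$first["x"])^2 +
                 (pair$first$y - truth_edge$first["y"])^2), tol)
  expect_lt(sqrt((pair$second$x - truth_edge$second["x"])^2 +
                 (pair$second$y - truth_edge$second["y"])^2), tol)
}
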