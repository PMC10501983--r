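test_that("a vertical line accumulates at theta = 0, rho = x", {
  em <- edge_map_from_points(rep(50, 100), 0:99, 100, 100)
  lines <- hough_accumulate(em)
  expect_equal(lines$theta[1], 0)
  expect_equal(lines$rho[1], 50)
  expect_equal(lines$votes[1], 100)
  expect_true(lines$vertical[1])
})

test_that("two orthogonal ideal lines produce two matching top peaks", {
  em <- edge_map_from_points(c(rep(30, 60), 0:59), c(0:59, rep(20, 60)),
                             64, 64)
  lines <- hough_accumulate(em, n_peaks = 4)
  top2 <- lines[1:2, ]
  # vertical x = 30 -> (rho 30, theta 0); horizontal y = 20 -> (20, 90)
  # or equivalently (-20, -90); accept within bin resolution
  has_v <- any(abs(top2$rho - 30) <= 1 & abs(top2$theta) <= 1)
  has_h <- any(abs(abs(top2$rho) - 20) <= 1 & abs(abs(top2$theta) - 90) <= 1)
  expect_true(has_v)
  expect_true(has_h)
})

test_that("sparse maps yield no peaks above the vote floor", {
  em <- edge_map_from_points(c(5, 40), c(7, 12), 64, 64)
  lines <- hough_accumulate(em, min_votes = 15)
  expect_equal(nrow(lines), 0)
  expect_error(hough_accumulate(edge_map(matrix(0L, 10, 10))),
               class = "mbl_description_error")
})

test_that("slope-intercept conversion satisfies the polar line equation", {
  sl <- hough_to_slope_intercept(5, 90)
  expect_equal(sl$m, 0)
  expect_equal(sl$d, 5)

  sl45 <- hough_to_slope_intercept(sqrt(2), 45)
  expect_equal(sl45$m, -1, tolerance = 1e-12)
  expect_equal(sl45$d, 2, tolerance = 1e-12)

  expect_true(hough_to_slope_intercept(17, 0)$vertical)

  # round trip: points generated on y = m x + d satisfy
  # rho = x cos(theta) + y sin(theta) to 1e-9
  set.seed(4)
  for (k in 1:25) {
    theta <- runif(1, -89, 89)
    if (abs(theta) < 1) theta <- theta + 5
    rho <- runif(1, -80, 80)
    sl <- hough_to_slope_intercept(rho, theta)
    x <- runif(50, -100, 100)
    y <- sl$m * x + sl$d
    th <- theta * pi / 180
    expect_lt(max(abs(x * cos(th) + y * sin(th) - rho)), 1e-9)
  }
})

test_that("slope filtering discards lines under 30 degrees from horizontal", {
  lines <- data.frame(rho = c(1, 2, 3), theta = c(45, 63.43, 0),
                      votes = c(10, 10, 10),
                      vertical = c(FALSE, FALSE, TRUE),
                      m = c(1, 0.5, NA), d = c(0, 0, NA))
  kept <- filter_by_slope(lines)
  expect_equal(kept$m[!kept$vertical], 1)     # atan(0.5) = 26.6 deg dropped
  expect_true(any(kept$vertical))             # vertical = 90 deg retained
})

test_that("segment extraction keeps banded pixels and drops strays", {
  em <- edge_map_from_points(rep(50, 80), 0:79, 100, 100)
  lines <- hough_accumulate(em)
  segs <- extract_segments(em, lines[1, ])
  expect_equal(sum(segs), 80)

  em2 <- edge_map_from_points(c(rep(50, 80), rep(57, 12)),
                              c(0:79, seq(5, 60, 5)), 100, 100)
  segs2 <- extract_segments(em2, lines[1, ])
  pts <- which(segs2 != 0, arr.ind = TRUE)
  expect_true(all(pts[, 2] - 1 == 50))        # 7 px away: removed

  # a curved edge is covered piecewise by several lines
  ys <- 0:199
  xs <- round(60 + 0.15 * ys + 0.0008 * ys^2)
  emc <- edge_map_from_points(xs, ys, 150, 220)
  lc <- filter_by_slope(hough_accumulate(emc, n_peaks = 16, min_votes = 10))
  segc <- extract_segments(emc, lc)
  expect_gte(sum(segc) / length(ys), 0.95)
})

test_that("grouping labels alignments and merges across small offsets", {
  # two parallel chains 20 px apart stay separate
  em <- edge_map_from_points(c(rep(30, 60), rep(50, 60)),
                             c(0:59, 0:59), 80, 80)
  g2 <- group_and_label(em, em, min_group_px = 10)
  expect_length(g2, 2)

  # collinear chains with a 3 px horizontal offset merge through the
  # 1x5 dilation
  em3 <- edge_map_from_points(c(rep(30, 40), rep(33, 40)),
                              c(0:39, 40:79), 80, 80)
  g1 <- group_and_label(em3, em3, min_group_px = 10)
  expect_length(g1, 1)
  expect_equal(g1[[1]]$y_min, 0)
  expect_equal(g1[[1]]$y_max, 79)

  # an isolated blob below the size floor is dropped
  em4 <- edge_map_from_points(c(rep(30, 60), 70, 71),
                              c(0:59, 10, 10), 80, 80)
  g4 <- group_and_label(em4, em4, min_group_px = 10)
  expect_length(g4, 1)

  expect_error(group_and_label(edge_map(matrix(0L, 5, 5)),
                               edge_map(matrix(0L, 5, 5))),
               class = "mbl_description_error")
})

test_that("polynomial fits recover exact generating coefficients", {
  g_lin <- list(pixels = data.frame(y = 0:50, x = 10 + 0.1 * (0:50)))
  f1 <- fit_edge(g_lin, 1)
  expect_equal(f1$coeffs, c(10, 0.1), tolerance = 1e-9)
  expect_equal(f1$mse, 0, tolerance = 1e-12)

  g_par <- list(pixels = data.frame(y = 0:80, x = 5 + 0.2 * (0:80) +
                                      0.001 * (0:80)^2))
  f2 <- fit_edge(g_par, 2)
  expect_equal(f2$coeffs, c(5, 0.2, 0.001), tolerance = 1e-6)
  expect_lt(f2$mse, 1e-12)
  expect_gt(fit_edge(g_par, 1)$mse, 0)

  expect_error(fit_edge(list(pixels = data.frame(y = rep(3, 10), x = 1:10)), 2),
               "rank-deficient")
  expect_error(fit_edge(list(pixels = data.frame(y = 1:2, x = 1:2)), 2),
               "pixels")
})

test_that("degree selection minimizes MSE with ties toward low degree", {
  g_lin <- list(pixels = data.frame(y = 0:50, x = 10 + 0.1 * (0:50)))
  expect_equal(select_degree(g_lin)$degree, 1)

  g_par <- list(pixels = data.frame(y = 0:80, x = 5 + 0.2 * (0:80) +
                                      0.002 * (0:80)^2))
  expect_equal(select_degree(g_par)$degree, 2)

  # noisy parabola: degree 2 must win in nearly all replicates
  set.seed(9)
  wins <- 0L
  for (k in 1:20) {
    y <- seq(0, 199, length.out = 200)
    x <- 5 + 0.2 * y + 0.001 * y^2 + rnorm(200, sd = 0.5)
    if (select_degree(list(pixels = data.frame(x = x, y = y)))$degree == 2)
      wins <- wins + 1L
  }
  expect_gte(wins, 18)
})

test_that("describe_edges yields one fitted edge per screw side on phantoms", {
  qp <- quick_phantom(seed = 31)
  units <- associate_implants(qp$detections)
  enh <- enhance_gamma(qp$phantom$radiograph, 1.5)
  roi <- screw_roi_edges(canny_edges(enh), units)
  edges <- describe_edges(roi, units)
  expect_length(edges, 2)
  expect_setequal(vapply(edges, `[[`, character(1), "side"),
                  c("left", "right"))
  for (e in edges) {
    te <- qp$phantom$truth$implants[[1]]$edges[[e$side]]
    ys <- seq(max(e$y_min, te$y_min) + 5, min(e$y_max, te$y_max) - 5)
    dev <- abs(eval_poly(e$curve, ys) -
               eval_poly(list(coeffs = te$coeffs), ys))
    expect_lt(mean(dev), 2)
  }
})
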