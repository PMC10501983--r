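test_that("rendering is deterministic and truth matches the construction", {
  sp <- phantom_spec(defect_fraction = 0.2, seed = 9)
  a <- render_phantom(sp)
  b <- render_phantom(sp)
  expect_identical(a$radiograph$pixels, b$radiograph$pixels)

  tr <- a$truth$implants[[1]]
  for (side in c("left", "right")) {
    expect_equal(tr$edges[[side]]$resorption_pct, 20)
    # the defect apex lies a fifth of the way down from the junction
    span <- tr$edges[[side]]$y_max - tr$edges[[side]]$y_min
    expect_equal(tr$edges[[side]]$first[["y"]] - tr$edges[[side]]$y_min,
                 0.2 * span, tolerance = 1)
    expect_equal(tr$edges[[side]]$second[["y"]], tr$edges[[side]]$y_min)
  }

  zero <- render_phantom(phantom_spec(defect_fraction = 0, seed = 9))
  expect_null(zero$truth$implants[[1]]$edges$left$first)
  expect_equal(zero$truth$implants[[1]]$edges$left$resorption_pct, 0)

  expect_error(phantom_spec(defect_fraction = 1.2), "0, 1")
  expect_error(phantom_spec(length_px = 400), "exceeds")
})

test_that("phantom intensities follow the clinical brightness ordering", {
  sp <- phantom_spec(defect_fraction = 0.3, noise_sd = 0, texture_sd = 0,
                     seed = 2)
  ph <- render_phantom(sp)
  px <- ph$radiograph$pixels
  tr <- ph$truth$implants[[1]]
  sb <- tr$screw_box; cb <- tr$crown_box
  screw_mid <- px[round(sb$y + sb$h / 2) + 1, round(sb$x + sb$w / 2) + 1]
  crown_mid <- px[round(cb$y + cb$h / 2) + 1, round(cb$x + cb$w / 2) + 1]
  expect_gte(crown_mid, screw_mid)
  expect_gt(screw_mid, sp$intensity$bone)
})

test_that("noise-free edges lie on the stored truth polynomials", {
  for (amp in c(0, 2)) {
    sp <- phantom_spec(defect_fraction = 0.2, noise_sd = 0, texture_sd = 0,
                       thread_amplitude = amp, seed = 3)
    ph <- render_phantom(sp)
    em <- canny_edges(enhance_gamma(ph$radiograph, 1.5))
    pts <- which(em != 0, arr.ind = TRUE)
    px <- pts[, 2] - 1; py <- pts[, 1] - 1
    # smooth edges must be within 1.5 px of the stored polynomial;
    # threaded edges within the thread amplitude plus rounding
    tol <- if (amp == 0) 1.5 else amp + 0.75
    for (side in c("left", "right")) {
      te <- ph$truth$implants[[1]]$edges[[side]]
      ys <- (te$y_min + 3):(te$y_max - 3)
      # pixel accuracy: detected pixels near the edge hug the truth
      sel <- py %in% ys
      d <- abs(px[sel] - eval_poly(list(coeffs = te$coeffs), py[sel]))
      expect_gte(mean(d[d <= 6] <= tol), 0.95)
      # coverage: the chain has no holes wider than a couple of rows
      cov <- vapply(ys, function(y) {
        cand <- px[abs(py - y) <= 2]
        length(cand) > 0 &&
          min(abs(cand - eval_poly(list(coeffs = te$coeffs), y))) <= tol
      }, logical(1))
      expect_gte(mean(cov), 0.95)
    }
  }
})

test_that("the Cum profile steps down at the defect apex", {
  sp <- phantom_spec(defect_fraction = 0.3, seed = 6)
  ph <- render_phantom(sp)
  te <- ph$truth$implants[[1]]$edges$left
  edge <- list(line = list(degree = 1L,
                           coeffs = c(eval_poly(list(coeffs = te$coeffs),
                                                te$y_max), 0)),
               curve = list(degree = 2L, coeffs = te$coeffs),
               y_min = te$y_min, y_max = te$y_max)
  scan <- scan_profile(ph$radiograph, edge, "lower")
  y_def <- te$first[["y"]]
  above <- scan$cum[scan$y > y_def + 3]       # apical side: healthy bone
  below <- scan$cum[scan$y < y_def - 3]       # coronal side: defect
  gap_cfg <- sp$intensity$bone - sp$intensity$defect
  expect_gte(mean(above) - mean(below), gap_cfg - 4 * sp$noise_sd)
})

test_that("emitted detections respect jitter bounds and the score range", {
  ph <- render_phantom(phantom_spec(seed = 5))
  d0 <- emit_detections(ph$truth, jitter = 0, seed = 1)
  tr <- ph$truth$implants[[1]]
  s0 <- d0$boxes[d0$boxes$label == "screw", ]
  expect_equal(s0$x, tr$screw_box$x)
  expect_equal(s0$w, tr$screw_box$w)

  d5 <- emit_detections(ph$truth, jitter = 5, score_range = c(0.6, 0.8),
                        seed = 2)
  s5 <- d5$boxes[d5$boxes$label == "screw", ]
  expect_lte(abs(s5$x - tr$screw_box$x), 5)
  expect_lte(abs(s5$y - tr$screw_box$y), 5)
  expect_lte(abs((s5$x + s5$w) - (tr$screw_box$x + tr$screw_box$w)), 5)
  expect_true(all(d5$boxes$score >= 0.6 & d5$boxes$score <= 0.8))

  # low scores are dropped at read time by the strict 0.5 gate
  f <- tempfile(fileext = ".json")
  set.seed(4)
  emit_detections(ph$truth, jitter = 0, score_range = c(0.3, 0.6),
                  path = f, seed = 3)
  d <- read_detections(f)
  expect_lt(nrow(d$boxes), 2 * length(ph$truth$implants) + 1)
})

test_that("suites are reproducible and difficulty presets hold", {
  d1 <- file.path(tempdir(), "suiteA"); d2 <- file.path(tempdir(), "suiteB")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_suite(2, seed = 3, difficulty = "easy", out_dir = d1)
  m2 <- make_suite(2, seed = 3, difficulty = "easy", out_dir = d2)
  expect_equal(nrow(m1), 2)
  for (k in 1:2) {
    expect_identical(unname(tools::md5sum(m1$image[k])),
                     unname(tools::md5sum(m2$image[k])))
    expect_identical(readLines(m1$detections[k]), readLines(m2$detections[k]))
    expect_identical(readLines(m1$truth[k]), readLines(m2$truth[k]))
  }

  # easy phantoms are high contrast, low_contrast ones are flagged
  for (k in 1:2) {
    r <- read_image(m1$image[k])
    d <- read_detections(m1$detections[k], image_width = 410,
                         image_height = 340)
    q <- contrast_quality(r, associate_implants(d))
    expect_true(q$high_contrast)
  }
  d3 <- file.path(tempdir(), "suiteC")
  unlink(d3, recursive = TRUE)
  m3 <- make_suite(2, seed = 4, difficulty = "low_contrast", out_dir = d3)
  for (k in 1:2) {
    r <- read_image(m3$image[k])
    d <- read_detections(m3$detections[k], image_width = 410,
                         image_height = 340)
    q <- contrast_quality(r, associate_implants(d))
    expect_lt(q$sigma_norm, 0.4)
  }

  # truth files round-trip through JSON
  tr <- read_truth(m1$truth[1])
  expect_equal(tr$jaw, "lower")
  expect_length(tr$implants[[1]]$edges$left$coeffs, 3)
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("rotated suites stay within the clinical inclination range", {
  d <- file.path(tempdir(), "suiteR")
  unlink(d, recursive = TRUE)
  m <- make_suite(3, seed = 11, difficulty = "rotated", out_dir = d)
  expect_true(all(abs(m$rotation) <= 10))
  expect_gt(max(abs(m$rotation)), 0)
  unlink(d, recursive = TRUE)
})
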