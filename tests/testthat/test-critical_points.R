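test_that("the accumulated profile always takes the darker flank", {
  set.seed(13)
  for (k in 1:10) {
    n <- 40
    L <- runif(n, 10, 240)
    R <- runif(n, 10, 240)
    r <- flank_radiograph(L, R)
    edge <- vertical_edge(50, 0, n - 1)
    scan <- scan_profile(r, edge, "upper")     # traverses y increasing
    expect_equal(scan$L, L, tolerance = 1e-9)
    expect_equal(scan$R, R, tolerance = 1e-9)
    expect_equal(scan$cum, pmin(L, R), tolerance = 1e-9)
  }
  # ties follow the else branch (cum = R), which equals the min anyway
  r <- flank_radiograph(rep(90, 20), rep(90, 20))
  scan <- scan_profile(r, vertical_edge(50, 0, 19), "upper")
  expect_equal(scan$cum, scan$R)
})

test_that("scan traversal starts at the apical end and spans the group", {
  L <- seq(60, 250, length.out = 30)
  r <- flank_radiograph(L, rev(L))
  edge <- vertical_edge(50, 0, 29)
  lower <- scan_profile(r, edge, "lower")
  upper <- scan_profile(r, edge, "upper")
  expect_equal(nrow(lower), 30)               # y_max - y_min + 1
  expect_equal(lower$y, 29:0)
  expect_equal(upper$y, 0:29)
  expect_error(scan_profile(r, vertical_edge(500, 0, 29), "lower"),
               class = "mbl_scan_error")
})

test_that("the first critical point marks the persistent drop of the profile", {
  # the worked two-level profile: 10 bright then 10 dark samples
  r <- flank_radiograph(rep(c(120, 60), c(10, 10)), rep(255, 20))
  edge <- vertical_edge(50, 0, 19)
  scan <- scan_profile(r, edge, "upper")
  fp <- first_critical_point(scan, edge)
  expect_equal(fp$p, 10)
  expect_equal(fp$y, 10)
  expect_equal(fp$x, 50)

  # flat profile: no resorption, no point
  rf <- flank_radiograph(rep(120, 40), rep(255, 40))
  scf <- scan_profile(rf, vertical_edge(50, 0, 39), "upper")
  expect_null(first_critical_point(scf, edge))

  # a short dip does not satisfy the persistence rule
  Ld <- rep(120, 40); Ld[15:16] <- 60
  rd <- flank_radiograph(Ld, rep(255, 40))
  scd <- scan_profile(rd, vertical_edge(50, 0, 39), "upper")
  expect_null(first_critical_point(scd, edge, persist = 3))

  # a shallow dark band is skipped in favour of the deep drop
  Lt <- c(rep(120, 20), rep(85, 5), rep(120, 20), rep(60, 35))
  rt <- flank_radiograph(Lt, rep(255, 80))
  sct <- scan_profile(rt, vertical_edge(50, 0, 79), "upper")
  ft <- first_critical_point(sct, edge)
  expect_equal(ft$p, 45)
})

test_that("the reference level averages the five profile values after the drop", {
  cum <- c(rep(120, 10), 60, 62, 58, 60, 60, 59)
  scan <- data.frame(step = 0:15, y = 0:15, x = 50, L = cum, R = 255,
                     D = cum - 255, cum = cum)
  expect_equal(reference_level(scan, p = 9), mean(c(60, 62, 58, 60, 60)))
  expect_equal(reference_level(data.frame(step = 0:9, cum = rep(50, 10)), 4),
               50)
  expect_error(reference_level(scan, p = 12), class = "mbl_scan_error")
})

test_that("crown entry needs a 5-run above the reference level", {
  # profile 65,70 after the first point; the crown brightening lies
  # beyond the fitted span and is reached by the coronal extension
  L <- c(rep(120, 10), rep(60, 5), 65, 70, 200, 210, 220, 230, 240)
  r <- flank_radiograph(L, rep(255, length(L)))
  edge <- vertical_edge(50, 0, 16)           # group ends before the crown
  scan <- scan_profile(r, edge, "upper")
  fp <- first_critical_point(scan, edge)
  expect_equal(fp$p, 10)
  r_av <- reference_level(scan, fp$p)
  sp <- second_critical_point(r, edge, scan, fp$p, r_av, extend_px = 60)
  expect_equal(sp$y, 17)                     # first sample of the 200+ run
  expect_gt(sp$p, fp$p)

  # never exceeding the reference: no second point
  L2 <- c(rep(120, 10), rep(60, 20))
  r2 <- flank_radiograph(L2, rep(255, 30))
  s2 <- scan_profile(r2, edge2 <- vertical_edge(50, 0, 29), "upper")
  f2 <- first_critical_point(s2, edge2)
  expect_null(second_critical_point(r2, edge2, s2, f2$p,
                                    reference_level(s2, f2$p),
                                    extend_px = 0))

  # a bright run of only 4 samples at the scan tail is insufficient
  L3 <- c(rep(120, 10), rep(60, 10), rep(200, 4))
  r3 <- flank_radiograph(L3, rep(255, 24))
  s3 <- scan_profile(r3, edge3 <- vertical_edge(50, 0, 23), "upper")
  f3 <- first_critical_point(s3, edge3)
  expect_null(second_critical_point(r3, edge3, s3, f3$p,
                                    reference_level(s3, f3$p),
                                    extend_px = 0))
})

test_that("detected pairs sit on the phantom ground truth", {
  qp <- quick_phantom(seed = 41, defect = 0.25)
  rep <- analyze(qp$phantom$radiograph, qp$detections)
  expect_equal(nrow(rep$edges), 2)
  for (j in 1:2) {
    row <- rep$edges[j, ]
    te <- qp$phantom$truth$implants[[1]]$edges[[row$side]]
    expect_identical(row$status, "both")
    expect_lt(abs(row$y_first - te$first["y"]), 3)
    expect_lt(abs(row$y_second - te$second["y"]), 3)
    expect_lt(abs(row$percentage - te$resorption_pct), 5)
  }
})

test_that("zero-defect edges report no critical points", {
  qp <- quick_phantom(seed = 43, defect = 0)
  rep <- analyze(qp$phantom$radiograph, qp$detections)
  expect_true(all(rep$edges$status == "none"))
  expect_true(rep$summary$no_resorption)
})

test_that("crown verification downgrades a point outside every crown box", {
  qp <- quick_phantom(seed = 45, defect = 0.2)
  units <- associate_implants(qp$detections)
  enh <- enhance_gamma(qp$phantom$radiograph, 1.5)
  roi <- screw_roi_edges(canny_edges(enh), units)
  edges <- describe_edges(roi, units)
  # a displaced crown box: the second point cannot fall inside it
  fake <- data.frame(x = 5, y = 300, w = 10, h = 10)
  expect_warning(
    pair <- detect_edge_critical_pair(enh, edges[[1]], "lower",
                                      crowns = fake, verify_crown = TRUE),
    "downgraded")
  expect_identical(pair$status, "first_only")
})

test_that("critical points mirror exactly under a vertical flip", {
  for (s in c(51, 52)) {
    lo <- quick_phantom(seed = s, defect = 0.25, jaw = "lower")
    up <- quick_phantom(seed = s, defect = 0.25, jaw = "upper")
    H <- lo$phantom$radiograph$height
    expect_identical(lo$phantom$radiograph$pixels[H:1, ],
                     up$phantom$radiograph$pixels)
    rl <- analyze(lo$phantom$radiograph, lo$detections)
    ru <- analyze(up$phantom$radiograph, up$detections)
    for (side in c("left", "right")) {
      a <- rl$edges[rl$edges$side == side, ]
      b <- ru$edges[ru$edges$side == side, ]
      expect_lte(abs(a$y_first - (H - 1 - b$y_first)), 1)
      expect_lte(abs(a$y_second - (H - 1 - b$y_second)), 1)
    }
  }
})

test_that("the first critical point always precedes the second in traversal", {
  set.seed(17)
  for (s in 61:66) {
    qp <- quick_phantom(seed = s, defect = runif(1, 0.15, 0.45))
    units <- associate_implants(qp$detections)
    enh <- enhance_gamma(qp$phantom$radiograph, 1.5)
    roi <- screw_roi_edges(canny_edges(enh), units)
    crowns <- qp$detections$boxes[qp$detections$boxes$label == "crown", ]
    for (e in describe_edges(roi, units)) {
      pair <- detect_edge_critical_pair(enh, e, "lower", crowns = crowns)
      if (identical(pair$status, "both"))
        expect_lt(pair$first$p, pair$second$p)
    }
  }
})
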