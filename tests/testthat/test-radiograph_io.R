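test_that("images round-trip through PNG and collapse colour to one channel", {
  px <- matrix(rep(0:255, length.out = 60 * 40), 40, 60)
  r <- radiograph(px)
  f <- tempfile(fileext = ".png")
  write_image(r, f)
  r2 <- read_image(f)
  expect_equal(r2$width, 60)
  expect_equal(r2$height, 40)
  expect_equal(r2$pixels, px, tolerance = 1e-6)

  # RGB input collapses to a single channel of the same size
  arr <- array(runif(20 * 30 * 3), dim = c(20, 30, 3))
  frgb <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), frgb)
  rc <- read_image(frgb)
  expect_equal(rc$width, 20)
  expect_equal(rc$height, 30)
  expect_true(is.matrix(rc$pixels))

  fe <- tempfile(fileext = ".png")
  file.create(fe)
  expect_error(read_image(fe), "empty")
  expect_error(read_image(tempfile(fileext = ".png")), "not found")
})

test_that("radiograph constructor enforces its invariants", {
  expect_error(radiograph(matrix(-1, 2, 2)), "0, 255")
  expect_error(radiograph(matrix(1, 2, 2), mm_per_px = 0), "positive")
  expect_error(radiograph("no"), "matrix")
})

test_that("bicubic resize: no-op, constants, and standardization", {
  px <- matrix(runif(50 * 40, 0, 255), 40, 50)
  r <- radiograph(px)
  expect_equal(resize_to_standard(r, 50, 40)$pixels, px)

  rc <- radiograph(matrix(77, 30, 20))
  out <- resize_to_standard(rc, 55, 44)
  expect_equal(dim(out$pixels), c(44, 55))
  expect_equal(max(abs(out$pixels - 77)), 0, tolerance = 1e-9)

  big <- radiograph(matrix(runif(876 * 1164, 0, 255), 876, 1164))
  std <- resize_to_standard(big, 410, 340)
  expect_equal(std$width, 410)
  expect_equal(std$height, 340)
  expect_true(all(std$pixels >= 0 & std$pixels <= 255))
})

test_that("box scaling preserves relative centre positions through a resize", {
  set.seed(11)
  w <- 820; h <- 680
  boxes <- data.frame(label = "screw",
                      x = runif(20, 0, w - 80), y = runif(20, 0, h - 80),
                      w = runif(20, 20, 80), h = runif(20, 20, 80),
                      score = 1)
  sx <- 410 / w; sy <- 340 / h
  sc <- scale_boxes(boxes, sx, sy)
  cx_rel <- (boxes$x + boxes$w / 2) / w
  cx_rel2 <- (sc$x + sc$w / 2) / 410
  expect_lt(max(abs(cx_rel - cx_rel2)) * 410, 1)
  cy_rel <- (boxes$y + boxes$h / 2) / h
  cy_rel2 <- (sc$y + sc$h / 2) / 340
  expect_lt(max(abs(cy_rel - cy_rel2)) * 340, 1)
})

test_that("JSON detections: score gate is strict and round-trips are exact", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    image = "a.png",
    boxes = list(
      list(label = "screw", x = 10, y = 20, w = 30, h = 40, score = 0.9),
      list(label = "crown", x = 10, y = 2, w = 30, h = 10, score = 0.3),
      list(label = "crown", x = 12, y = 3, w = 30, h = 10, score = 0.5))),
    f, auto_unbox = TRUE)
  d <- read_detections(f)
  expect_equal(nrow(d$boxes), 1)          # 0.3 and the boundary 0.5 dropped
  expect_equal(d$boxes$label, "screw")
  expect_identical(d$jaw, "unknown")      # no crown survived

  fe <- tempfile(fileext = ".json")
  jsonlite::write_json(list(image = "b.png", boxes = list()), fe,
                       auto_unbox = TRUE)
  de <- read_detections(fe)
  expect_equal(nrow(de$boxes), 0)
  expect_identical(de$jaw, "unknown")

  fb <- tempfile(fileext = ".json")
  jsonlite::write_json(list(boxes = list(
    list(label = "tooth", x = 1, y = 1, w = 5, h = 5, score = 0.9))),
    fb, auto_unbox = TRUE)
  expect_error(read_detections(fb), "unknown label")

  # write -> read preserves the box table bit-exactly
  d0 <- detection_set(rbind(
    bounding_box("screw", 100, 120, 40, 110, 0.93),
    bounding_box("crown", 95, 60, 50, 45, 0.81)), image = "x.png")
  fr <- tempfile(fileext = ".json")
  write_detections(d0, fr)
  d1 <- read_detections(fr)
  expect_identical(d1$boxes, d0$boxes)
  expect_identical(d1$jaw, d0$jaw)
})

test_that("YOLO-style text detections convert and validate per line", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.2 0.2 0.9",
               "1 0.5 0.8 0.1 0.3 0.7"), f)
  d <- read_detections(f, image_width = 410, image_height = 340)
  crown <- d$boxes[d$boxes$label == "crown", ]
  expect_equal(crown$x + crown$w / 2, 205)
  expect_equal(crown$y + crown$h / 2, 170)
  expect_equal(crown$w, 82)
  expect_equal(crown$h, 68)

  fb <- tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.2 0.2 0.9", "2 0.1 0.1 0.1 0.1 0.9"), fb)
  expect_error(read_detections(fb, image_width = 410, image_height = 340),
               "line 2")
  expect_error(read_detections(f), "image_width")
})

test_that("annotation files validate the 10-point minimum", {
  f <- tempfile(fileext = ".json")
  pts <- lapply(1:12, function(i) c(100 + i * 0.1, 50 + i))
  jsonlite::write_json(list(edges = list(list(
    points = pts, critical = list(c(101, 55), c(100.5, 52)),
    resorption_pct = 18))), f, auto_unbox = FALSE)
  ann <- read_annotations(f)
  expect_length(ann, 1)
  expect_equal(nrow(ann[[1]]$points), 12)
  expect_equal(ann[[1]]$resorption_pct, 18)

  fbad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(edges = list(list(
    points = lapply(1:5, function(i) c(1, i)), resorption_pct = 0))),
    fbad, auto_unbox = FALSE)
  expect_error(read_annotations(fbad), "10")
})
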