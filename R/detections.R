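#' Bounding box constructor
#'
#' Boxes use 0-based upper-left corner coordinates with y growing
#' downward and half-open extents: a box covers pixels
#' `[x, x + w) x [y, y + h)`.
#'
#' @param label `"crown"` or `"screw"`.
#' @param x,y upper-left corner (pixels, 0-based).
#' @param w,h width and height in pixels (> 0).
#' @param score detector confidence in `[0, 1]`.
#' @return a one-row data frame.
#' @export
bounding_box <- function(label, x, y, w, h, score = 1) {
  label <- match.arg(label, c("crown", "screw"))
  if (w <= 0 || h <= 0) stop("box width and height must be positive")
  if (score < 0 || score > 1) stop("score must lie in [0, 1]")
  data.frame(label = label, x = x, y = y, w = w, h = h, score = score,
             stringsAsFactors = FALSE)
}

#' Detection set constructor
#'
#' Bundles crown/screw boxes for one image and classifies the jaw side
#' from the relative mean y of the two classes (see [classify_jaw()]).
#'
#' @param boxes data frame with columns `label`, `x`, `y`, `w`, `h`,
#'   `score` (e.g. rows from [bounding_box()]).
#' @param image optional image identifier.
#' @return an object of class `mbl_detections` with elements `boxes`,
#'   `jaw`, `image`.
#' @export
detection_set <- function(boxes = NULL, image = "") {
  if (is.null(boxes) || nrow(boxes) == 0L) {
    boxes <- data.frame(label = character(), x = numeric(), y = numeric(),
                        w = numeric(), h = numeric(), score = numeric(),
                        stringsAsFactors = FALSE)
  }
  need <- c("label", "x", "y", "w", "h", "score")
  if (!all(need %in% names(boxes)))
    stop("boxes must have columns: ", paste(need, collapse = ", "))
  if (!all(boxes$label %in% c("crown", "screw")))
    stop("box labels must be 'crown' or 'screw'")
  rownames(boxes) <- NULL
  d <- structure(list(boxes = boxes[need], jaw = "unknown",
                      image = as.character(image)),
                 class = "mbl_detections")
  d$jaw <- classify_jaw(d)
  d
}

#' @export
print.mbl_detections <- function(x, ...) {
  cat(sprintf("<mbl_detections> %d box(es), jaw=%s, image='%s'\n",
              nrow(x$boxes), x$jaw, x$image))
  invisible(x)
}

.clamp_boxes <- function(boxes, width, height) {
  if (nrow(boxes) == 0L) return(boxes)
  x2 <- pmin(boxes$x + boxes$w, width)
  y2 <- pmin(boxes$y + boxes$h, height)
  boxes$x <- pmax(boxes$x, 0)
  boxes$y <- pmax(boxes$y, 0)
  boxes$w <- x2 - boxes$x
  boxes$h <- y2 - boxes$y
  keep <- boxes$w > 0 & boxes$h > 0
  boxes[keep, , drop = FALSE]
}

#' Read detector output for one image
#'
#' Two dialects are supported. JSON:
#' `{"image": "...", "boxes": [{"label": "crown"|"screw", "x":..,"y":..,
#' "w":..,"h":..,"score":..}, ...]}` with pixel coordinates. YOLO-style
#' text: one `class cx cy w h score` row per box with coordinates
#' normalized to the image size and class `0` = crown, `1` = screw
#' (requires `image_width`/`image_height`).
#'
#' Records with a confidence score of 0.5 or less are dropped (the score
#' must be strictly greater than 0.5 to count as a detection). When image
#' dimensions are supplied, boxes are clamped to the image and boxes left
#' empty by clamping are removed.
#'
#' @param path detections file.
#' @param format `"auto"` (from extension), `"json"` or `"yolo_txt"`.
#' @param image_width,image_height image size in pixels; required for
#'   YOLO text, optional (used for clamping) for JSON.
#' @param score_min score cutoff; boxes with `score <= score_min` are
#'   discarded.
#' @return an [detection_set()].
#' @export
read_detections <- function(path, format = c("auto", "json", "yolo_txt"),
                            image_width = NULL, image_height = NULL,
                            score_min = 0.5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("detections file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yolo_txt"

  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    image <- if (!is.null(obj$image)) obj$image else ""
    rows <- lapply(seq_along(obj$boxes), function(i) {
      b <- obj$boxes[[i]]
      need <- c("label", "x", "y", "w", "h", "score")
      if (!all(need %in% names(b)))
        stop("malformed detection record ", i, " in ", path,
             ": missing field(s) ",
             paste(setdiff(need, names(b)), collapse = ", "), call. = FALSE)
      if (!b$label %in% c("crown", "screw"))
        stop("unknown label '", b$label, "' in record ", i, " of ", path,
             call. = FALSE)
      data.frame(label = b$label, x = as.numeric(b$x), y = as.numeric(b$y),
                 w = as.numeric(b$w), h = as.numeric(b$h),
                 score = as.numeric(b$score), stringsAsFactors = FALSE)
    })
    boxes <- if (length(rows)) do.call(rbind, rows) else NULL
  } else {
    if (is.null(image_width) || is.null(image_height))
      stop("image_width and image_height are required for YOLO-style text")
    image <- basename(path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      if (length(f) != 6L)
        stop("malformed row at line ", i, " of ", path,
             " (expected 'class cx cy w h score')", call. = FALSE)
      v <- suppressWarnings(as.numeric(f))
      if (anyNA(v))
        stop("malformed row at line ", i, " of ", path,
             " (non-numeric field)", call. = FALSE)
      if (!v[1] %in% c(0, 1))
        stop("unknown class '", f[1], "' at line ", i, " of ", path,
             call. = FALSE)
      w <- v[4] * image_width; h <- v[5] * image_height
      data.frame(label = if (v[1] == 0) "crown" else "screw",
                 x = v[2] * image_width - w / 2,
                 y = v[3] * image_height - h / 2,
                 w = w, h = h, score = v[6], stringsAsFactors = FALSE)
    })
    boxes <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  if (!is.null(boxes) && nrow(boxes) > 0L) {
    boxes <- boxes[boxes$score > score_min, , drop = FALSE]
    if (!is.null(image_width) && !is.null(image_height))
      boxes <- .clamp_boxes(boxes, image_width, image_height)
  }
  detection_set(boxes, image = image)
}

#' Write a detection set to a JSON file
#'
#' Emits the JSON dialect read by [read_detections()]; a
#' write-then-read round trip reproduces the boxes exactly.
#'
#' @param d an [detection_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detections <- function(d, path) {
  stopifnot(inherits(d, "mbl_detections"))
  boxes <- lapply(seq_len(nrow(d$boxes)), function(i) as.list(d$boxes[i, ]))
  jsonlite::write_json(list(image = d$image, boxes = boxes), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground-truth edge annotations
#'
#' Annotation JSON holds manually placed control points per screw edge
#' (at least 10 per edge), the two critical points, and the reference
#' resorption percentage:
#' `{"edges": [{"points": [[x, y], ...], "critical": [[x, y], [x, y]],
#' "resorption_pct": p}, ...]}`.
#'
#' @param path annotation file.
#' @return list with one element per edge: `points` (n x 2 matrix),
#'   `critical` (2 x 2 matrix or NULL), `resorption_pct`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- obj$edges
  if (is.data.frame(edges)) edges <- split(edges, seq_len(nrow(edges)))
  lapply(edges, function(e) {
    pts <- e$points
    if (is.list(pts) && !is.matrix(pts)) pts <- do.call(rbind, pts)
    if (is.data.frame(pts)) pts <- as.matrix(pts)
    pts <- matrix(as.numeric(pts), ncol = 2)
    if (nrow(pts) < 10L)
      stop("each annotated edge needs at least 10 control points")
    crit <- e$critical
    if (!is.null(crit)) {
      if (is.list(crit) && !is.matrix(crit)) crit <- do.call(rbind, crit)
      crit <- matrix(as.numeric(crit), ncol = 2)
    }
    pct <- as.numeric(e$resorption_pct)
    if (length(pct) == 1 && !is.na(pct) && (pct < 0 || pct > 100))
      stop("resorption_pct must lie in [0, 100]")
    list(points = pts, critical = crit, resorption_pct = pct)
  })
}
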