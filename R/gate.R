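#' Classify the jaw side from crown/screw box positions
#'
#' With the origin at the upper-left corner and y growing downward, the
#' mean box-centre y is computed for crowns (`y_c`) and screws (`y_s`).
#' Crowns sitting above the screws (`y_c < y_s`) place the implants in
#' the lower jaw, and vice versa. If either class is absent, or the two
#' means coincide, the jaw is `"unknown"`.
#'
#' @param d an [detection_set()] or a data frame of boxes.
#' @return `"lower"`, `"upper"` or `"unknown"`.
#' @export
classify_jaw <- function(d) {
  boxes <- if (inherits(d, "mbl_detections")) d$boxes else d
  cy <- boxes$y + boxes$h / 2
  y_c <- mean(cy[boxes$label == "crown"])
  y_s <- mean(cy[boxes$label == "screw"])
  if (is.nan(y_c) || is.nan(y_s) || y_c == y_s) return("unknown")
  if (y_c < y_s) "lower" else "upper"
}

.rect_intersection <- function(ax, ay, aw, ah, bx, by, bw, bh) {
  ix <- max(0, min(ax + aw, bx + bw) - max(ax, bx))
  iy <- max(0, min(ay + ah, by + bh) - max(ay, by))
  ix * iy
}

#' Associate screws with crowns
#'
#' A crown box is valid for a screw when, after extending the screw box
#' along the y axis toward the crown side (up for the lower jaw, down
#' for the upper) until the crown's far edge, the intersection with the
#' crown box exceeds 30% of the crown box area. Each screw is paired
#' with at most one crown: the one with the largest overlap fraction,
#' ties broken by the nearest crown centre. Screws with no valid crown
#' are excluded from downstream processing.
#'
#' @param d an [detection_set()].
#' @param jaw `"lower"` or `"upper"`; defaults to the set's own
#'   classification. An `"unknown"` jaw is a gating error: the image is
#'   excluded from measurement.
#' @param overlap_min minimum overlap fraction (strictly exceeded).
#' @return list of implant units, each
#'   `list(screw_box=, crown_box=, overlap_fraction=)`.
#' @export
associate_implants <- function(d, jaw = NULL, overlap_min = 0.3) {
  stopifnot(inherits(d, "mbl_detections"))
  if (is.null(jaw)) jaw <- d$jaw
  if (!jaw %in% c("lower", "upper"))
    stop(mbl_error("jaw is unknown; image excluded from measurement",
                   "mbl_gating_error"))
  screws <- d$boxes[d$boxes$label == "screw", , drop = FALSE]
  crowns <- d$boxes[d$boxes$label == "crown", , drop = FALSE]
  units <- list()
  for (i in seq_len(nrow(screws))) {
    s <- screws[i, ]
    s_cy <- s$y + s$h / 2
    best <- NULL; best_frac <- overlap_min; best_dist <- Inf
    for (j in seq_len(nrow(crowns))) {
      cr <- crowns[j, ]
      c_cy <- cr$y + cr$h / 2
      # crown must sit on the coronal side of the screw
      if (jaw == "lower" && c_cy >= s_cy) next
      if (jaw == "upper" && c_cy <= s_cy) next
      if (jaw == "lower") {           # extend screw box upward to crown top
        ey <- min(s$y, cr$y); eh <- (s$y + s$h) - ey
      } else {                        # extend downward to crown bottom
        ey <- s$y; eh <- max(s$y + s$h, cr$y + cr$h) - ey
      }
      inter <- .rect_intersection(s$x, ey, s$w, eh, cr$x, cr$y, cr$w, cr$h)
      frac <- inter / (cr$w * cr$h)
      if (frac <= overlap_min) next
      dist <- sqrt((s$x + s$w / 2 - cr$x - cr$w / 2)^2 + (s_cy - c_cy)^2)
      if (frac > best_frac || (frac == best_frac && dist < best_dist)) {
        best <- list(screw_box = s, crown_box = cr, overlap_fraction = frac)
        best_frac <- frac; best_dist <- dist
      }
    }
    if (!is.null(best)) units[[length(units) + 1L]] <- best
  }
  units
}

#' Contrast quality of the implant regions
#'
#' Contrast is quantified as the population standard deviation of the
#' intensities inside the union of the unit bounding boxes (screws and
#' crowns), normalized by the maximum observed over high-contrast
#' radiographs (`sigma_max`, about 98 gray levels) and capped at 1. A
#' normalized value of at least `threshold` (0.4) marks the image as
#' high contrast; lower values flag it for additional linear
#' enhancement before edge extraction.
#'
#' @param r an [radiograph()].
#' @param units implant units from [associate_implants()].
#' @param sigma_max normalizing constant (gray levels).
#' @param threshold high-contrast cutoff on the normalized value
#'   (inclusive).
#' @return `list(sigma_raw, sigma_norm, high_contrast)`.
#' @export
contrast_quality <- function(r, units, sigma_max = 98, threshold = 0.4) {
  stopifnot(inherits(r, "mbl_radiograph"))
  if (length(units) < 1L) stop("contrast_quality needs at least one unit")
  mask <- matrix(FALSE, r$height, r$width)
  for (u in units) {
    for (b in list(u$screw_box, u$crown_box)) {
      x1 <- max(0L, floor(b$x)); y1 <- max(0L, floor(b$y))
      x2 <- min(r$width, ceiling(b$x + b$w)); y2 <- min(r$height, ceiling(b$y + b$h))
      if (x2 > x1 && y2 > y1) mask[(y1 + 1):y2, (x1 + 1):x2] <- TRUE
    }
  }
  v <- r$pixels[mask]
  sigma_raw <- sqrt(mean((v - mean(v))^2))
  sigma_norm <- min(1, sigma_raw / sigma_max)
  list(sigma_raw = sigma_raw, sigma_norm = sigma_norm,
       high_contrast = sigma_norm >= threshold)
}

# condition helper: typed errors so the CLI can map them to exit codes
mbl_error <- function(message, class) {
  structure(class = c(class, "mbl_error", "error", "condition"),
            list(message = message, call = NULL))
}
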