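# Canny edge detection: Gaussian smoothing, Sobel gradients,
# non-maximum suppression and hysteresis thresholding. Thresholds are
# derived from the gradient-magnitude distribution (high at a
# percentile, low as a fraction of high) so the detector adapts to the
# contrast of each radiograph.

.gaussian_kernel2d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

.conv2_replicate <- function(m, kern) {
  EBImage::filter2(m, kern, boundary = "replicate")
}

#' Edge map constructor
#'
#' @param mask 0/1 matrix, same shape as the source radiograph.
#' @param provenance one of `"raw"`, `"dilated"`, `"masked"`.
#' @return an `mbl_edge_map` (integer 0/1 matrix with a provenance
#'   attribute).
#' @export
edge_map <- function(mask, provenance = "raw") {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  structure(m, provenance = provenance, class = c("mbl_edge_map", "matrix"))
}

#' Canny edge detection
#'
#' @param r an [radiograph()] (typically after [enhance_gamma()]).
#' @param sigma Gaussian smoothing scale in pixels.
#' @param high_pct percentile of the positive gradient magnitudes used
#'   as the high hysteresis threshold.
#' @param low_ratio low threshold as a fraction of the high threshold.
#' @param high_floor lower bound on the high threshold as a fraction of
#'   the maximum gradient magnitude.
#' @return an [edge_map()] of thin binary edge curves.
#' @export
canny_edges <- function(r, sigma = sqrt(2), high_pct = 0.90,
                        low_ratio = 0.4, high_floor = 0.15) {
  stopifnot(inherits(r, "mbl_radiograph"))
  px <- r$pixels
  h <- nrow(px); w <- ncol(px)
  sm <- .conv2_replicate(px, .gaussian_kernel2d(sigma))
  # Sobel kernels in [row = y, col = x] orientation
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- .conv2_replicate(sm, kx)
  gy <- .conv2_replicate(sm, ky)
  mag <- sqrt(gx^2 + gy^2)
  # FFT convolution leaves ~1e-13 ripple on flat images; treat it as 0
  mag[mag < 1e-6] <- 0
  if (max(mag) == 0) return(edge_map(matrix(0L, h, w)))

  # non-maximum suppression on 4 quantized gradient directions
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  sh <- function(dy, dx) .shift_mat2(mag, dy, dx)
  s0 <- (ang < 22.5) | (ang >= 157.5)          # gradient along x: compare x+-1
  s45 <- ang >= 22.5 & ang < 67.5
  s90 <- ang >= 67.5 & ang < 112.5             # gradient along y: compare y+-1
  s135 <- ang >= 112.5 & ang < 157.5
  l <- sh(0, -1); rg <- sh(0, 1); u <- sh(-1, 0); d <- sh(1, 0)
  ul <- sh(-1, -1); ur <- sh(-1, 1); dl <- sh(1, -1); dr <- sh(1, 1)
  n1[s0] <- l[s0];    n2[s0] <- rg[s0]
  n1[s90] <- u[s90];  n2[s90] <- d[s90]
  n1[s45] <- ur[s45]; n2[s45] <- dl[s45]       # gradient at +45 deg (y down)
  n1[s135] <- ul[s135]; n2[s135] <- dr[s135]
  nms <- mag >= n1 & mag > n2 & mag > 0

  # percentile threshold with a floor tied to the strongest gradient:
  # on images that are flat over most of their area the bare percentile
  # collapses to the noise level and everything becomes an edge
  pos <- mag[mag > 0]
  hi <- max(as.numeric(quantile(pos, high_pct)), high_floor * max(mag))
  lo <- low_ratio * hi
  strong <- nms & mag >= hi
  weak <- nms & mag >= lo
  if (!any(strong)) return(edge_map(matrix(0L, h, w)))
  lab <- label_components(weak, connectivity = 8)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  edge_map(matrix(as.integer(lab %in% keep), h, w))
}

# zero-padded shift used by NMS (separate from morphology's integer one)
.shift_mat2 <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Expand a bounding box by a fraction of its size
#'
#' Grows the box by `expand/2` of its width on each side and `expand/2`
#' of its height on each end (10% per dimension in total by default).
#' The top-left corner is floored and the size is ceiled so that the
#' expanded box always contains the original; the result is clamped to
#' the image.
#'
#' @param box one-row data frame with `x`, `y`, `w`, `h`.
#' @param expand total relative growth per dimension.
#' @param width,height image dimensions for clamping (optional).
#' @return list with integer `x`, `y`, `w`, `h`.
#' @export
expand_box <- function(box, expand = 0.10, width = NULL, height = NULL) {
  x <- floor(round(box$x - expand / 2 * box$w, 9))
  y <- floor(round(box$y - expand / 2 * box$h, 9))
  w <- ceiling(round(box$w * (1 + expand), 9))
  h <- ceiling(round(box$h * (1 + expand), 9))
  if (!is.null(width)) {
    x2 <- min(x + w, width); x <- max(x, 0); w <- x2 - x
  }
  if (!is.null(height)) {
    y2 <- min(y + h, height); y <- max(y, 0); h <- y2 - y
  }
  list(x = x, y = y, w = w, h = h)
}

#' Restrict an edge map to the screw regions and dilate
#'
#' Each screw bounding box is expanded by 10% in all dimensions so that
#' the full edges fall inside, edges outside every expanded box are
#' discarded, and the retained edges are dilated with a 3x3 structuring
#' element to emphasize them and close small gaps before line fitting.
#'
#' @param e an [edge_map()] from [canny_edges()].
#' @param units implant units from [associate_implants()].
#' @param expand relative box growth per dimension.
#' @param se dilation structuring element size, `c(rows, cols)`.
#' @return a dilated, masked [edge_map()]; the expanded boxes are
#'   attached as attribute `"roi_boxes"`.
#' @export
screw_roi_edges <- function(e, units, expand = 0.10, se = c(3L, 3L)) {
  stopifnot(length(units) >= 1L)
  h <- nrow(e); w <- ncol(e)
  mask <- matrix(FALSE, h, w)
  rois <- list()
  for (u in units) {
    b <- expand_box(u$screw_box, expand, width = w, height = h)
    if (b$w <= 0 || b$h <= 0) {
      warning("expanded screw box degenerate after clamping; unit skipped")
      next
    }
    mask[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)] <- TRUE
    rois[[length(rois) + 1L]] <- b
  }
  kept <- matrix(as.integer(e != 0 & mask), h, w)
  out <- edge_map(dilate_binary(kept, se[1], se[2]), provenance = "masked")
  attr(out, "roi_boxes") <- rois
  out
}
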