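# Polar Hough transform for straight lines: rho = x cos(theta) + y sin(theta),
# with 1 px and 1 degree accumulator resolution. theta is the angle of
# the line normal with the x axis, sampled on [-90, 89] degrees; rho can
# be negative. Coordinates are 0-based image pixels.

.hough_thetas <- function() -90:89

#' Accumulate a polar Hough transform and pick its peaks
#'
#' Builds the (rho, theta) accumulator at 1 pixel and 1 degree
#' resolution over all edge pixels and returns the `n_peaks` strongest
#' local maxima by greedy selection with neighbourhood suppression:
#' repeatedly take the highest remaining bin (ties broken toward the
#' smallest theta, then the smallest rho), then zero a `nhood` window
#' around it. Peaks below `min_votes` are not returned, so sparse maps
#' do not admit noise lines.
#'
#' @param e an [edge_map()] (or 0/1 matrix).
#' @param n_peaks maximum number of peaks.
#' @param min_votes minimum accumulator count for a peak.
#' @param nhood suppression window `c(rho_bins, theta_bins)` (odd).
#' @return data frame with columns `rho`, `theta` (degrees), `votes`,
#'   `vertical`, `m`, `d` (slope/intercept; `NA` for vertical lines),
#'   ordered by decreasing votes. The full accumulator is attached as
#'   attribute `"accumulator"` with rho values as rownames and thetas as
#'   colnames.
#' @export
hough_accumulate <- function(e, n_peaks = 16L, min_votes = 15L,
                             nhood = c(5L, 5L)) {
  pts <- which(e != 0, arr.ind = TRUE)
  if (nrow(pts) < 2L)
    stop(mbl_error("edge map has fewer than 2 edge pixels",
                   "mbl_description_error"))
  x <- pts[, 2] - 1; y <- pts[, 1] - 1
  thetas <- .hough_thetas()
  th <- thetas * pi / 180
  D <- ceiling(sqrt(max(x)^2 + max(y)^2))
  nr <- 2L * D + 1L
  acc <- matrix(0L, nr, length(thetas),
                dimnames = list(-D:D, thetas))
  for (t in seq_along(thetas)) {
    rho <- round(x * cos(th[t]) + y * sin(th[t]))
    acc[, t] <- tabulate(rho + D + 1L, nbins = nr)
  }
  peaks <- .hough_peaks(acc, n_peaks, min_votes, nhood)
  res <- data.frame(rho = numeric(0), theta = numeric(0), votes = integer(0))
  if (nrow(peaks) > 0L) {
    res <- data.frame(rho = as.numeric(rownames(acc))[peaks$ri],
                      theta = thetas[peaks$ti],
                      votes = peaks$votes)
    sl <- hough_to_slope_intercept(res$rho, res$theta)
    res$vertical <- sl$vertical
    res$m <- sl$m
    res$d <- sl$d
  } else {
    res$vertical <- logical(0); res$m <- numeric(0); res$d <- numeric(0)
  }
  attr(res, "accumulator") <- acc
  res
}

# greedy peak picking with rectangular suppression; deterministic
# tie-break = first bin in column-major order (smallest theta index,
# then smallest rho index)
.hough_peaks <- function(acc, n_peaks, min_votes, nhood) {
  a <- acc
  hr <- (nhood[1] - 1L) %/% 2L; ht <- (nhood[2] - 1L) %/% 2L
  out <- data.frame(ri = integer(0), ti = integer(0), votes = integer(0))
  for (k in seq_len(n_peaks)) {
    i <- which.max(a)
    v <- a[i]
    if (length(v) == 0L || v < min_votes) break
    ri <- (i - 1L) %% nrow(a) + 1L
    ti <- (i - 1L) %/% nrow(a) + 1L
    out <- rbind(out, data.frame(ri = ri, ti = ti, votes = as.integer(v)))
    rs <- max(1L, ri - hr):min(nrow(a), ri + hr)
    ts <- max(1L, ti - ht):min(ncol(a), ti + ht)
    a[rs, ts] <- -1L
  }
  out
}

#' Convert Hough line parameters to slope-intercept form
#'
#' Applies `m = -cos(theta)/sin(theta)` and `d = rho/sin(theta)`, the
#' slope/intercept of the line `y = m x + d` whose normal makes angle
#' `theta` with the x axis at distance `rho` from the origin. Lines with
#' `sin(theta) = 0` are vertical (`x = rho`) and are flagged instead of
#' converted.
#'
#' @param rho,theta line parameters; `theta` in degrees. Vectorized.
#' @return `list(vertical, m, d)`; `m` and `d` are `NA` where `vertical`
#'   is `TRUE`.
#' @export
hough_to_slope_intercept <- function(rho, theta) {
  th <- theta * pi / 180
  s <- sin(th); cth <- cos(th)
  vertical <- abs(s) < 1e-12
  m <- ifelse(vertical, NA_real_, -cth / s)
  d <- ifelse(vertical, NA_real_, rho / s)
  list(vertical = vertical, m = m, d = d)
}

#' Discard lines too close to horizontal
#'
#' The screw edges of interest run near-vertically, so detected lines
#' whose angle from the horizontal axis (`atan(|m|)`, 90 degrees for
#' vertical lines) is below `min_angle` are discarded.
#'
#' @param lines data frame from [hough_accumulate()].
#' @param min_angle minimum angle from horizontal, degrees (retained
#'   when `>= min_angle`).
#' @return the filtered data frame.
#' @export
filter_by_slope <- function(lines, min_angle = 30) {
  if (nrow(lines) == 0L) return(lines)
  ang <- ifelse(lines$vertical, 90, atan(abs(lines$m)) * 180 / pi)
  lines[ang >= min_angle, , drop = FALSE]
}

#' Keep edge pixels explained by the retained lines
#'
#' For each retained line, edge pixels within `band` pixels of
#' perpendicular distance are collected; along the line direction, runs
#' separated by more than `max_gap` pixels are split, and runs spanning
#' fewer than `min_seg_len` pixels are dropped. The union of the
#' surviving piecewise segments over all lines forms the output, so a
#' curved edge is covered by several straight segments.
#'
#' @param e an [edge_map()].
#' @param lines retained lines (rows of [hough_accumulate()] output).
#' @param band half-width of the distance band, pixels.
#' @param min_seg_len minimum along-line span of a segment, pixels.
#' @param max_gap largest along-line gap bridged within a segment,
#'   pixels.
#' @return an [edge_map()] of the retained pixels.
#' @export
extract_segments <- function(e, lines, band = 2, min_seg_len = 10,
                             max_gap = 3) {
  if (nrow(lines) < 1L)
    stop(mbl_error("no lines retained for segment extraction",
                   "mbl_description_error"))
  pts <- which(e != 0, arr.ind = TRUE)
  if (nrow(pts) == 0L)
    stop(mbl_error("empty edge map", "mbl_description_error"))
  x <- pts[, 2] - 1; y <- pts[, 1] - 1
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(lines))) {
    th <- lines$theta[i] * pi / 180
    dist <- abs(x * cos(th) + y * sin(th) - lines$rho[i])
    cand <- which(dist <= band)
    if (length(cand) == 0L) next
    tt <- -x[cand] * sin(th) + y[cand] * cos(th)  # along-line coordinate
    o <- order(tt)
    tt_s <- tt[o]
    brk <- c(0L, which(diff(tt_s) > max_gap), length(tt_s))
    for (s in seq_len(length(brk) - 1L)) {
      idx <- (brk[s] + 1L):brk[s + 1L]
      if (tt_s[idx[length(idx)]] - tt_s[idx[1L]] >= min_seg_len)
        keep[cand[o[idx]]] <- TRUE
    }
  }
  if (!any(keep))
    stop(mbl_error("no edge pixels retained by any line",
                   "mbl_description_error"))
  out <- matrix(0L, nrow(e), ncol(e))
  out[pts[keep, , drop = FALSE]] <- 1L
  edge_map(out, provenance = "raw")
}

#' Group segment pixels into labeled edges
#'
#' The segment map is dilated horizontally with a 1x5 structuring
#' element (merging alignments offset by a few pixels, e.g. across
#' screw threads), connected components are labeled with
#' 8-connectivity, and each component is intersected with the
#' region-of-interest edge map to recover the full pixel alignment of
#' the edge. Groups with fewer than `min_group_px` pixels are dropped.
#'
#' @param segs segment [edge_map()] from [extract_segments()].
#' @param roi_edges the masked, dilated [edge_map()] from
#'   [screw_roi_edges()].
#' @param min_group_px minimum pixel count per group.
#' @return list of edge groups, each
#'   `list(label, pixels = data.frame(x, y), y_min, y_max)` with
#'   0-based coordinates; `y_min`/`y_max` are the group's vertical
#'   extremes (the paper's `y_im` and `y_iM`).
#' @export
group_and_label <- function(segs, roi_edges, min_group_px = 30L) {
  if (!any(segs != 0))
    stop(mbl_error("empty segment map", "mbl_description_error"))
  dil <- dilate_binary(segs, 1L, 5L)
  lab <- label_components(dil, connectivity = 8)
  roi <- roi_edges != 0
  groups <- list()
  for (l in seq_len(max(lab))) {
    sel <- lab == l & roi
    n <- sum(sel)
    if (n < min_group_px) next
    pts <- which(sel, arr.ind = TRUE)
    g <- list(label = length(groups) + 1L,
              pixels = data.frame(x = pts[, 2] - 1, y = pts[, 1] - 1),
              y_min = min(pts[, 1]) - 1, y_max = max(pts[, 1]) - 1)
    groups[[length(groups) + 1L]] <- g
  }
  if (length(groups) == 0L)
    stop(mbl_error("no edge groups survive labeling",
                   "mbl_description_error"))
  groups
}
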