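# Least-squares polynomial description of edge groups. Because the
# target edges are near-vertical, x is modelled as a polynomial in y:
# x = a + b*y + c*y^2 (+ d*y^3), the only orientation in which the fit
# is well posed.

#' Fit a polynomial x(y) to an edge group
#'
#' @param g an edge group from [group_and_label()], or any list with a
#'   `pixels` data frame holding `x` and `y`.
#' @param degree polynomial degree, 1 to 3.
#' @return `list(degree, coeffs, mse)` with `coeffs = c(a, b, c, ...)`
#'   such that `x = a + b*y + c*y^2 + ...`, and `mse` the mean squared
#'   x residual in squared pixels.
#' @export
fit_edge <- function(g, degree = 2L) {
  degree <- as.integer(degree)
  stopifnot(degree %in% 1:3)
  px <- g$pixels
  if (nrow(px) <= degree + 1L)
    stop("edge group needs more than degree + 1 pixels")
  if (length(unique(px$y)) < degree + 1L)
    stop("rank-deficient fit: too few distinct y values")
  X <- outer(px$y, 0:degree, `^`)
  f <- stats::lm.fit(X, px$x)
  co <- unname(f$coefficients)
  if (anyNA(co)) stop("rank-deficient fit")
  list(degree = degree, coeffs = co,
       mse = mean(f$residuals^2))
}

#' Evaluate a polynomial fit at given y
#'
#' @param fit a fit from [fit_edge()].
#' @param y vector of y coordinates.
#' @return x values.
#' @export
eval_poly <- function(fit, y) {
  drop(outer(y, seq_along(fit$coeffs) - 1L, `^`) %*% fit$coeffs)
}

# derivative dx/dy of a fit at y
.eval_poly_deriv <- function(fit, y) {
  co <- fit$coeffs
  p <- seq_along(co) - 1L
  drop(outer(y, pmax(p - 1L, 0L), `^`) %*% (co * p))
}

#' Select the best-supported polynomial degree
#'
#' Fits increasing degrees and keeps the lowest one unless a higher
#' degree reduces the residual error significantly (nested-model F
#' test at level `alpha`). A raw in-sample MSE comparison would always
#' prefer the highest degree by a chance margin; the significance
#' criterion makes collinear points select a straight line and keeps a
#' noisy parabola at degree 2. In the measurement pipeline itself the
#' curve is always degree 2; degree selection is used when fitting
#' ground-truth control points during evaluation.
#'
#' @param g an edge group (see [fit_edge()]).
#' @param degrees candidate degrees, ascending.
#' @param alpha significance level for accepting a higher degree.
#' @return the winning [fit_edge()] result.
#' @export
select_degree <- function(g, degrees = 1:3, alpha = 0.01) {
  degrees <- sort(degrees)
  fits <- lapply(degrees, function(d)
    tryCatch(fit_edge(g, d), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  if (length(fits) == 0L) stop("no degree could be fitted")
  n <- nrow(g$pixels)
  cur <- fits[[1L]]
  for (cand in fits[-1L]) {
    df2 <- n - (cand$degree + 1L)
    if (df2 <= 0L) break
    rss_lo <- cur$mse * n
    rss_hi <- cand$mse * n
    df1 <- cand$degree - cur$degree
    if (rss_hi <= 1e-12) {
      if (rss_lo > 1e-12) cur <- cand
      next
    }
    Fstat <- (rss_lo - rss_hi) / df1 / (rss_hi / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    if (!is.na(p) && p < alpha) cur <- cand
  }
  cur
}

#' Describe screw edges: Hough lines, segments, groups and fits
#'
#' Runs the edge-description stage on a masked edge map: Hough peak
#' detection, slope filtering, piecewise segment extraction, grouping
#' and labeling, then a straight-line and a degree-2 polynomial fit per
#' group. Groups are assigned to the implant unit whose expanded screw
#' box contains the majority of their pixels, and to the left or right
#' side of that screw by comparing the curve's mean x with the box
#' centre; when several groups claim one side, the largest is kept.
#'
#' @param roi_edges [edge_map()] from [screw_roi_edges()] (must carry
#'   the `"roi_boxes"` attribute).
#' @param units implant units from [associate_implants()].
#' @param config an [mbl_config()].
#' @return list of fitted edges, each `list(group, line, curve, side,
#'   unit, y_min, y_max)`; `line` is the degree-1 fit, `curve` the
#'   degree-2 fit.
#' @export
describe_edges <- function(roi_edges, units, config = mbl_config()) {
  config <- as_mbl_config(config)
  lines <- hough_accumulate(roi_edges,
                            n_peaks = config$hough$n_peaks,
                            min_votes = config$hough$min_votes,
                            nhood = config$hough$nhood)
  lines <- filter_by_slope(lines, config$slope_min_deg)
  if (nrow(lines) == 0L)
    stop(mbl_error("no near-vertical lines detected",
                   "mbl_description_error"))
  segs <- extract_segments(roi_edges, lines, band = config$line_band,
                           min_seg_len = config$min_seg_len,
                           max_gap = config$max_gap)
  groups <- group_and_label(segs, roi_edges,
                            min_group_px = config$min_group_px)
  rois <- attr(roi_edges, "roi_boxes")
  if (is.null(rois)) rois <- lapply(units, function(u)
    expand_box(u$screw_box, config$roi_expand,
               width = ncol(roi_edges), height = nrow(roi_edges)))

  # unit assignment by majority of pixels inside the expanded screw box
  assign_unit <- function(g) {
    counts <- vapply(rois, function(b)
      sum(g$pixels$x >= b$x & g$pixels$x < b$x + b$w &
          g$pixels$y >= b$y & g$pixels$y < b$y + b$h), numeric(1))
    if (max(counts) == 0) return(NA_integer_)
    which.max(counts)
  }

  # a group that wraps around the apex tip (or across the crown) spans
  # both sides of its screw; split such groups at the box centre so
  # each side is fitted on its own pixels
  split_sides <- function(g, cx) {
    lp <- g$pixels[g$pixels$x < cx - 2, , drop = FALSE]
    rp <- g$pixels[g$pixels$x > cx + 2, , drop = FALSE]
    if (nrow(lp) < config$min_group_px || nrow(rp) < config$min_group_px)
      return(list(g))
    lapply(list(lp, rp), function(p)
      list(label = g$label, pixels = p, y_min = min(p$y), y_max = max(p$y)))
  }
  # trimmed refit: drop pixels far from the fitted description
  # (apex-tip and crown-junction stubs, stray texture edges). The
  # first pass trims against the stiff straight-line fit - a flexible
  # quadratic can bend toward high-leverage contamination at the group
  # ends - with a tolerance wide enough for the edge's own curvature
  # and threads; later passes tighten against the degree-2 curve.
  trim_group <- function(g, tol = config$fit_trim) {
    plan <- list(c(1L, max(2 * tol, 6)), c(2L, tol), c(2L, tol))
    for (st in plan) {
      f <- tryCatch(fit_edge(g, st[1]), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      keep <- abs(g$pixels$x - eval_poly(f, g$pixels$y)) <= st[2]
      if (sum(keep) < config$min_group_px) break
      if (!all(keep)) {
        g$pixels <- g$pixels[keep, , drop = FALSE]
        g$y_min <- min(g$pixels$y); g$y_max <- max(g$pixels$y)
      }
    }
    g
  }

  # pieces: groups assigned to a unit, split at the box centre when
  # they wrap around the screw, with a side label
  pieces <- list()
  for (g in groups) {
    ui <- assign_unit(g)
    if (is.na(ui)) next
    sb <- units[[ui]]$screw_box
    cx <- sb$x + sb$w / 2
    for (p in split_sides(g, cx)) {
      p$unit <- ui
      p$side <- if (mean(p$pixels$x) < cx) "left" else "right"
      pieces[[length(pieces) + 1L]] <- p
    }
  }
  # one physical edge per screw side: union the fragments that a
  # coverage gap may have split, then refit on the merged pixels
  key <- vapply(pieces, function(p) paste(p$unit, p$side), character(1))
  edges <- list()
  for (k in unique(key)) {
    ps <- pieces[key == k]
    pix <- unique(do.call(rbind, lapply(ps, `[[`, "pixels")))
    g <- list(label = length(edges) + 1L, pixels = pix,
              y_min = min(pix$y), y_max = max(pix$y))
    g <- trim_group(g)
    if (is.null(g) || nrow(g$pixels) < config$min_group_px) next
    line <- tryCatch(fit_edge(g, 1L), error = function(e) NULL)
    curve <- tryCatch(fit_edge(g, 2L), error = function(e) NULL)
    if (is.null(line) || is.null(curve)) next
    # enforce the near-vertical constraint on the fitted line as well:
    # x = a + b*y has angle atan(1/|b|) from horizontal
    ang <- if (abs(line$coeffs[2]) < 1e-12) 90
           else atan(1 / abs(line$coeffs[2])) * 180 / pi
    if (ang < config$slope_min_deg) next
    edges[[length(edges) + 1L]] <-
      list(group = g, line = line, curve = curve,
           side = ps[[1]]$side, unit = ps[[1]]$unit,
           y_min = g$y_min, y_max = g$y_max)
  }
  if (length(edges) == 0L)
    stop(mbl_error("no fitted edges", "mbl_description_error"))
  edges
}
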