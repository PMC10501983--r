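# From critical pairs to clinical quantities: arc lengths along the
# fitted curve, resorption percentages, severity bands and millimetre
# conversion.

#' Discrete arc length of a polynomial curve x(y)
#'
#' Sums `sqrt(1 + (dx/dy)^2) * dy` over unit y steps (plus a final
#' partial step), with the derivative evaluated at interval midpoints.
#' For integer endpoints the sum is exactly additive over subdivision.
#'
#' @param curve a fit from [fit_edge()].
#' @param y_a,y_b integration bounds, `y_a <= y_b`.
#' @return arc length in pixels.
#' @export
arc_length <- function(curve, y_a, y_b) {
  if (!is.numeric(y_a) || !is.numeric(y_b) || y_a > y_b)
    stop("need numeric bounds with y_a <= y_b")
  if (y_a == y_b) return(0)
  breaks <- seq(y_a, y_b, by = 1)
  if (breaks[length(breaks)] < y_b) breaks <- c(breaks, y_b)
  widths <- diff(breaks)
  mids <- breaks[-length(breaks)] + widths / 2
  der <- .eval_poly_deriv(curve, mids)
  sum(sqrt(1 + der^2) * widths)
}

#' Bone-resorption percentage of an edge
#'
#' The resorbed span is the arc of the fitted curve between the two
#' critical points; its ratio to the full curve length (the visible
#' fitted span by default) gives the resorption percentage. When the
#' physical implant length is known, it can replace the visible span as
#' the denominator (`known_length_mm / mm_per_px`), which handles
#' radiographs where the apical tip is occluded.
#'
#' @param edge a fitted edge from [describe_edges()].
#' @param pair a critical pair from [detect_edge_critical_pair()].
#' @param mm_per_px vertical calibration.
#' @param known_length_mm optional physical implant length in mm.
#' @return `list(percentage, loss_px, denominator_px)`; `percentage` is
#'   clamped to `[0, 100]` and `NA` when the pair status is not
#'   `"both"`.
#' @export
resorption_percentage <- function(edge, pair, mm_per_px = 0.063,
                                  known_length_mm = NULL) {
  if (is.null(pair) || !identical(pair$status, "both"))
    return(list(percentage = NA_real_, loss_px = NA_real_,
                denominator_px = NA_real_))
  y1 <- min(pair$first$y, pair$second$y)
  y2 <- max(pair$first$y, pair$second$y)
  loss <- arc_length(edge$curve, y1, y2)
  denom <- if (!is.null(known_length_mm)) {
    if (known_length_mm <= 0) stop("known_length_mm must be positive")
    known_length_mm / mm_per_px
  } else {
    arc_length(edge$curve, edge$y_min, edge$y_max)
  }
  pct <- min(100, max(0, 100 * loss / denom))
  list(percentage = pct, loss_px = loss, denominator_px = denom)
}

#' Severity class of a resorption percentage
#'
#' Bands: normal (<= 10%, including null impact), early (10-25%],
#' moderate (25-50%), severe (>= 50%). The explicit inclusive marks at
#' 10 and 50 take precedence at the boundaries.
#'
#' @param p percentage in `[0, 100]`; `NA` yields `"undetected"`.
#' @return one of `"normal"`, `"early"`, `"moderate"`, `"severe"`,
#'   `"undetected"`.
#' @export
classify_severity <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("undetected")
    if (pi < 0 || pi > 100) stop("percentage must lie in [0, 100]")
    if (pi <= 10) "normal"
    else if (pi <= 25) "early"
    else if (pi < 50) "moderate"
    else "severe"
  }, character(1))
}

#' Convert vertical pixels to millimetres
#'
#' @param v distance in pixels.
#' @param calib calibration in mm per vertical pixel.
#' @param digits decimals to report (2 by default, the clinical
#'   reporting precision).
#' @return distance in millimetres.
#' @export
px_to_mm <- function(v, calib = 0.063, digits = 2) {
  if (calib <= 0) stop("calibration must be positive")
  round(v * calib, digits)
}

#' Assemble a resorption report
#'
#' @param image image identifier.
#' @param jaw jaw classification.
#' @param quality contrast metric from [contrast_quality()] (or NULL).
#' @param edges fitted edges from [describe_edges()].
#' @param pairs critical pairs, one per edge.
#' @param percents results of [resorption_percentage()], one per edge.
#' @param mm_per_px vertical calibration.
#' @return an `mbl_report`: `list(image, edges = <data frame>, summary)`.
#'   The edge table has one row per fitted edge with the critical-point
#'   coordinates, loss in px and mm, percentage, severity and the
#'   degree-2 curve coefficients; the summary counts edges by status
#'   and records the extreme percentages.
#' @export
build_report <- function(image, jaw, quality, edges, pairs, percents,
                         mm_per_px = 0.063) {
  n <- length(edges)
  rows <- lapply(seq_len(n), function(i) {
    e <- edges[[i]]; p <- pairs[[i]]; rp <- percents[[i]]
    data.frame(
      edge = i, unit = e$unit, side = e$side,
      y_min = e$y_min, y_max = e$y_max,
      a = e$curve$coeffs[1], b = e$curve$coeffs[2], c = e$curve$coeffs[3],
      status = p$status,
      x_first = if (is.null(p$first)) NA_real_ else p$first$x,
      y_first = if (is.null(p$first)) NA_real_ else p$first$y,
      x_second = if (is.null(p$second)) NA_real_ else p$second$x,
      y_second = if (is.null(p$second)) NA_real_ else p$second$y,
      loss_px = rp$loss_px,
      loss_mm = px_to_mm(rp$loss_px, mm_per_px),
      percentage = rp$percentage,
      severity = classify_severity(rp$percentage),
      stringsAsFactors = FALSE)
  })
  tab <- if (n > 0) do.call(rbind, rows) else
    data.frame(edge = integer(0), unit = integer(0), side = character(0),
               y_min = numeric(0), y_max = numeric(0), a = numeric(0),
               b = numeric(0), c = numeric(0), status = character(0),
               x_first = numeric(0), y_first = numeric(0),
               x_second = numeric(0), y_second = numeric(0),
               loss_px = numeric(0), loss_mm = numeric(0),
               percentage = numeric(0), severity = character(0),
               stringsAsFactors = FALSE)
  meas <- tab$percentage[!is.na(tab$percentage)]
  summary <- list(
    jaw = jaw,
    sigma_norm = if (is.null(quality)) NA_real_ else quality$sigma_norm,
    high_contrast = if (is.null(quality)) NA else quality$high_contrast,
    n_edges = n,
    n_both = sum(tab$status == "both"),
    n_first_only = sum(tab$status == "first_only"),
    n_none = sum(tab$status == "none"),
    max_percentage = if (length(meas)) max(meas) else NA_real_,
    min_percentage = if (length(meas)) min(meas) else NA_real_,
    no_resorption = length(meas) == 0L)
  structure(list(image = as.character(image), edges = tab,
                 summary = summary, mm_per_px = mm_per_px),
            class = "mbl_report")
}

#' @export
print.mbl_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<mbl_report> image='%s' jaw=%s edges=%d (both=%d, first_only=%d, none=%d)\n",
              x$image, s$jaw, s$n_edges, s$n_both, s$n_first_only, s$n_none))
  if (!s$no_resorption)
    cat(sprintf("  resorption %% range: %.1f - %.1f\n",
                s$min_percentage, s$max_percentage))
  else cat("  no resorption detected\n")
  invisible(x)
}

#' Write a resorption report (JSON + CSV)
#'
#' Writes the full report as JSON to `path` and the per-edge table as
#' CSV next to it (same name, `.csv` extension). [read_report()] on the
#' JSON restores an equal structure.
#'
#' @param report an `mbl_report` from [build_report()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mbl_report"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  obj <- list(image = report$image, mm_per_px = report$mm_per_px,
              summary = report$summary, edges = report$edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  csv <- sub("\\.json$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  write.csv(report$edges, csv, row.names = FALSE)
  invisible(path)
}

#' Read back a JSON resorption report
#'
#' @param path JSON file produced by [write_report()].
#' @return an `mbl_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- obj$edges
  if (length(edges) == 0L || is.null(nrow(edges)))
    edges <- build_report("", "unknown", NULL, list(), list(), list())$edges
  summary <- obj$summary
  summary$sigma_norm <- as.numeric(summary$sigma_norm)
  structure(list(image = obj$image, edges = as.data.frame(edges),
                 summary = summary, mm_per_px = obj$mm_per_px),
            class = "mbl_report")
}
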