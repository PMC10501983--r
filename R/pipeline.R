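#' Measure marginal bone loss in one radiograph
#'
#' Runs the full image-understanding pipeline: jaw classification and
#' crown-screw association from the detector boxes, contrast-quality
#' gating, image enhancement (gamma always; the linear stretch
#' additionally on low-contrast images), Canny edge extraction
#' restricted to the expanded screw boxes, Hough-guided edge
#' description with degree-2 polynomial fits, perpendicular
#' intensity-profile scanning for the two critical points per edge,
#' and conversion to resorption percentages, severity classes and
#' millimetres.
#'
#' @param image an [radiograph()] or a path readable by
#'   [read_image()].
#' @param detections an [detection_set()] or a path readable by
#'   [read_detections()].
#' @param config an [mbl_config()] (or a list of overrides).
#' @param known_length_mm optional physical implant length; when given
#'   it replaces the visible fitted span as the percentage denominator.
#' @param out optional path: the report is written there with
#'   [write_report()].
#' @return an `mbl_report` (see [build_report()]).
#' @export
analyze <- function(image, detections, config = mbl_config(),
                    known_length_mm = NULL, out = NULL) {
  config <- as_mbl_config(config)
  r <- if (inherits(image, "mbl_radiograph")) image
       else read_image(image, mm_per_px = config$mm_per_px)
  if (r$width != config$target_w || r$height != config$target_h) {
    sx <- config$target_w / r$width; sy <- config$target_h / r$height
    r <- resize_to_standard(r, config$target_w, config$target_h)
  } else sx <- sy <- 1
  d <- if (inherits(detections, "mbl_detections")) detections
       else read_detections(detections, image_width = r$width / sx,
                            image_height = r$height / sy,
                            score_min = config$score_min)
  if (sx != 1 || sy != 1) {
    d$boxes <- .clamp_boxes(scale_boxes(d$boxes, sx, sy),
                            r$width, r$height)
    d <- detection_set(d$boxes, image = d$image)
  }
  jaw <- d$jaw
  units <- associate_implants(d, jaw, overlap_min = config$overlap_min)
  if (length(units) == 0L)
    stop(mbl_error("no valid crown-screw association",
                   "mbl_gating_error"))
  quality <- contrast_quality(r, units, sigma_max = config$sigma_max,
                              threshold = config$contrast_threshold)
  enhanced <- r
  if (!quality$high_contrast) enhanced <- enhance_linear(enhanced)
  enhanced <- enhance_gamma(enhanced, config$gamma)
  em <- canny_edges(enhanced, sigma = config$canny$sigma,
                    high_pct = config$canny$high_pct,
                    low_ratio = config$canny$low_ratio,
                    high_floor = config$canny$high_floor)
  roi <- screw_roi_edges(em, units, expand = config$roi_expand,
                         se = config$dilate_se)
  edges <- describe_edges(roi, units, config)
  crowns <- do.call(rbind, lapply(units, function(u) u$crown_box))
  crowns <- as.data.frame(crowns)
  for (cn in c("x", "y", "w", "h")) crowns[[cn]] <- as.numeric(crowns[[cn]])
  pairs <- lapply(edges, function(e)
    detect_edge_critical_pair(enhanced, e, jaw, crowns = crowns,
                              verify_crown = config$verify_crown,
                              config = config))
  percents <- mapply(function(e, p)
    resorption_percentage(e, p, mm_per_px = config$mm_per_px,
                          known_length_mm = known_length_mm),
    edges, pairs, SIMPLIFY = FALSE)
  report <- build_report(if (is.character(image)) image else r$source_id,
                         jaw, quality, edges, pairs, percents,
                         mm_per_px = config$mm_per_px)
  if (!is.null(out)) write_report(report, out)
  report
}

# ground-truth fit for one annotated/phantom edge: either stored
# polynomial coefficients or control points fitted with the
# minimum-MSE degree (1-3)
.truth_fit <- function(e) {
  if (!is.null(e$coeffs))
    return(list(fit = list(degree = length(e$coeffs) - 1L,
                           coeffs = e$coeffs, mse = 0),
                y_range = c(e$y_min, e$y_max)))
  g <- list(pixels = data.frame(x = e$points[, 1], y = e$points[, 2]))
  list(fit = select_degree(g), y_range = range(e$points[, 2]))
}

#' Evaluate predicted reports against ground truth
#'
#' Pairs report and truth files (matched by their numeric suffix),
#' matches predicted edges to true edges by implant unit and side, and
#' summarizes: the edge-fit matching scores and their t tests
#' ([edge_fit_evaluation()]), the critical-point localization errors in
#' pixels and millimetres, and the batched resorption-percentage
#' errors ([resorption_error_batches()]) when enough measured pairs
#' exist.
#'
#' @param pred_dir directory of `report_*.json` files (or a list of
#'   `mbl_report` objects).
#' @param truth_dir directory of `truth_*.json` files (or a list of
#'   truth lists).
#' @param config an [mbl_config()].
#' @param n_batches batches for the percentage-error t tests.
#' @return `list(fit, points, resorption, n_images, n_edges_matched)`
#'   where `fit` is the [edge_fit_evaluation()] summary, `points` has
#'   `mean_error_px`, `sd_error_px`, `mean_error_mm` and per-point
#'   detail, and `resorption` is the [resorption_error_batches()]
#'   output (or `NULL`).
#' @export
evaluate_corpus <- function(pred_dir, truth_dir, config = mbl_config(),
                            n_batches = 10L) {
  config <- as_mbl_config(config)
  if (is.character(pred_dir)) {
    pf <- sort(list.files(pred_dir, "^report_.*\\.json$", full.names = TRUE))
    tf <- sort(list.files(truth_dir, "^truth_.*\\.json$", full.names = TRUE))
    key <- function(x) sub("^.*_([0-9]+)\\.json$", "\\1", basename(x))
    if (length(pf) == 0L || length(tf) == 0L)
      stop(mbl_error("no report/truth files found", "mbl_evaluation_error"))
    common <- intersect(key(pf), key(tf))
    orphans <- c(setdiff(key(pf), common), setdiff(key(tf), common))
    if (length(orphans) > 0L)
      stop(mbl_error(paste("unmatched report/truth files:",
                           paste(orphans, collapse = ", ")),
                     "mbl_evaluation_error"))
    reports <- lapply(pf[match(common, key(pf))], read_report)
    truths <- lapply(tf[match(common, key(tf))], read_truth)
  } else {
    reports <- pred_dir; truths <- truth_dir
  }
  stopifnot(length(reports) == length(truths))

  matches <- list(); pt_err <- numeric(0)
  A <- numeric(0); G <- numeric(0)
  n_edges <- 0L
  for (k in seq_along(reports)) {
    rep_k <- reports[[k]]; tr <- truths[[k]]
    tab <- rep_k$edges
    for (j in seq_len(nrow(tab))) {
      row <- tab[j, ]
      imp <- if (row$unit <= length(tr$implants)) tr$implants[[row$unit]]
             else NULL
      te <- imp$edges[[row$side]]
      if (is.null(te)) next
      n_edges <- n_edges + 1L
      gt <- .truth_fit(te)
      af <- list(degree = 2L, coeffs = c(row$a, row$b, row$c), mse = 0)
      m <- tryCatch(matching_score(gt$fit, af, gt$y_range,
                                   c(row$y_min, row$y_max)),
                    error = function(e) NULL)
      if (!is.null(m)) matches[[length(matches) + 1L]] <- m
      # critical-point localization error (detected vs true), px
      for (f in c("first", "second")) {
        tp <- te[[f]]
        dx <- row[[paste0("x_", f)]]; dy <- row[[paste0("y_", f)]]
        if (!is.null(tp) && !is.na(dx))
          pt_err <- c(pt_err, sqrt((dx - tp["x"])^2 + (dy - tp["y"])^2))
      }
      G <- c(G, te$resorption_pct)
      A <- c(A, row$percentage)
    }
  }
  fit <- if (length(matches) > 0L)
    edge_fit_evaluation(matches, alpha = config$alpha) else NULL
  resorp <- tryCatch(
    resorption_error_batches(A, G, n_batches = n_batches,
                             alpha = config$alpha),
    error = function(e) NULL)
  list(fit = fit,
       points = list(mean_error_px = if (length(pt_err)) mean(pt_err) else NA_real_,
                     sd_error_px = if (length(pt_err) > 1) sd(pt_err) else NA_real_,
                     mean_error_mm = if (length(pt_err))
                       px_to_mm(mean(pt_err), config$mm_per_px) else NA_real_,
                     n = length(pt_err)),
       resorption = resorp,
       n_images = length(reports), n_edges_matched = n_edges)
}
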