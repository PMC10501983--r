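#' Pipeline configuration
#'
#' Builds the configuration list consumed by [analyze()] and the
#' individual pipeline stages. Defaults are the operating point of the
#' measurement procedure: gamma 1.5 enhancement, 16 Hough peaks at 1 px /
#' 1 degree resolution, a 30 degree slope filter, 10% bounding-box
#' expansion, 3x3 and 1x5 structuring elements, a 10 px perpendicular
#' scan extent, 5-sample confirmation runs, a 0.5 detector-score cutoff,
#' 30% crown overlap, a 0.4 normalized-contrast threshold and a vertical
#' calibration of 0.063 mm per pixel.
#'
#' @param file optional YAML file with overrides (keys as below, nested
#'   sections `canny`, `hough`, `scan`).
#' @param ... named overrides, e.g. `gamma = 1.2`,
#'   `scan = list(extent = 12)`. Unknown keys are rejected.
#' @return a named list with class `mbl_config`.
#' @examples
#' cfg <- mbl_config(gamma = 1.2)
#' cfg$gamma
#' @export
mbl_config <- function(file = NULL, ...) {
  defaults <- list(
    target_w = 410L,
    target_h = 340L,
    mm_per_px = 0.063,
    score_min = 0.5,
    overlap_min = 0.3,
    sigma_max = 98,
    contrast_threshold = 0.4,
    gamma = 1.5,
    canny = list(sigma = sqrt(2), high_pct = 0.90, low_ratio = 0.4,
                 high_floor = 0.15),
    roi_expand = 0.10,
    dilate_se = c(3L, 3L),
    hough = list(n_peaks = 16L, min_votes = 15L, nhood = c(5L, 5L)),
    slope_min_deg = 30,
    line_band = 2,
    min_seg_len = 10,
    max_gap = 3,
    min_group_px = 30L,
    fit_trim = 3,
    scan = list(start_offset = 3, extent = 10L, persist = 3L,
                run_len = 5L, run_factor = 1.0, min_drop = 30,
                min_rise = 10, extend_px = 60L),
    verify_crown = FALSE,
    alpha = 0.05
  )
  cfg <- defaults
  apply_over <- function(cfg, over, where = "") {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0L)
      stop("unknown config key", if (nzchar(where)) paste0(" in '", where, "'"),
           ": ", paste(bad, collapse = ", "), call. = FALSE)
    for (k in names(over)) {
      if (is.list(cfg[[k]]) && is.list(over[[k]]))
        cfg[[k]] <- apply_over(cfg[[k]], over[[k]], k)
      else cfg[[k]] <- over[[k]]
    }
    cfg
  }
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.null(y)) cfg <- apply_over(cfg, y)
  }
  over <- list(...)
  if (length(over) > 0L) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("config overrides must be named")
    cfg <- apply_over(cfg, over)
  }
  structure(cfg, class = "mbl_config")
}

as_mbl_config <- function(config) {
  if (inherits(config, "mbl_config")) return(config)
  if (is.null(config)) return(mbl_config())
  if (is.list(config)) return(do.call(mbl_config, config))
  stop("config must be NULL, a list, or an mbl_config object")
}
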