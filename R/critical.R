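# Critical-point detection along fitted screw edges. The edge curve is
# traversed from the apical end toward the crown; at each step the mean
# intensity is sampled on both sides of the edge along the normal of
# the straight-line fit, and the accumulated profile Cum takes the
# darker flank (D = L - R; Cum = L if D < 0, else R). The first
# critical point is the abrupt drop of Cum below its mean (onset of the
# bone defect); the second is where the profile rises above the
# reference level R_av on both flanks, i.e. full entry into the crown.

#' Bilinear intensity sampling
#'
#' @param px intensity matrix (rows = y, cols = x).
#' @param x,y 0-based sample coordinates (vectors); clamped to the
#'   image borders.
#' @return interpolated intensities.
#' @export
bilinear_sample <- function(px, x, y) {
  h <- nrow(px); w <- ncol(px)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- px[cbind(y0 + 1, x0 + 1)]
  i01 <- px[cbind(y0 + 1, x1 + 1)]
  i10 <- px[cbind(y1 + 1, x0 + 1)]
  i11 <- px[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# profile records for arbitrary y positions along an edge curve
.profile_rows <- function(r, edge, ys, start_offset, extent) {
  b1 <- edge$line$coeffs[2]            # straight-line fit x = a1 + b1*y
  nrm <- c(1, -b1) / sqrt(1 + b1^2)    # unit normal, +x pointing (right)
  xs <- eval_poly(edge$curve, ys)
  ks <- start_offset + seq_len(extent) - 1
  n <- length(ys)
  # sample grids: rows = steps, cols = offsets
  Lx <- outer(xs, -ks * nrm[1], `+`); Ly <- outer(ys, -ks * nrm[2], `+`)
  Rx <- outer(xs, ks * nrm[1], `+`);  Ry <- outer(ys, ks * nrm[2], `+`)
  L <- rowMeans(matrix(bilinear_sample(r$pixels, as.vector(Lx),
                                       as.vector(Ly)), n))
  R <- rowMeans(matrix(bilinear_sample(r$pixels, as.vector(Rx),
                                       as.vector(Ry)), n))
  D <- L - R
  data.frame(y = ys, x = xs, L = L, R = R, D = D,
             cum = ifelse(D < 0, L, R))
}

#' Perpendicular intensity-profile scan along an edge
#'
#' Traverses the fitted curve from the apical end (the group's maximum
#' y for lower-jaw implants, minimum y for upper) toward the coronal
#' end in unit y steps. At each step, `extent` intensity samples per
#' side are read by bilinear interpolation along the unit normal of the
#' straight-line fit, starting `start_offset` pixels away from the
#' curve so the bright edge itself is not sampled; `L` and `R` are the
#' side means, `D = L - R`, and the accumulated profile takes the
#' darker flank: `Cum = L` if `D < 0`, else `R`.
#'
#' @param r an [radiograph()] (the enhanced image used for edge
#'   extraction).
#' @param edge a fitted edge from [describe_edges()].
#' @param jaw `"lower"` or `"upper"`; sets the traversal direction.
#' @param start_offset first sampling distance from the curve, pixels.
#' @param extent number of samples per side (about 2.5% of the image
#'   width at the standard 410 px resolution).
#' @return data frame with one row per step and columns `step` (0-based
#'   traversal index), `y`, `x`, `L`, `R`, `D`, `cum`; traversal
#'   direction is attached as attribute `"dir"` (-1 when y decreases).
#' @export
scan_profile <- function(r, edge, jaw = c("lower", "upper"),
                         start_offset = 3, extent = 10L) {
  jaw <- match.arg(jaw)
  stopifnot(inherits(r, "mbl_radiograph"))
  ys <- if (jaw == "lower") seq(edge$y_max, edge$y_min) else
    seq(edge$y_min, edge$y_max)
  xs <- eval_poly(edge$curve, ys)
  outside <- xs < 0 | xs > r$width - 1 | ys < 0 | ys > r$height - 1
  if (mean(outside) > 0.5)
    stop(mbl_error("fitted curve leaves the image for most of the scan",
                   "mbl_scan_error"))
  prof <- .profile_rows(r, edge, ys, start_offset, extent)
  prof <- cbind(step = seq_len(nrow(prof)) - 1L, prof)
  attr(prof, "dir") <- if (jaw == "lower") -1L else 1L
  prof
}

# first index (1-based row) opening a run of `len` consecutive TRUEs
.first_run <- function(flag, len) {
  if (len <= 1L) return(if (any(flag)) which(flag)[1L] else NA_integer_)
  n <- length(flag)
  if (n < len) return(NA_integer_)
  run <- stats::filter(as.numeric(flag), rep(1, len), sides = 1)
  hit <- which(run == len)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L] - len + 1L
}

#' First critical point: onset of the bone defect
#'
#' Finds the first traversal position where the `Cum` profile drops
#' abruptly to its dark level and stays there. The profile values are
#' split into a bright (bone) and a dark (defect/soft-tissue) level by
#' an Otsu two-class partition; the statistical-mean threshold is the
#' midpoint of the two class means, which coincides with the profile
#' mean for a balanced two-level profile. The detected step `p` opens
#' the first run of `persist` consecutive samples below the threshold.
#' When the two levels are separated by less than `min_drop` gray
#' levels the profile is considered flat - noise and bone texture alone
#' do not constitute tissue degradation - and no point is returned.
#'
#' @param scan a [scan_profile()] data frame.
#' @param edge the fitted edge the scan belongs to.
#' @param persist consecutive samples required below the threshold.
#' @param min_drop minimum separation between the bright and dark
#'   profile levels, gray levels.
#' @return `list(x, y, p)` with `p` the 0-based traversal index, or
#'   `NULL` when no abrupt drop exists (no measurable resorption).
#' @export
first_critical_point <- function(scan, edge, persist = 3L, min_drop = 30) {
  if (nrow(scan) < 10L) stop("scan must have at least 10 steps")
  sp <- .otsu_split(scan$cum)
  if (is.null(sp) || sp$gap < min_drop) return(NULL)
  # the critical point is a drop FROM the initial (healthy bone)
  # level: the traversal must start in the bright class, otherwise the
  # partition reflects some other structure (e.g. residual crown
  # brightening) and no degradation onset exists
  if (mean(scan$cum[seq_len(min(5L, nrow(scan)))]) < sp$tau) return(NULL)
  # at the onset the profile reaches the dark (defect) level, not just
  # the class boundary: candidates whose first samples average above
  # the midpoint between the dark mean and the threshold are shallow
  # bands (bone texture, vessels) and are skipped
  n <- nrow(scan)
  below <- scan$cum < sp$tau
  deep <- (sp$mu_lo + sp$tau) / 2
  pos <- 1L
  row <- NA_integer_
  while (pos <= n - persist + 1L) {
    cand <- .first_run(below[pos:n], persist)
    if (is.na(cand)) break
    cand <- cand + pos - 1L
    if (mean(scan$cum[cand:min(n, cand + 4L)]) <= deep) { row <- cand; break }
    pos <- cand + 1L
  }
  if (is.na(row)) return(NULL)
  y_f <- scan$y[row]
  list(x = eval_poly(edge$curve, y_f), y = y_f, p = scan$step[row])
}

# Otsu split of a numeric vector: threshold tau maximizing the
# between-class variance. Each class must hold at least `min_share` of
# the samples (and 3 absolute), so a couple of stray bright or dark
# samples cannot define a level of their own.
.otsu_split <- function(v, min_share = 0.05) {
  n <- length(v)
  minn <- max(3L, ceiling(min_share * n))
  if (n < 2L * minn) return(NULL)
  vs <- sort(v)
  cs <- cumsum(vs)
  k <- seq.int(minn, n - minn)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  bc <- k * (n - k) * (m2 - m1)^2
  i <- which.max(bc)
  list(tau = (m1[i] + m2[i]) / 2, gap = m2[i] - m1[i],
       mu_lo = m1[i], mu_hi = m2[i])
}

#' Reference intensity level after the first critical point
#'
#' Averages the five `Cum` values immediately after the detected drop
#' (traversal indices `p + 1` to `p + 5`), giving the reference level
#' `R_av` of the defect region against which crown entry is judged.
#'
#' @param scan a [scan_profile()] data frame.
#' @param p 0-based traversal index of the first critical point.
#' @param n number of samples averaged.
#' @return the reference level `r_av`.
#' @export
reference_level <- function(scan, p, n = 5L) {
  rows <- which(scan$step > p)
  if (length(rows) < n)
    stop(mbl_error("fewer than 5 samples after the first critical point",
                   "mbl_scan_error"))
  mean(scan$cum[rows[seq_len(n)]])
}

#' Second critical point: entry into the crown
#'
#' Continues the traversal past the first critical point and declares
#' crown entry at the first run of `run_len` consecutive profile values
#' all above `r_av * run_factor + min_rise`. The profile value remains
#' the darker-flank `Cum`: it only clears the reference level once both
#' flanks are bright, which is exactly full entry into the crown (at
#' the junction the darker flank switches sides, L to R for a left
#' edge). The second point's y is the first sample of that run.
#'
#' Because the fitted group ends at the screw-crown junction, the
#' traversal may be extended beyond the group's coronal end along the
#' extrapolated curve, by at most `extend_px` rows and never past
#' `coronal_limit` (e.g. the far edge of the crown box) or the image
#' border.
#'
#' @param r the [radiograph()] being scanned.
#' @param edge the fitted edge.
#' @param scan the [scan_profile()] data frame.
#' @param p 0-based traversal index of the first critical point.
#' @param r_av reference level from [reference_level()].
#' @param run_len consecutive samples required above the threshold.
#' @param run_factor multiplier on `r_av`.
#' @param min_rise additive margin above `r_av`, gray levels.
#' @param extend_px maximum traversal extension beyond the scan,
#'   pixels.
#' @param coronal_limit optional y bound for the extension (minimum y
#'   for lower jaw, maximum for upper).
#' @param start_offset,extent sampling geometry, as in
#'   [scan_profile()].
#' @return `list(x, y, p)` (`p` = 0-based traversal index), or `NULL`
#'   when the profile never clears the threshold.
#' @export
second_critical_point <- function(r, edge, scan, p, r_av,
                                  run_len = 5L, run_factor = 1.0,
                                  min_rise = 10, extend_px = 60L,
                                  coronal_limit = NULL,
                                  start_offset = 3, extent = 10L) {
  dir <- attr(scan, "dir")
  if (is.null(dir)) dir <- if (scan$y[1] > scan$y[nrow(scan)]) -1L else 1L
  after <- scan[scan$step > p, , drop = FALSE]
  vals <- after$cum
  ys_all <- after$y
  if (extend_px > 0L && nrow(scan) > 0L) {
    y_end <- scan$y[nrow(scan)]
    lim <- if (dir < 0L) max(0, if (is.null(coronal_limit)) 0 else coronal_limit)
           else min(r$height - 1, if (is.null(coronal_limit)) r$height - 1 else coronal_limit)
    ys_ext <- if (dir < 0L) seq(y_end - 1, max(lim, y_end - extend_px))
              else seq(y_end + 1, min(lim, y_end + extend_px))
    ys_ext <- ys_ext[ys_ext >= 0 & ys_ext <= r$height - 1]
    if (length(ys_ext) > 0L && (dir < 0L) == (ys_ext[1] < y_end)) {
      ext <- .profile_rows(r, edge, ys_ext, start_offset, extent)
      vals <- c(vals, ext$cum)
      ys_all <- c(ys_all, ext$y)
    }
  }
  if (length(vals) == 0L) return(NULL)
  row <- .first_run(vals > r_av * run_factor + min_rise, run_len)
  if (is.na(row)) return(NULL)
  y_s <- ys_all[row]
  list(x = eval_poly(edge$curve, y_s), y = y_s, p = p + row)
}

#' Detect the critical pair of an edge
#'
#' Composes [scan_profile()], [first_critical_point()],
#' [reference_level()] and [second_critical_point()] into the full
#' per-edge landmark detection. The result status is `"both"` when the
#' defect onset and the crown entry were found, `"first_only"` when
#' only the onset was (insufficient profile after the drop, no crown
#' brightening, or a failed crown-box verification), and `"none"` for a
#' flat profile with no measurable resorption.
#'
#' @param r the [radiograph()] to scan (enhanced image).
#' @param edge a fitted edge from [describe_edges()].
#' @param jaw `"lower"` or `"upper"`.
#' @param crowns optional data frame of crown boxes; used to bound the
#'   coronal extension and, with `verify_crown`, to confirm the second
#'   point.
#' @param verify_crown when `TRUE`, a second point falling inside no
#'   crown box downgrades the status to `"first_only"`.
#' @param config an [mbl_config()].
#' @return `list(first, second, r_av, status, scan)`; `first`/`second`
#'   are `list(x, y, p)` or `NULL`.
#' @export
detect_edge_critical_pair <- function(r, edge, jaw, crowns = NULL,
                                      verify_crown = FALSE,
                                      config = mbl_config()) {
  config <- as_mbl_config(config)
  sc <- config$scan
  scan <- scan_profile(r, edge, jaw, start_offset = sc$start_offset,
                       extent = sc$extent)
  # the tissue profile ends at the crown: when the fitted group
  # overruns the screw-crown junction, rows falling inside a crown box
  # would pull the two-level split toward the bright crown level, so
  # the scan is truncated at the first row inside a crown
  if (!is.null(crowns) && nrow(crowns) > 0L) {
    dir <- attr(scan, "dir")
    inside <- vapply(seq_len(nrow(scan)), function(i)
      any(scan$x[i] >= crowns$x & scan$x[i] < crowns$x + crowns$w &
          scan$y[i] >= crowns$y & scan$y[i] < crowns$y + crowns$h),
      logical(1))
    if (any(inside) && which(inside)[1L] > 10L) {
      scan <- scan[seq_len(which(inside)[1L] - 1L), , drop = FALSE]
      attr(scan, "dir") <- dir
    }
  }
  fp <- first_critical_point(scan, edge, persist = sc$persist,
                             min_drop = sc$min_drop)
  if (is.null(fp))
    return(list(first = NULL, second = NULL, r_av = NA_real_,
                status = "none", scan = scan))
  r_av <- tryCatch(reference_level(scan, fp$p),
                   error = function(e) NA_real_)
  if (is.na(r_av))
    return(list(first = fp, second = NULL, r_av = NA_real_,
                status = "first_only", scan = scan))
  lim <- NULL
  if (!is.null(crowns) && nrow(crowns) > 0L)
    lim <- if (jaw == "lower") min(crowns$y) else max(crowns$y + crowns$h)
  sp <- second_critical_point(r, edge, scan, fp$p, r_av,
                              run_len = sc$run_len,
                              run_factor = sc$run_factor,
                              min_rise = sc$min_rise,
                              extend_px = sc$extend_px,
                              coronal_limit = lim,
                              start_offset = sc$start_offset,
                              extent = sc$extent)
  status <- if (is.null(sp)) "first_only" else "both"
  if (!is.null(sp) && verify_crown && !is.null(crowns) && nrow(crowns) > 0L) {
    inside <- any(sp$x >= crowns$x & sp$x < crowns$x + crowns$w &
                  sp$y >= crowns$y & sp$y < crowns$y + crowns$h)
    if (!inside) {
      warning("second critical point outside every crown box; ",
              "downgraded to first_only")
      sp <- NULL
      status <- "first_only"
    }
  }
  list(first = fp, second = sp, r_av = r_av, status = status, scan = scan)
}
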