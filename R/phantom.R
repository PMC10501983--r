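# Synthetic radiograph phantoms with full ground truth. A phantom
# emulates the structures the measurement pipeline relies on: a bright
# threaded screw with smooth near-vertical side edges (degree-2
# polynomials plus a sinusoidal thread perturbation), a brighter crown
# adjacent at the coronal end and overhanging the screw, textured bone
# of intermediate intensity flanking the screw from the defect apex
# down, and a darker soft-tissue/defect region whose per-side extent
# encodes a known resorption percentage.

#' Specify a synthetic radiograph phantom
#'
#' Defaults reflect the standard working resolution (410 x 340 px) and
#' a 10 mm implant at 0.063 mm/px (about 160 px long). Intensities obey
#' the clinical ordering crown >= screw > bone > defect/soft tissue.
#'
#' @param width,height image size in pixels.
#' @param jaw `"lower"` or `"upper"` (upper phantoms are vertical
#'   mirrors of lower ones).
#' @param implants optional data frame with one row per implant and
#'   columns `cx_apex`, `y_apex`, `length`, `width`, `rotation`,
#'   `defect_left`, `defect_right`; when omitted a single centred
#'   implant is built from the scalar arguments below.
#' @param length_px,width_px screw length and coronal width, pixels.
#' @param rotation_deg inclination from vertical, degrees (clinically
#'   within about +-10).
#' @param defect_fraction per-side bone-defect extent as a fraction of
#'   the screw length, in `[0, 1]`; length 1 or 2 (left, right).
#' @param apex_taper apex half-width as a fraction of the coronal
#'   half-width.
#' @param side_bulge outward mid-screw bulge of each edge, pixels (the
#'   curvature the degree-2 fit must capture).
#' @param thread_amplitude,thread_period sinusoidal thread perturbation
#'   of the rendered edge, pixels.
#' @param crown_height crown height, pixels.
#' @param crown_overhang lateral crown overhang beyond the screw,
#'   pixels.
#' @param bone_flank width of the bone slab flanking the screw, pixels.
#' @param intensity named list with gray levels `crown`, `screw`,
#'   `bone`, `defect`.
#' @param noise_sd global Gaussian noise, gray levels.
#' @param texture_sd amplitude of the low-pass bone texture, gray
#'   levels.
#' @param mm_per_px vertical calibration attached to the rendered
#'   radiograph.
#' @param seed RNG seed making the rendering deterministic.
#' @return a `mbl_phantom_spec` list.
#' @export
phantom_spec <- function(width = 410L, height = 340L,
                         jaw = c("lower", "upper"),
                         implants = NULL,
                         length_px = 160, width_px = 38,
                         rotation_deg = 0,
                         defect_fraction = 0.2,
                         apex_taper = 0.55,
                         side_bulge = 1.5,
                         thread_amplitude = 2, thread_period = 8,
                         crown_height = 45, crown_overhang = 15,
                         bone_flank = 30,
                         intensity = list(crown = 235, screw = 205,
                                          bone = 112, defect = 55),
                         noise_sd = 6, texture_sd = 12,
                         mm_per_px = 0.063,
                         seed = 1L) {
  jaw <- match.arg(jaw)
  if (any(defect_fraction < 0 | defect_fraction > 1))
    stop("defect_fraction must lie in [0, 1]")
  if (length(defect_fraction) == 1L)
    defect_fraction <- rep(defect_fraction, 2L)
  if (is.null(implants)) {
    implants <- data.frame(
      cx_apex = width / 2,
      y_apex = round(height * 0.74),
      length = length_px, width = width_px, rotation = rotation_deg,
      defect_left = defect_fraction[1], defect_right = defect_fraction[2])
  }
  with(intensity, stopifnot(crown >= screw, screw > bone, bone > defect))
  for (i in seq_len(nrow(implants))) {
    if (implants$y_apex[i] - implants$length[i] - crown_height < 0 ||
        implants$y_apex[i] > height - 1)
      stop("implant geometry exceeds the image vertically")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 jaw = jaw, implants = implants,
                 apex_taper = apex_taper, side_bulge = side_bulge,
                 thread_amplitude = thread_amplitude,
                 thread_period = thread_period,
                 crown_height = crown_height,
                 crown_overhang = crown_overhang,
                 bone_flank = bone_flank, intensity = intensity,
                 noise_sd = noise_sd, texture_sd = texture_sd,
                 mm_per_px = mm_per_px, seed = as.integer(seed)),
            class = "mbl_phantom_spec")
}

# exact quadratic through three (y, x) points
.quad_through <- function(ys, xs) {
  solve(outer(ys, 0:2, `^`), xs)
}

.poly_val <- function(co, y) drop(outer(y, seq_along(co) - 1L, `^`) %*% co)

#' Render a phantom radiograph with ground truth
#'
#' Deterministic given the spec's seed. The returned truth stores, per
#' implant and side, the smooth baseline edge polynomial (the thread
#' perturbation oscillates around it), the true critical points (defect
#' onset and screw-crown junction), the true resorption percentage, and
#' the tight crown/screw bounding boxes.
#'
#' @param spec a [phantom_spec()].
#' @return `list(radiograph, truth)`; `truth` is a list with `jaw`,
#'   `width`, `height` and `implants`, each implant holding
#'   `screw_box`, `crown_box` and `edges$left`/`edges$right` with
#'   `coeffs`, `y_min`, `y_max`, `first`, `second`, `resorption_pct`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "mbl_phantom_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  w <- spec$width; h <- spec$height
  ity <- spec$intensity
  px <- matrix(ity$defect, h, w)       # soft tissue / defect background
  bone_mask <- matrix(FALSE, h, w)
  implants <- list()

  for (i in seq_len(nrow(spec$implants))) {
    im <- spec$implants[i, ]
    L <- im$length
    y_apex <- round(im$y_apex); y_top <- round(y_apex - L)
    s <- tan(im$rotation * pi / 180)
    center <- function(y) im$cx_apex + s * (y_apex - y)
    hw_top <- im$width / 2
    hw_apex <- hw_top * spec$apex_taper
    y_mid <- (y_top + y_apex) / 2
    ys3 <- c(y_top, y_mid, y_apex)
    co_l <- .quad_through(ys3, c(center(y_top) - hw_top,
                                 center(y_mid) - (hw_top + hw_apex) / 2 -
                                   spec$side_bulge,
                                 center(y_apex) - hw_apex))
    co_r <- .quad_through(ys3, c(center(y_top) + hw_top,
                                 center(y_mid) + (hw_top + hw_apex) / 2 +
                                   spec$side_bulge,
                                 center(y_apex) + hw_apex))
    ys <- y_top:y_apex
    lx <- .poly_val(co_l, ys)
    rx <- .poly_val(co_r, ys)
    delta <- spec$thread_amplitude * sin(2 * pi * (ys - y_top) /
                                           spec$thread_period)
    y_def_l <- round(y_top + im$defect_left * L)
    y_def_r <- round(y_top + im$defect_right * L)

    # bone slabs, clipped to the image; the screw fill overwrites them
    for (k in seq_along(ys)) {
      y <- ys[k]; row <- y + 1L
      cl <- round(center(y))
      if (y >= y_def_l) {
        c1 <- max(0L, round(lx[k]) - spec$bone_flank)
        if (cl >= c1) { px[row, (c1 + 1):(cl + 1)] <- ity$bone
                        bone_mask[row, (c1 + 1):(cl + 1)] <- TRUE }
      }
      if (y >= y_def_r) {
        c2 <- min(w - 1L, round(rx[k]) + spec$bone_flank)
        if (c2 >= cl) { px[row, (cl + 1):(c2 + 1)] <- ity$bone
                        bone_mask[row, (cl + 1):(c2 + 1)] <- TRUE }
      }
    }
    # bone below the apex
    for (y in seq_len(min(h - 1L, y_apex + 12L) - y_apex) + y_apex) {
      c1 <- max(0L, round(.poly_val(co_l, y_apex)) - spec$bone_flank)
      c2 <- min(w - 1L, round(.poly_val(co_r, y_apex)) + spec$bone_flank)
      px[y + 1L, (c1 + 1):(c2 + 1)] <- ity$bone
      bone_mask[y + 1L, (c1 + 1):(c2 + 1)] <- TRUE
    }
    # threaded screw body
    for (k in seq_along(ys)) {
      c1 <- max(0L, round(lx[k] - delta[k]))
      c2 <- min(w - 1L, round(rx[k] + delta[k]))
      if (c2 >= c1) px[ys[k] + 1L, (c1 + 1):(c2 + 1)] <- ity$screw
    }
    # crown, overhanging the screw laterally
    cx1 <- max(0L, round(center(y_top) - hw_top - spec$crown_overhang))
    cx2 <- min(w - 1L, round(center(y_top) + hw_top + spec$crown_overhang))
    cy1 <- max(0L, y_top - spec$crown_height)
    px[(cy1 + 1):y_top, (cx1 + 1):(cx2 + 1)] <- ity$crown
    bone_mask[(cy1 + 1):y_top, (cx1 + 1):(cx2 + 1)] <- FALSE

    sx1 <- floor(min(lx) - spec$thread_amplitude)
    sx2 <- ceiling(max(rx) + spec$thread_amplitude)
    edge_truth <- function(co, f, y_def) {
      first <- second <- NULL
      if (f > 0) {
        first <- c(x = .poly_val(co, y_def), y = y_def)
        second <- c(x = .poly_val(co, y_top), y = y_top)
      }
      list(coeffs = as.numeric(co), y_min = y_top, y_max = y_apex,
           first = first, second = second, resorption_pct = 100 * f)
    }
    implants[[i]] <- list(
      screw_box = list(x = sx1, y = y_top, w = sx2 - sx1,
                       h = y_apex - y_top + 1L),
      crown_box = list(x = cx1, y = cy1, w = cx2 - cx1 + 1L,
                       h = y_top - cy1),
      edges = list(left = edge_truth(co_l, im$defect_left, y_def_l),
                   right = edge_truth(co_r, im$defect_right, y_def_r)))
  }

  # bone texture: low-pass Gaussian noise confined to the bone slabs
  if (spec$texture_sd > 0 && any(bone_mask)) {
    tex <- .conv2_replicate(matrix(rnorm(h * w), h, w),
                            .gaussian_kernel2d(1.5))
    tex <- tex / sd(as.vector(tex)) * spec$texture_sd
    px[bone_mask] <- px[bone_mask] + tex[bone_mask]
  }
  if (spec$noise_sd > 0) px <- px + rnorm(h * w, sd = spec$noise_sd)
  px <- round(pmin(pmax(px, 0), 255))

  truth <- list(jaw = spec$jaw, width = w, height = h,
                mm_per_px = spec$mm_per_px, implants = implants)
  if (spec$jaw == "upper") {
    px <- px[h:1, , drop = FALSE]
    truth$implants <- lapply(truth$implants, .flip_implant_truth, h = h)
  }
  list(radiograph = radiograph(px, mm_per_px = spec$mm_per_px,
                               source_id = sprintf("phantom_seed%d", spec$seed)),
       truth = truth)
}

# vertical mirror of one implant's truth (y -> h-1-y)
.flip_implant_truth <- function(imp, h) {
  H <- h - 1
  flip_edge <- function(e) {
    co <- e$coeffs
    e$coeffs <- c(co[1] + co[2] * H + co[3] * H^2,
                  -(co[2] + 2 * co[3] * H), co[3])
    yr <- c(H - e$y_max, H - e$y_min)
    e$y_min <- yr[1]; e$y_max <- yr[2]
    for (f in c("first", "second"))
      if (!is.null(e[[f]])) e[[f]]["y"] <- H - e[[f]]["y"]
    e
  }
  flip_box <- function(b) { b$y <- h - b$y - b$h; b }
  imp$screw_box <- flip_box(imp$screw_box)
  imp$crown_box <- flip_box(imp$crown_box)
  imp$edges <- lapply(imp$edges, flip_edge)
  imp
}

#' Emit detector-like bounding boxes for a phantom
#'
#' Stands in for the object-detection stage: the true boxes are
#' perturbed by uniform corner jitter and given confidence scores drawn
#' uniformly from `score_range`.
#'
#' @param truth phantom truth from [render_phantom()].
#' @param jitter maximum absolute corner displacement, pixels.
#' @param score_range `c(lo, hi)` for the confidence scores.
#' @param path optional JSON output path (dialect of
#'   [read_detections()]).
#' @param seed RNG seed for the jitter and scores.
#' @return an [detection_set()] (written to `path` when given).
#' @export
emit_detections <- function(truth, jitter = 0, score_range = c(0.8, 0.99),
                            path = NULL, seed = 1L) {
  stopifnot(jitter >= 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rows <- list()
  for (imp in truth$implants) {
    for (lab in c("screw", "crown")) {
      b <- imp[[paste0(lab, "_box")]]
      x1 <- b$x + round(runif(1, -jitter, jitter))
      y1 <- b$y + round(runif(1, -jitter, jitter))
      x2 <- b$x + b$w + round(runif(1, -jitter, jitter))
      y2 <- b$y + b$h + round(runif(1, -jitter, jitter))
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, x = x1, y = y1,
        w = max(4, x2 - x1), h = max(4, y2 - y1),
        score = runif(1, score_range[1], score_range[2]),
        stringsAsFactors = FALSE)
    }
  }
  boxes <- .clamp_boxes(do.call(rbind, rows), truth$width, truth$height)
  d <- detection_set(boxes)
  if (!is.null(path)) write_detections(d, path)
  d
}

#' Write phantom truth to JSON
#' @param truth truth list from [render_phantom()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read phantom truth back from JSON
#' @param path file written by [write_truth()].
#' @return the truth list.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  tr$implants <- lapply(tr$implants, function(imp) {
    imp$edges <- lapply(imp$edges, function(e) {
      e$coeffs <- as.numeric(e$coeffs)
      for (f in c("first", "second"))
        if (!is.null(e[[f]])) {
          v <- as.numeric(unlist(e[[f]]))
          names(v) <- c("x", "y")
          e[[f]] <- v
        }
      e
    })
    imp
  })
  tr
}

#' Generate a directory of phantom/detections/truth triples
#'
#' Each triple is a PNG radiograph, a detections JSON (jittered true
#' boxes with detector-like scores) and a truth JSON. Difficulty
#' presets: `"easy"` uses the default high-contrast intensities;
#' `"low_contrast"` compresses the gray levels so the normalized
#' contrast falls below the 0.4 threshold; `"rotated"` draws the
#' implant inclination uniformly in +-10 degrees. Per-side defect
#' fractions are drawn uniformly from `defect_range` unless a fixed
#' `defect_fraction` is supplied (0 renders healthy bone with no
#' defect).
#'
#' @param n number of triples.
#' @param seed master seed; per-image seeds are derived from it.
#' @param difficulty `"easy"`, `"low_contrast"` or `"rotated"`.
#' @param out_dir output directory (created).
#' @param defect_fraction fixed per-side defect fraction, or `NULL` to
#'   draw from `defect_range`.
#' @param defect_range range for drawn defect fractions.
#' @param jitter detection box jitter in pixels.
#' @param jaw jaw side, or `"both"` to alternate.
#' @return manifest data frame with the file names, seeds and true
#'   defect fractions.
#' @export
make_suite <- function(n, seed = 1L,
                       difficulty = c("easy", "low_contrast", "rotated"),
                       out_dir, defect_fraction = NULL,
                       defect_range = c(0.1, 0.5), jitter = 2,
                       jaw = "lower") {
  stopifnot(n >= 1)
  difficulty <- match.arg(difficulty)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sub_seeds <- sample.int(2^30, n + 1L)
  rows <- list()
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    f <- if (!is.null(defect_fraction)) rep(defect_fraction, 2)[1:2]
         else runif(2, defect_range[1], defect_range[2])
    rot <- if (difficulty == "rotated") runif(1, -10, 10) else 0
    ity <- if (difficulty == "low_contrast")
      list(crown = 160, screw = 150, bone = 122, defect = 100)
    else list(crown = 235, screw = 205, bone = 112, defect = 55)
    this_jaw <- if (jaw == "both") c("lower", "upper")[(i %% 2) + 1] else jaw
    spec <- phantom_spec(jaw = this_jaw, rotation_deg = rot,
                         defect_fraction = f, intensity = ity,
                         noise_sd = if (difficulty == "low_contrast") 5 else 6,
                         texture_sd = if (difficulty == "low_contrast") 6 else 12,
                         seed = sub_seeds[i])
    ph <- render_phantom(spec)
    img <- file.path(out_dir, sprintf("img_%03d.png", i))
    det <- file.path(out_dir, sprintf("det_%03d.json", i))
    tru <- file.path(out_dir, sprintf("truth_%03d.json", i))
    write_image(ph$radiograph, img)
    emit_detections(ph$truth, jitter = jitter, path = det,
                    seed = sub_seeds[i] + 1L)
    write_truth(ph$truth, tru)
    rows[[i]] <- data.frame(image = img, detections = det, truth = tru,
                            seed = sub_seeds[i], jaw = this_jaw,
                            rotation = rot, defect_left = f[1],
                            defect_right = f[2], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
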