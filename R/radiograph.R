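#' Radiograph container
#'
#' A radiograph is stored as a numeric matrix of 8-bit intensities in
#' `[0, 255]`, rows indexing the vertical (y) direction and columns the
#' horizontal (x) direction, together with the vertical calibration in
#' millimetres per pixel. Throughout the package, pixel coordinates are
#' 0-based with the origin at the upper-left corner and y growing
#' downward; pixel `(x, y)` corresponds to matrix element
#' `pixels[y + 1, x + 1]`.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param mm_per_px vertical calibration, millimetres per pixel (> 0).
#' @param source_id free-text identifier (e.g. the file the image came
#'   from).
#' @return an object of class `mbl_radiograph` with elements `pixels`,
#'   `width`, `height`, `mm_per_px`, `source_id`.
#' @export
radiograph <- function(pixels, mm_per_px = 0.063, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("radiograph must have width >= 1 and height >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L || mm_per_px <= 0)
    stop("mm_per_px must be a positive scalar")
  structure(
    list(pixels = pixels, width = ncol(pixels), height = nrow(pixels),
         mm_per_px = mm_per_px, source_id = as.character(source_id)),
    class = "mbl_radiograph")
}

#' @export
print.mbl_radiograph <- function(x, ...) {
  cat(sprintf("<mbl_radiograph> %dx%d px, %.3f mm/px, source='%s'\n",
              x$width, x$height, x$mm_per_px, x$source_id))
  invisible(x)
}

#' Read a radiograph from a JPEG or PNG file
#'
#' Colour inputs are collapsed to a single channel with an unweighted
#' channel mean (radiographs are effectively monochrome, so no luminance
#' weighting is applied).
#'
#' @param path path to a JPEG or PNG file.
#' @param mm_per_px vertical calibration to attach (mm per pixel).
#' @return an [radiograph()] object.
#' @export
read_image <- function(path, mm_per_px = 0.063) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (file.size(path) == 0) stop("image file is empty: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- rowMeans(dat, dims = 2L)
  px <- t(dat) * 255
  px[px < 0] <- 0; px[px > 255] <- 255
  radiograph(px, mm_per_px = mm_per_px, source_id = basename(path))
}

#' Write a radiograph to an image file
#'
#' @param r an [radiograph()] object.
#' @param path output path; format chosen from the extension (.png or
#'   .jpg).
#' @return `path`, invisibly.
#' @export
write_image <- function(r, path) {
  stopifnot(inherits(r, "mbl_radiograph"))
  EBImage::writeImage(EBImage::Image(t(r$pixels) / 255), path)
  invisible(path)
}

# Keys cubic interpolation kernel (a = -0.5), the standard bicubic choice.
.cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# Row-interpolation weight matrix (n_out x n_in), border-replicated.
.cubic_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * scale - 0.5       # 0-based source position
    base <- floor(s)
    for (k in -1:2) {
      j <- base + k
      w <- .cubic_kernel(s - j)
      j <- min(max(j, 0), n_in - 1)    # replicate borders
      W[i, j + 1] <- W[i, j + 1] + w
    }
  }
  W
}

#' Resize a radiograph by bicubic interpolation
#'
#' Resamples to the standard working resolution (410 x 340 by default)
#' with a separable Keys bicubic kernel and border replication. Output is
#' clamped to `[0, 255]`. Bounding boxes belonging to the image must be
#' rescaled alongside with [scale_boxes()] using the same factors
#' `target_w / width` and `target_h / height`.
#'
#' @param r an [radiograph()] object.
#' @param target_w,target_h output dimensions in pixels (>= 1).
#' @return the resized [radiograph()].
#' @export
resize_to_standard <- function(r, target_w = 410L, target_h = 340L) {
  stopifnot(inherits(r, "mbl_radiograph"))
  target_w <- as.integer(target_w); target_h <- as.integer(target_h)
  if (target_w < 1L || target_h < 1L) stop("target dimensions must be >= 1")
  if (target_w == r$width && target_h == r$height) return(r)
  Wr <- .cubic_weights(r$height, target_h)
  Wc <- .cubic_weights(r$width, target_w)
  out <- Wr %*% r$pixels %*% t(Wc)
  out[out < 0] <- 0; out[out > 255] <- 255
  radiograph(out, mm_per_px = r$mm_per_px, source_id = r$source_id)
}

#' Rescale bounding boxes after an image resize
#'
#' @param boxes data frame with columns `x`, `y`, `w`, `h` (pixels).
#' @param sx,sy horizontal and vertical scale factors.
#' @return the data frame with scaled coordinates.
#' @export
scale_boxes <- function(boxes, sx, sy) {
  boxes$x <- boxes$x * sx
  boxes$y <- boxes$y * sy
  boxes$w <- boxes$w * sx
  boxes$h <- boxes$h * sy
  boxes
}
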