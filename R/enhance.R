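#' Gamma intensity adjustment
#'
#' Applies `out = round(255 * (in/255)^gamma)`. With gamma above 1 the
#' mapping pushes mid intensities toward darker values while leaving the
#' bright metallic implant structures close to white, increasing the
#' implant/tissue separation ahead of edge detection. The mapping is
#' monotone and fixes 0 and 255.
#'
#' @param r an [radiograph()].
#' @param gamma exponent, > 0; 1 is the identity.
#' @return the adjusted [radiograph()].
#' @export
enhance_gamma <- function(r, gamma = 1.5) {
  stopifnot(inherits(r, "mbl_radiograph"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar")
  out <- round(255 * (r$pixels / 255)^gamma)
  radiograph(out, mm_per_px = r$mm_per_px, source_id = r$source_id)
}

#' Linear contrast enhancement
#'
#' Maps the intensity range `[m - s, m + s]` affinely onto `[0, 255]`,
#' where `m` and `s` are the image mean and standard deviation;
#' intensities outside the range are clamped. Used as a corrective step
#' for radiographs flagged as low contrast, where implant edges would
#' otherwise come out broken.
#'
#' @param r an [radiograph()].
#' @return the enhanced [radiograph()].
#' @export
enhance_linear <- function(r) {
  stopifnot(inherits(r, "mbl_radiograph"))
  m <- mean(r$pixels)
  s <- sd(as.vector(r$pixels))
  if (!is.finite(s) || s == 0)
    stop("cannot enhance a constant image (zero standard deviation)")
  out <- (r$pixels - (m - s)) / (2 * s) * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  radiograph(round(out), mm_per_px = r$mm_per_px, source_id = r$source_id)
}
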