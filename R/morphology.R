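# Exact binary morphology and labeling on 0/1 matrices.
# Shift-union dilation avoids the numerical fuzz of FFT convolution and
# is fast enough at radiograph sizes.

.shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Binary dilation with a rectangular structuring element
#'
#' @param mask 0/1 matrix.
#' @param se_h,se_w structuring element height and width (odd integers);
#'   `c(3, 3)` expands edges isotropically, `c(1, 5)` horizontally.
#' @return dilated 0/1 integer matrix.
#' @export
dilate_binary <- function(mask, se_h, se_w) {
  stopifnot(se_h >= 1, se_w >= 1, se_h %% 2 == 1, se_w %% 2 == 1)
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  out <- matrix(0L, nrow(m), ncol(m))
  ry <- (se_h - 1L) / 2L; rx <- (se_w - 1L) / 2L
  for (dy in -ry:ry) for (dx in -rx:rx)
    out <- out | .shift_mat(m, dy, dx)
  matrix(as.integer(out), nrow(m), ncol(m))
}

#' Connected-component labeling
#'
#' Labels connected foreground regions of a binary matrix, by default
#' with 8-connectivity (diagonal neighbours connect).
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; 0 is background, components
#'   are numbered 1..k in scan order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  # pad with a zero border so linear-index neighbour offsets cannot wrap
  P <- matrix(0L, h + 2L, w + 2L)
  P[2:(h + 1L), 2:(w + 1L)] <- as.integer(mask != 0)
  hp <- h + 2L
  offs <- if (connectivity == 8)
    c(-1L, 1L, -hp, hp, -hp - 1L, -hp + 1L, hp - 1L, hp + 1L)
  else c(-1L, 1L, -hp, hp)
  lab <- matrix(0L, hp, w + 2L)
  fg <- which(P == 1L)
  nextlab <- 0L
  stack <- integer(length(fg))
  for (s in fg) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    top <- 1L
    stack[1L] <- s
    lab[s] <- nextlab
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      for (o in offs) {
        nb <- cur + o
        if (P[nb] == 1L && lab[nb] == 0L) {
          lab[nb] <- nextlab
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
  }
  lab[2:(h + 1L), 2:(w + 1L), drop = FALSE]
}
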