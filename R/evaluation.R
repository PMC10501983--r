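# Evaluation statistics: per-edge matching scores against ground-truth
# fits, one-sample t tests, polynomial-degree census, and batched
# resorption-percentage errors.

#' Matching score between a ground-truth and an adjusted edge fit
#'
#' Over the vertical overlap `[Y_m, Y_M]` of the two fits, the x
#' coordinates `X_G` and `X_A` are evaluated at every integer y and the
#' score is `ms_e = sum((X_G - X_A)^2) / (Y_M - Y_m)`. The denominator
#' is the span (not the sample count), matching the printed definition;
#' `rms_e = sqrt(ms_e)` is also returned since mean deviations are
#' reported in linear pixel units.
#'
#' @param G,A polynomial fits ([fit_edge()]), ground truth and
#'   adjusted.
#' @param y_range_G,y_range_A `c(min, max)` y extents of the two fits.
#' @return `list(Y_m, Y_M, L_e, x_e, ms_e, rms_e, df)` where `x_e` is
#'   the per-y difference sequence `X_G - X_A` and `df = L_e - 1`.
#' @export
matching_score <- function(G, A, y_range_G, y_range_A) {
  Y_m <- max(min(y_range_G), min(y_range_A))
  Y_M <- min(max(y_range_G), max(y_range_A))
  if (Y_M - Y_m < 2)
    stop(mbl_error("edge y ranges overlap by less than 2 px",
                   "mbl_evaluation_error"))
  ys <- seq(ceiling(Y_m), floor(Y_M))
  x_e <- eval_poly(G, ys) - eval_poly(A, ys)
  L_e <- Y_M - Y_m
  ms_e <- sum(x_e^2) / L_e
  list(Y_m = Y_m, Y_M = Y_M, L_e = L_e, x_e = x_e,
       ms_e = ms_e, rms_e = sqrt(ms_e), df = L_e - 1)
}

#' One-sample Student t test of zero mean
#'
#' `t = mean(x) / (sd(x) / sqrt(n))` with the sample standard deviation
#' and a two-sided p value on `n - 1` degrees of freedom.
#'
#' @param x numeric sample, `n >= 2`, non-constant.
#' @return `list(t, df, p)`.
#' @export
one_sample_t_test <- function(x) {
  if (length(x) < 2L) stop("need at least 2 observations")
  if (sd(x) == 0)
    stop("degenerate sample: zero variance")
  tt <- stats::t.test(x, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

# p value tolerant of perfect (constant-zero) matches
.safe_p <- function(x) {
  if (sd(x) == 0) return(if (mean(x) == 0) 1 else 0)
  one_sample_t_test(x)$p
}

#' Summarize edge-fit quality over a set of matches
#'
#' For each edge, the deviation sequence `x_e` is tested against zero
#' mean; the summary reports the mean and standard deviation of the
#' per-edge RMS deviations (`m_e`, `sigma_e`, in pixels), the mean p
#' value (`p_p`) and mean per-edge standard deviation (`sigma_p`), and
#' the share of edges whose deviation from zero is not rejected at
#' level `alpha` (p >= alpha).
#'
#' @param matches list of [matching_score()] results.
#' @param alpha significance level.
#' @return `list(m_e, sigma_e, p_p, sigma_p, pct_H0_not_rejected, n)`.
#' @export
edge_fit_evaluation <- function(matches, alpha = 0.05) {
  if (length(matches) < 1L) stop("need at least one match")
  rms <- vapply(matches, `[[`, numeric(1), "rms_e")
  ps <- vapply(matches, function(m) .safe_p(m$x_e), numeric(1))
  sds <- vapply(matches, function(m) sd(m$x_e), numeric(1))
  list(m_e = mean(rms),
       sigma_e = if (length(rms) > 1L) sd(rms) else 0,
       p_p = mean(ps),
       sigma_p = mean(sds),
       pct_H0_not_rejected = 100 * mean(ps >= alpha),
       n = length(matches))
}

#' Census of best-fitting polynomial degrees
#'
#' Selects the minimum-MSE degree for each edge group (or takes a
#' vector of already-selected degrees) and tabulates counts and
#' integer-rounded percentages per degree.
#'
#' @param groups list of edge groups (see [select_degree()]); ignored
#'   when `degrees` is given.
#' @param degrees optional integer vector of selected degrees.
#' @return data frame with columns `degree`, `count`, `pct`.
#' @export
degree_census <- function(groups = NULL, degrees = NULL) {
  if (is.null(degrees)) {
    if (is.null(groups) || length(groups) == 0L)
      stop("need groups or degrees")
    degrees <- vapply(groups, function(g) select_degree(g)$degree,
                      integer(1))
  }
  total <- length(degrees)
  counts <- vapply(1:3, function(d) sum(degrees == d), integer(1))
  data.frame(degree = 1:3, count = counts,
             pct = round(100 * counts / total))
}

#' Batched t-test summary of resorption-percentage errors
#'
#' Pairs where the automatic approach detected no critical points
#' (`A` missing) are excluded; the remaining errors `E = A - G` are
#' partitioned into `n_batches` batches (contiguous in input order, or
#' shuffled first when `shuffle_seed` is given), a one-sample t test of
#' zero mean error is run per batch, and the batch-averaged p value,
#' mean absolute error and error standard deviation are reported.
#'
#' @param A automatic percentages (`NA` where undetected).
#' @param G ground-truth percentages.
#' @param n_batches number of batches.
#' @param alpha significance level (recorded alongside).
#' @param shuffle_seed optional seed for random batch assignment.
#' @return `list(p_b, m_b, sigma_b, n_used, n_excluded, alpha,
#'   batch_p)`.
#' @export
resorption_error_batches <- function(A, G, n_batches = 10L, alpha = 0.05,
                                     shuffle_seed = NULL) {
  stopifnot(length(A) == length(G))
  ok <- !is.na(A) & !is.na(G)
  E <- A[ok] - G[ok]
  if (length(E) < n_batches)
    stop(mbl_error("fewer valid pairs than batches",
                   "mbl_evaluation_error"))
  if (!is.null(shuffle_seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(shuffle_seed)
    E <- sample(E)
  }
  f <- cut(seq_along(E), n_batches, labels = FALSE)
  batches <- split(E, f)
  ps <- vapply(batches, .safe_p, numeric(1))
  list(p_b = mean(ps),
       m_b = mean(vapply(batches, function(b) mean(abs(b)), numeric(1))),
       sigma_b = mean(vapply(batches, function(b)
         if (length(b) > 1L) sd(b) else 0, numeric(1))),
       n_used = length(E), n_excluded = sum(!ok),
       alpha = alpha, batch_p = unname(ps))
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
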