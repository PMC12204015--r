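#' Parameter-recovery experiment: 5PL half-decline time
#'
#' Simulates replicate ΔHSP70-versus-weeks datasets from a declining 5PL
#' with a prescribed half-decline time, refits each with [fit_5pl()], and
#' summarises how well the half-decline time is recovered. With `b` and
#' `g` fixed, the generating location is `c = t_half / (2^(1/g) - 1)^(1/b)`.
#'
#' @param t_half generating half-decline time, weeks.
#' @param weeks sampling weeks (default the post-weaning design weeks).
#' @param n_per_timepoint animals per timepoint.
#' @param sd Gaussian measurement SD on the ΔHSP70 scale.
#' @param a,d,b,g remaining generating 5PL parameters.
#' @param n_rep number of seeded replicates.
#' @param seed master seed; replicate `i` uses `seed + i`.
#' @return list with `mean_t_half`, `median_t_half`, `t_half` (per
#'   replicate), `relative_error` (of the mean), and the generating
#'   parameters.
#' @export
recover_half_decline <- function(t_half,
                                 weeks = c(1, 4, 8, 10, 14, 18, 22),
                                 n_per_timepoint = 6, sd = 0.03,
                                 a = 0.45, d = 0.05, b = 2, g = 1,
                                 n_rep = 50, seed = 1L) {
  c0 <- t_half / (2^(1 / g) - 1)^(1 / b)
  truth <- list(a = a, d = d, c = c0, b = b, g = g)
  x <- rep(weeks, each = n_per_timepoint)
  mu <- eval_5pl(truth, x)
  est <- vapply(seq_len(n_rep), function(i) {
    set.seed(seed + i)
    y <- mu + stats::rnorm(length(x), sd = sd)
    fit <- fit_5pl(x, y, seed = seed + i)
    characteristic_times(fit$params)$x50
  }, numeric(1))
  list(mean_t_half = mean(est), median_t_half = stats::median(est),
       t_half = est, relative_error = abs(mean(est) - t_half) / t_half,
       truth = truth)
}

#' Round-trip recovery of ΔHSP70 thresholds through a calibrated 5PL
#'
#' Calibrates a generating 5PL (index versus ΔHSP70) through two anchor
#' threshold points ([calibrate_5pl()]), simulates replicate noisy
#' datasets over a grid of ΔHSP70 levels, refits each with [fit_5pl()],
#' and inverts the fitted curve at the requested index cutoffs. The mean
#' recovered ΔHSP70 at each cutoff is compared with the generating value.
#'
#' @param a,d generating plateaus (index units).
#' @param x1,y1,x2,y2 anchor threshold points (ΔHSP70, index).
#' @param invert_at index cutoffs at which to invert the fitted curves;
#'   defaults to the anchor responses.
#' @param levels ΔHSP70 design levels.
#' @param n_per_level noisy observations per level.
#' @param sd Gaussian measurement SD in index units.
#' @param n_rep number of seeded replicates.
#' @param seed master seed; replicate `i` uses `seed + i`.
#' @return list with `mean_delta` (named by cutoff), `delta` (replicate ×
#'   cutoff matrix), `truth_delta` (generating inversions), `params`.
#' @export
recover_thresholds <- function(a, d, x1, y1, x2, y2,
                               invert_at = c(y1, y2),
                               levels = seq(0.05, 0.45, length.out = 8),
                               n_per_level = 12, sd = 0.2,
                               n_rep = 50, seed = 1L) {
  truth <- calibrate_5pl(a, d, x1, y1, x2, y2)
  x <- rep(levels, each = n_per_level)
  mu <- eval_5pl(truth, x)
  raw <- vapply(seq_len(n_rep), function(i) {
    set.seed(seed + i)
    y <- mu + stats::rnorm(length(x), sd = sd)
    fit <- fit_5pl(x, y, seed = seed + i)
    p <- fit$params
    lo <- min(p$a, p$d); hi <- max(p$a, p$d)
    vapply(invert_at, function(cut) {
      if (cut > lo && cut < hi) invert_5pl(p, cut) else NA_real_
    }, numeric(1))
  }, numeric(length(invert_at)))
  est <- matrix(raw, nrow = n_rep, ncol = length(invert_at), byrow = TRUE,
                dimnames = list(NULL, sprintf("%g", invert_at)))
  list(mean_delta = colMeans(est, na.rm = TRUE), delta = est,
       truth_delta = stats::setNames(invert_5pl(truth, invert_at),
                                     sprintf("%g", invert_at)),
       params = truth)
}

#' Recovery of a linear-trend threshold-crossing time
#'
#' Simulates replicate fasting-glycaemia-versus-weeks datasets from a
#' generating line, fits each by ordinary least squares
#' ([fit_linear_trend()]), and reads off the week at which the fitted line
#' crosses a threshold ([crossing_time()]).
#'
#' @param intercept,slope generating line (mM, mM/week).
#' @param threshold threshold to cross, mM.
#' @param weeks sampling weeks.
#' @param n_per_timepoint animals per timepoint.
#' @param sd Gaussian measurement SD, mM.
#' @param n_rep number of seeded replicates.
#' @param seed master seed; replicate `i` uses `seed + i`.
#' @return list with `mean_time`, `time` (per replicate), `truth_time`.
#' @export
recover_crossing <- function(intercept, slope, threshold = 5.6,
                             weeks = c(0, 1, 4, 8, 10, 14, 18, 22),
                             n_per_timepoint = 6, sd = 0.15,
                             n_rep = 50, seed = 1L) {
  x <- rep(weeks, each = n_per_timepoint)
  mu <- intercept + slope * x
  est <- vapply(seq_len(n_rep), function(i) {
    set.seed(seed + i)
    y <- mu + stats::rnorm(length(x), sd = sd)
    crossing_time(fit_linear_trend(x, y), threshold)$time
  }, numeric(1))
  list(mean_time = mean(est), time = est,
       truth_time = (threshold - intercept) / slope)
}
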