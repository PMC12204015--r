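# shared fixtures: small deterministic datasets built in code

# noisy observations from a known 5PL over a longitudinal design
make_5pl_data <- function(params, weeks = c(1, 4, 8, 10, 14, 18, 22),
                          n_per = 6, sd = 0.03, seed = 1) {
  x <- rep(weeks, each = n_per)
  set.seed(seed)
  list(x = x, y = eval_5pl(params, x) + rnorm(length(x), sd = sd))
}

# a two-round densitometry lane table with known ratios
make_lanes <- function(ratios_by_round, gapdh = 1000) {
  do.call(rbind, lapply(names(ratios_by_round), function(rd) {
    r <- ratios_by_round[[rd]]
    data.frame(animal_id = sprintf("%s_a%d", rd, seq_along(r)),
               round_id = rd,
               arm_c = rep(c(37, 42), length.out = length(r)),
               hsp70_intensity = r * gapdh, gapdh_intensity = gapdh,
               stringsAsFactors = FALSE)
  }))
}

# independent fine-grid numerical oracle for incremental areas: integrate
# max(interpolant - baseline, 0) on a dense grid (trapezoid on the grid)
grid_iauc_oracle <- function(times, values, baseline = values[1],
                             n_grid = 200001) {
  tg <- seq(times[1], times[length(times)], length.out = n_grid)
  vg <- approx(times, values, xout = tg)$y
  ex <- pmax(vg - baseline, 0)
  sum((ex[-1] + ex[-n_grid]) / 2 * diff(tg))
}

zero_noise_config <- function(seed = 11) {
  generator_config(
    noise_sd = list(densitometry = 0, glucose_mm = 0, insulin_uUml = 0),
    seed = seed)
}
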