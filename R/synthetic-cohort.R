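#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the study conditions a simulated two-arm (normal chow / high-fat
#' diet) mouse cohort is generated under: the diet groups, the terminal
#' timepoints (weeks on diet), animals per group per timepoint, and the
#' noise-free "truth" every downstream statistic can be checked against.
#'
#' Defaults emulate the design the analysis targets: timepoints
#' T0–T22 weeks with 6 males per group per timepoint; a declining 5PL
#' ΔHSP70 trajectory per group whose half-decline time is 8.24 weeks (NC)
#' or 3.14 weeks (HFD) with plateaus 0.45 and 0.05; fasting glycaemia
#' drifting linearly at 0.05 mM/week from intercepts chosen so the 5.6 mM
#' normal limit is reached at 13.1 (NC) and 6.3 (HFD) weeks; fasting
#' insulinaemia rising linearly from 8 μU/mL to cross the 15 μU/mL upper
#' physiological limit at 102.6 (NC) and 17.8 (HFD) weeks; oGTT curves with
#' a single peak returning toward baseline; ipITT curves with a
#' piecewise-linear drop-and-partial-recovery; and diet energy densities
#' 16.6 (NC) and 22.8 (HFD) MJ/kg. Measurement noise is additive Gaussian
#' per channel (densitometry fraction 0.03, glucose 0.15 mM, insulin
#' 1 μU/mL by default).
#'
#' @param groups character vector of group labels.
#' @param timepoints_weeks strictly increasing non-negative terminal weeks.
#' @param n_per_timepoint animals per group per timepoint, >= 2.
#' @param delta_hsp70_truth named list (one element per group) of 5PL
#'   parameter lists `a, d, c, b, g` with `a > d >= 0`.
#' @param fasting_glucose_truth named list of `c(intercept, slope)` in mM
#'   and mM/week.
#' @param fasting_insulin_truth named list of `c(intercept, slope)` in
#'   μU/mL and μU/mL/week.
#' @param ogtt_shape list `peak_mm` (peak glycaemic increment, mM),
#'   `peak_min` (time of peak, min), `decay_per_min` (return-rate constant,
#'   1/min; `1/peak_min` gives the canonical single-peak shape
#'   `A (t/tp) exp(1 - t/tp)`).
#' @param ipitt_shape list `drop_fraction` (fractional glycaemia drop at
#'   the nadir) and `nadir_min` (nadir time, min, within the 45-min test).
#' @param noise_sd list `densitometry` (normalized-fraction scale),
#'   `glucose_mm`, `insulin_uUml`; all >= 0.
#' @param diet_energy_density named list, MJ/kg per group.
#' @param baseline37 mean 37 °C normalized fraction before round scaling.
#' @param baseline37_slope optional drift of the 37 °C arm per week
#'   (default 0: no baseline trend).
#' @param seed integer master seed.
#' @return a validated object of class `"generator_config"`.
#' @export
generator_config <- function(
    groups = c("NC", "HFD"),
    timepoints_weeks = c(0, 1, 4, 8, 10, 14, 18, 22),
    n_per_timepoint = 6,
    delta_hsp70_truth = list(
      NC = list(a = 0.45, d = 0.05, c = 8.24, b = 2, g = 1),
      HFD = list(a = 0.45, d = 0.05, c = 3.14, b = 2, g = 1)),
    fasting_glucose_truth = list(
      NC = c(intercept = 4.945, slope = 0.05),
      HFD = c(intercept = 5.285, slope = 0.05)),
    fasting_insulin_truth = list(
      NC = c(intercept = 8, slope = 7 / 102.6),
      HFD = c(intercept = 8, slope = 7 / 17.8)),
    ogtt_shape = list(peak_mm = 9, peak_min = 15, decay_per_min = 1 / 15),
    ipitt_shape = list(drop_fraction = 0.35, nadir_min = 30),
    noise_sd = list(densitometry = 0.03, glucose_mm = 0.15,
                    insulin_uUml = 1.0),
    diet_energy_density = list(NC = 16.6, HFD = 22.8),
    baseline37 = 0.35,
    baseline37_slope = 0,
    seed = 1L) {
  cfg <- list(groups = groups, timepoints_weeks = timepoints_weeks,
              n_per_timepoint = as.integer(n_per_timepoint),
              delta_hsp70_truth = delta_hsp70_truth,
              fasting_glucose_truth = fasting_glucose_truth,
              fasting_insulin_truth = fasting_insulin_truth,
              ogtt_shape = ogtt_shape, ipitt_shape = ipitt_shape,
              noise_sd = noise_sd,
              diet_energy_density = diet_energy_density,
              baseline37 = baseline37,
              baseline37_slope = baseline37_slope,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (length(cfg$groups) < 1) stop("at least one group is required",
                                   call. = FALSE)
  tp <- cfg$timepoints_weeks
  if (any(tp < 0) || any(diff(tp) <= 0)) {
    stop("timepoints must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (cfg$n_per_timepoint < 2) stop("n_per_timepoint must be >= 2",
                                    call. = FALSE)
  for (nm in c("delta_hsp70_truth", "fasting_glucose_truth",
               "fasting_insulin_truth", "diet_energy_density")) {
    miss <- setdiff(cfg$groups, names(cfg[[nm]]))
    if (length(miss)) {
      stop(sprintf("'%s' missing entries for group(s): %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  for (g in cfg$groups) {
    p <- check_5pl_params(cfg$delta_hsp70_truth[[g]])
    if (!(p$a > p$d && p$d >= 0)) {
      stop("delta truth plateaus must satisfy a > d >= 0 ",
           "(declining trajectory)", call. = FALSE)
    }
  }
  if (any(unlist(cfg$noise_sd) < 0)) stop("noise SDs must be >= 0",
                                          call. = FALSE)
  invisible(cfg)
}

#' Read a generator configuration from a YAML file
#'
#' Flat YAML mirror of the [generator_config()] arguments; any field left
#' out keeps its default. Group-keyed fields are maps from group label to
#' value.
#'
#' @param path YAML file path.
#' @return a `"generator_config"`.
#' @export
generator_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(generator_config, raw)
}

#' Noise-free trajectories implied by a generator configuration
#'
#' Evaluates the generating truth for one group at time `t` weeks:
#' the 5PL ΔHSP70 value, and the linear fasting glucose and insulin values.
#' Deterministic; this is the closed form every zero-noise simulated
#' statistic must reproduce.
#'
#' @param config a `"generator_config"`.
#' @param group a group label present in the config.
#' @param t weeks on diet, >= 0 (vectorised).
#' @return list with numeric `delta_hsp70`, `glucose_mm`, `insulin_uUml`.
#' @export
eval_true_trajectories <- function(config, group, t) {
  stopifnot(inherits(config, "generator_config"))
  if (!group %in% config$groups) {
    stop(sprintf("unknown group label '%s'", group), call. = FALSE)
  }
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  gl <- config$fasting_glucose_truth[[group]]
  ins <- config$fasting_insulin_truth[[group]]
  list(
    delta_hsp70 = eval_5pl(config$delta_hsp70_truth[[group]], t),
    glucose_mm = unname(gl[1] + gl[2] * t),
    insulin_uUml = unname(ins[1] + ins[2] * t))
}

# Deterministic per-animal seed: a 31-bit string hash of the animal id
# folded with the master seed, so adding animals (or reordering groups)
# never perturbs the draws of existing ones.
animal_seed <- function(master_seed, animal_id) {
  h <- 0
  for (ch in utf8ToInt(animal_id)) h <- (h * 31 + ch) %% 2147483647
  as.integer(bitwXor(as.integer(h), as.integer(master_seed)) %% 2147483647)
}

ogtt_increment <- function(t, shape) {
  tp <- shape$peak_min; k <- shape$decay_per_min
  # generalises A (t/tp) exp(1 - t/tp); reduces to it when k = 1/tp
  shape$peak_mm * (t / tp)^(k * tp) * exp(k * (tp - t))
}

ipitt_level <- function(t, baseline, shape) {
  tn <- shape$nadir_min
  nadir <- baseline * (1 - shape$drop_fraction)
  end <- baseline * (1 - shape$drop_fraction / 2)  # partial recovery at 45'
  ifelse(t <= tn,
         baseline + (nadir - baseline) * t / tn,
         nadir + (end - nadir) * (t - tn) / (45 - tn))
}

# smooth monotone Michaelis-type growth, weeks on diet
growth_curve <- function(t, start, plateau, half_time) {
  start + (plateau - start) * t / (t + half_time)
}

#' Generate a seeded synthetic cohort
#'
#' Draws a complete cohort dataset with the measurement inventory of the
#' longitudinal design: per-animal densitometry lanes (37 °C and 42 °C arms
#' with GAPDH loading controls, one experimental round per timepoint),
#' fasting glycaemia and insulinaemia, oGTT and ipITT curves, and weekly
#' morphometry (body weight, nasoanal length, food intake).
#'
#' Densitometry: the 37 °C arm is drawn as a baseline normalized fraction
#' plus noise; the 42 °C arm is that same draw plus the group's true
#' ΔHSP70 at the animal's timepoint plus noise. Within each round all
#' fractions are then shifted so the brightest lane sits exactly at 1 —
#' a shift preserves every pairwise ΔHSP70 while emulating a round whose
#' secondary normalization is saturated, so recomputing the statistic
#' downstream reproduces the truth exactly at zero noise. Lane intensities
#' are stored as fraction × GAPDH with GAPDH drawn positive. Just-weaned
#' (week 0) animals are generated for glycaemia but excluded from
#' densitometry (too little blood for the heat challenge).
#'
#' Randomness is split hierarchically: every animal has its own stream
#' seeded from the master seed and its id, so identical configs and seeds
#' give byte-identical tables and adding animals does not perturb existing
#' ones.
#'
#' @param config a `"generator_config"`.
#' @return object of class `"cohort"`: list of data frames `animals`
#'   (`animal_id`, `group`, `week`), `densitometry` (`animal_id`,
#'   `round_id`, `arm_c`, `hsp70_intensity`, `gapdh_intensity`),
#'   `glycaemia` (`animal_id`, `glucose_mm`, `insulin_uUml`), `ogtt` and
#'   `ipitt` (`animal_id`, `minute`, `glycaemia_mm`), `morphometry`
#'   (`animal_id`, `week`, `weight_g`, `length_cm`, `food_g`).
#' @examples
#' cfg <- generator_config(seed = 42)
#' cohort <- generate_cohort(cfg)
#' head(cohort$densitometry)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  ns <- config$noise_sd
  ogtt_min <- c(0, 15, 30, 60, 90, 120)
  ipitt_min <- c(0, 15, 30, 45)

  animals <- do.call(rbind, lapply(config$groups, function(g) {
    do.call(rbind, lapply(config$timepoints_weeks, function(w) {
      data.frame(
        animal_id = sprintf("%s_w%02d_%d", g, w,
                            seq_len(config$n_per_timepoint)),
        group = g, week = w, stringsAsFactors = FALSE)
    }))
  }))

  dens <- list(); glyc <- list(); ogtt <- list(); ipitt <- list()
  morph <- list()

  for (i in seq_len(nrow(animals))) {
    id <- animals$animal_id[i]
    g <- animals$group[i]
    w <- animals$week[i]
    truth <- eval_true_trajectories(config, g, w)

    set.seed(animal_seed(config$seed, id))
    # fixed draw order per animal: densitometry, glycaemia, oGTT, ipITT
    gapdh <- exp(stats::rnorm(2, mean = log(1000), sd = 0.1))
    f37 <- config$baseline37 + config$baseline37_slope * w +
      stats::rnorm(1, sd = ns$densitometry)
    f42 <- f37 + truth$delta_hsp70 + stats::rnorm(1, sd = ns$densitometry)
    if (w > 0) {
      dens[[id]] <- data.frame(
        animal_id = id, round_id = sprintf("T%02d", w),
        arm_c = c(37, 42), frac = c(f37, f42),
        gapdh_intensity = gapdh, stringsAsFactors = FALSE)
    }

    g0 <- max(truth$glucose_mm + stats::rnorm(1, sd = ns$glucose_mm), 0.1)
    i0 <- max(truth$insulin_uUml + stats::rnorm(1, sd = ns$insulin_uUml), 0.1)
    glyc[[id]] <- data.frame(animal_id = id, glucose_mm = g0,
                             insulin_uUml = i0, stringsAsFactors = FALSE)

    ob <- max(truth$glucose_mm + stats::rnorm(1, sd = ns$glucose_mm), 0.1)
    ov <- ob + ogtt_increment(ogtt_min, config$ogtt_shape)
    ov[-1] <- ov[-1] + stats::rnorm(length(ogtt_min) - 1, sd = ns$glucose_mm)
    ogtt[[id]] <- data.frame(animal_id = id, minute = ogtt_min,
                             glycaemia_mm = pmax(ov, 0.1),
                             stringsAsFactors = FALSE)

    ib <- max(truth$glucose_mm + stats::rnorm(1, sd = ns$glucose_mm), 0.1)
    iv <- ipitt_level(ipitt_min, ib, config$ipitt_shape)
    iv[-1] <- iv[-1] + stats::rnorm(length(ipitt_min) - 1, sd = ns$glucose_mm)
    ipitt[[id]] <- data.frame(animal_id = id, minute = ipitt_min,
                              glycaemia_mm = pmax(iv, 0.1),
                              stringsAsFactors = FALSE)

    wk <- 0:w
    hfd_like <- config$diet_energy_density[[g]] >=
      max(unlist(config$diet_energy_density)) && length(config$groups) > 1
    w_plateau <- if (hfd_like) 46 else 38
    food <- if (hfd_like) 16 else 21  # g/week; similar energy intake
    morph[[id]] <- data.frame(
      animal_id = id, week = wk,
      weight_g = growth_curve(wk, 9, w_plateau, 10),
      length_cm = growth_curve(wk, 7.5, 10, 8),
      food_g = rep(food, length(wk)), stringsAsFactors = FALSE)
  }

  densitometry <- do.call(rbind, dens)
  if (!is.null(densitometry)) {
    # per-round shift so the brightest lane is exactly 1 (preserves deltas)
    shift <- stats::ave(densitometry$frac, densitometry$round_id,
                        FUN = function(v) 1 - max(v))
    densitometry$frac <- pmax(densitometry$frac + shift, 1e-6)
    densitometry$hsp70_intensity <-
      densitometry$frac * densitometry$gapdh_intensity
    densitometry$frac <- NULL
  } else {
    densitometry <- data.frame(animal_id = character(0),
                               round_id = character(0), arm_c = numeric(0),
                               hsp70_intensity = numeric(0),
                               gapdh_intensity = numeric(0))
  }

  out <- list(animals = animals,
              densitometry = densitometry,
              glycaemia = do.call(rbind, glyc),
              ogtt = do.call(rbind, ogtt),
              ipitt = do.call(rbind, ipitt),
              morphometry = do.call(rbind, morph),
              config = config)
  for (nm in c("densitometry", "glycaemia", "ogtt", "ipitt", "morphometry")) {
    rownames(out[[nm]]) <- NULL
    stray <- setdiff(out[[nm]]$animal_id, out$animals$animal_id)
    if (length(stray)) stop("internal error: stray animal ids", call. = FALSE)
  }
  structure(out, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$animals), "animals in",
      length(unique(x$animals$group)), "group(s) across",
      length(unique(x$animals$week)), "timepoints (seed",
      x$config$seed, ")\n")
  invisible(x)
}

#' Write the cohort tables as CSV files
#'
#' @param cohort a `"cohort"` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("animals", "densitometry", "glycaemia", "ogtt", "ipitt",
            "morphometry")
  paths <- file.path(dir, paste0(tabs, ".csv"))
  for (i in seq_along(tabs)) {
    utils::write.csv(cohort[[tabs[i]]], paths[i], row.names = FALSE)
  }
  invisible(paths)
}

#' Read cohort tables back from a directory of CSV files
#'
#' @param dir directory containing the tables written by
#'   [write_cohort_csv()] (the `ogtt`/`ipitt`/`morphometry` tables are
#'   optional).
#' @param config optional `"generator_config"` to attach.
#' @return a `"cohort"` object.
#' @export
read_cohort_csv <- function(dir, config = NULL) {
  req <- c("animals", "densitometry", "glycaemia")
  opt <- c("ogtt", "ipitt", "morphometry")
  out <- list()
  for (nm in c(req, opt)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(p)) {
      out[[nm]] <- utils::read.csv(p, stringsAsFactors = FALSE)
    } else if (nm %in% req) {
      stop("missing required cohort table: ", p, call. = FALSE)
    }
  }
  out$config <- config
  structure(out, class = "cohort")
}
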