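test_that("configuration validation enforces the design invariants", {
  expect_error(generator_config(timepoints_weeks = c(0, 4, 2)),
               "increasing")
  expect_error(generator_config(n_per_timepoint = 1), ">= 2")
  expect_error(generator_config(
    noise_sd = list(densitometry = -0.1, glucose_mm = 0.1,
                    insulin_uUml = 1)), ">= 0")
  expect_error(generator_config(delta_hsp70_truth = list(
    NC = list(a = 0.1, d = 0.4, c = 3, b = 2, g = 1),
    HFD = list(a = 0.45, d = 0.05, c = 3, b = 2, g = 1))),
    "a > d")
  expect_error(generator_config(fasting_glucose_truth = list(
    NC = c(5, 0.05))), "HFD")
})

test_that("true trajectories evaluate the closed forms", {
  cfg <- generator_config()
  tr <- eval_true_trajectories(cfg, "NC", 0)
  expect_equal(tr$delta_hsp70, 0.45)        # left plateau at t = 0
  expect_equal(tr$glucose_mm, 4.945)
  tr10 <- eval_true_trajectories(cfg, "NC", 10)
  expect_equal(tr10$glucose_mm, 4.945 + 0.5, tolerance = 1e-12)
  # g = 1 at t = c gives the plateau midpoint; cross-check against eval_5pl
  p <- cfg$delta_hsp70_truth$HFD
  trc <- eval_true_trajectories(cfg, "HFD", p$c)
  expect_equal(trc$delta_hsp70, p$a - (p$a - p$d) / 2, tolerance = 1e-12)
  expect_equal(trc$delta_hsp70, eval_5pl(p, p$c), tolerance = 1e-12)
  expect_error(eval_true_trajectories(cfg, "keto", 1), "unknown group")
  expect_error(eval_true_trajectories(cfg, "NC", -1), ">= 0")
})

test_that("identical config and seed give identical cohorts", {
  cfg <- generator_config(seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(generator_config(seed = 100))
  expect_false(identical(c1$densitometry, c3$densitometry))
})

test_that("cohort tables satisfy the structural invariants", {
  cohort <- generate_cohort(generator_config(seed = 3))
  ids <- cohort$animals$animal_id
  for (nm in c("densitometry", "glycaemia", "ogtt", "ipitt", "morphometry")) {
    expect_true(all(cohort[[nm]]$animal_id %in% ids))
  }
  expect_true(all(cohort$densitometry$hsp70_intensity > 0))
  expect_true(all(cohort$densitometry$gapdh_intensity > 0))
  expect_true(all(cohort$glycaemia$glucose_mm > 0))
  expect_true(all(cohort$ogtt$glycaemia_mm > 0))
  expect_true(all(cohort$morphometry$weight_g > 0))
  expect_true(all(cohort$morphometry$length_cm > 0))
  # week-0 (just-weaned) animals appear in glycaemia but not densitometry
  w0 <- ids[cohort$animals$week == 0]
  expect_true(all(w0 %in% cohort$glycaemia$animal_id))
  expect_false(any(w0 %in% cohort$densitometry$animal_id))
  # 6 animals per group per timepoint, two arms each in densitometry
  expect_equal(nrow(cohort$animals), 2 * 8 * 6)
  expect_equal(nrow(cohort$densitometry), 2 * 7 * 6 * 2)
})

test_that("adding a timepoint leaves existing animals' draws unchanged", {
  base <- generate_cohort(generator_config(seed = 12))
  wider <- generate_cohort(generator_config(
    timepoints_weeks = c(0, 1, 4, 8, 10, 14, 18, 22, 26), seed = 12))
  shared <- base$glycaemia$animal_id
  merged <- merge(base$glycaemia, wider$glycaemia, by = "animal_id")
  expect_equal(merged$glucose_mm.x, merged$glucose_mm.y, tolerance = 1e-12)
  expect_equal(merged$insulin_uUml.x, merged$insulin_uUml.y,
               tolerance = 1e-12)
})

test_that("zero-noise cohorts reproduce every closed-form statistic", {
  cfg <- zero_noise_config(seed = 8)
  cohort <- generate_cohort(cfg)
  # glycaemia equals the linear truth
  gly <- merge(cohort$animals, cohort$glycaemia, by = "animal_id")
  for (g in cfg$groups) {
    sub <- gly[gly$group == g, ]
    truth <- eval_true_trajectories(cfg, g, sub$week)
    expect_equal(sub$glucose_mm, truth$glucose_mm, tolerance = 1e-12)
    expect_equal(sub$insulin_uUml, truth$insulin_uUml, tolerance = 1e-12)
  }
  # oGTT iAUC equals the analytic area of the noise-free shape
  sh <- cfg$ogtt_shape
  tm <- c(0, 15, 30, 60, 90, 120)
  inc <- sh$peak_mm * (tm / sh$peak_min)^(sh$decay_per_min * sh$peak_min) *
    exp(sh$decay_per_min * (sh$peak_min - tm))
  expected_auc <- sum((inc[-1] + inc[-6]) / 2 * diff(tm))
  auc <- tolerance_auc(data.frame(animal_id = cohort$ogtt$animal_id,
                                  kind = "oGTT",
                                  minute = cohort$ogtt$minute,
                                  glycaemia_mm = cohort$ogtt$glycaemia_mm))
  expect_equal(auc$auc_mm_min, rep(expected_auc, nrow(auc)),
               tolerance = 1e-9)
})

test_that("recomputed ΔHSP70 dispersion grows with densitometry noise", {
  sds <- c(0.01, 0.05, 0.15)
  spread <- vapply(sds, function(s) {
    cfg <- generator_config(
      noise_sd = list(densitometry = s, glucose_mm = 0.15,
                      insulin_uUml = 1), seed = 44)
    cohort <- generate_cohort(cfg)
    recs <- delta_hsp70(normalize_run(cohort$densitometry), cohort$animals)
    truth <- vapply(seq_len(nrow(recs)), function(i) {
      eval_true_trajectories(cfg, recs$group[i], recs$week[i])$delta_hsp70
    }, numeric(1))
    sd(recs$delta - truth)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("cohort CSV round trip preserves the tables", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(generator_config(seed = 2))
  write_cohort_csv(cohort, dir)
  back <- read_cohort_csv(dir, config = cohort$config)
  for (nm in c("animals", "densitometry", "glycaemia", "ogtt", "ipitt")) {
    expect_equal(back[[nm]], cohort[[nm]], tolerance = 1e-12)
  }
})

test_that("YAML configs override defaults and reject unknown fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_per_timepoint: 4", "seed: 21",
               "timepoints_weeks: [0, 2, 6, 12]"), path)
  cfg <- generator_config_from_yaml(path)
  expect_equal(cfg$n_per_timepoint, 4L)
  expect_equal(cfg$timepoints_weeks, c(0, 2, 6, 12))
  expect_equal(cfg$seed, 21L)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("frobnicate: 3", bad)
  expect_error(generator_config_from_yaml(bad), "unknown config")
})
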