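#' Map clinical cutoffs to ΔHSP70 thresholds by inverse prediction
#'
#' Given a fitted 5PL mapping ΔHSP70 to a glycaemic index, inverts the
#' curve at each clinical cutoff ([invert_5pl()]) to obtain the ΔHSP70
#' level at which that cutoff is crossed, together with the side of the
#' threshold on which the healthy state lies. A cutoff outside the open
#' plateau interval of the fitted curve cannot be resolved; it is flagged
#' (with the admissible interval reported) and the run continues.
#'
#' @param fit a `"fit5pl"` object mapping ΔHSP70 (predictor) to the index.
#' @param cutoffs numeric vector of cutoff values in the index's native
#'   units.
#' @param labels optional character labels for the cutoffs.
#' @param healthy_low logical: is a low index value the healthy state
#'   (`TRUE` for glycaemia, HOMA-IR, iAUC; `FALSE` for QUICKI)? Determines,
#'   together with the fitted curve's monotonicity, whether ΔHSP70 above or
#'   below the threshold is healthy.
#' @return object of class `"threshold_map"`: data frame with `label`,
#'   `cutoff`, `delta_threshold`, `healthy_side` ("above"/"below"),
#'   `resolved`, plus attributes `plateau_interval` and `fit_params`.
#' @examples
#' p <- calibrate_5pl(7.2, 4.8, 0.2250, 5.6, 0.2125, 6.1)
#' x <- rep(seq(0.05, 0.45, length.out = 8), each = 12)
#' set.seed(1)
#' y <- eval_5pl(p, x) + rnorm(length(x), sd = 0.2)
#' fit <- fit_5pl(x, y, seed = 1)
#' derive_thresholds(fit, c(5.6, 6.1), c("normal limit", "IGT onset"))
#' @export
derive_thresholds <- function(fit, cutoffs, labels = NULL,
                              healthy_low = TRUE) {
  stopifnot(inherits(fit, "fit5pl"))
  p <- fit$params
  lo <- min(p$a, p$d); hi <- max(p$a, p$d)
  if (is.null(labels)) labels <- sprintf("cutoff_%g", cutoffs)
  decreasing <- p$a > p$d
  # decreasing curve & healthy-low index -> high ΔHSP70 is healthy
  healthy_side <- if (decreasing == healthy_low) "above" else "below"

  delta <- rep(NA_real_, length(cutoffs))
  resolved <- cutoffs > lo & cutoffs < hi
  if (any(resolved)) delta[resolved] <- invert_5pl(p, cutoffs[resolved])

  out <- data.frame(label = labels, cutoff = cutoffs,
                    delta_threshold = delta,
                    healthy_side = healthy_side,
                    resolved = resolved, stringsAsFactors = FALSE)
  structure(out, class = c("threshold_map", "data.frame"),
            plateau_interval = c(lo, hi), fit_params = p)
}

#' @export
print.threshold_map <- function(x, ...) {
  iv <- attr(x, "plateau_interval")
  cat(sprintf("ΔHSP70 threshold map (fitted plateau interval %.4g–%.4g):\n",
              iv[1], iv[2]))
  print.data.frame(x, row.names = FALSE)
  if (any(!x$resolved)) {
    cat(sprintf("  unresolved cutoffs lie outside (%.4g, %.4g)\n",
                iv[1], iv[2]))
  }
  invisible(x)
}

# tiny FNV-1a hash of a deparsed object, for config provenance in logs
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full ΔHSP70 / glycaemic-status analysis
#'
#' Orchestrates the complete pipeline on a cohort (simulated or read from
#' CSV tables): densitometry normalization and per-animal ΔHSP70;
#' per-timepoint aggregation (mean ± SD); a 5PL fit of ΔHSP70 versus weeks
#' per group with half-decline/inflection times and likelihood-based
#' goodness of fit; glycaemic indices (HOMA-IR, QUICKI) and status labels;
#' oGTT iAUC and ipITT inv-iAUC; linear trends of the fasting indices over
#' weeks with threshold-crossing times (onset of insulin resistance and of
#' the type-2-diabetes range); 5PL fits of each glycaemic index against the
#' per-timepoint mean ΔHSP70 pooled across diet groups (a per-group mode is
#' available via `pool_groups = FALSE`); and the resulting ΔHSP70
#' threshold map. Week-0 animals enter the glycaemic trends but are
#' excluded from all ΔHSP70 fits.
#'
#' @param config a `"generator_config"`; defaults to the standard study
#'   conditions. Its `seed` is overridden by `seed` when simulating.
#' @param cohort optional `"cohort"` object (e.g., from
#'   [read_cohort_csv()]); when `NULL`, a cohort is simulated from
#'   `config`.
#' @param seed integer seed for simulation and fit provenance.
#' @param out_dir optional directory; when given, CSV/JSON outputs, a
#'   human-readable report and a log (seed, package version, config hash)
#'   are written there.
#' @param pool_groups pool diet groups per timepoint for the
#'   index-versus-ΔHSP70 fits (default `TRUE`).
#' @param cutoffs cutoff overrides passed to [classify_status()].
#' @return object of class `"hsr_run"`: list with `delta_records`,
#'   `delta_summary`, `delta_fits` (per group: `fit`, `times`, `gof`),
#'   `panel`, `status`, `auc`, `trends` (per index), `index_fits`,
#'   `thresholds` (list of `"threshold_map"`), `counts`, `log`.
#' @export
run_pipeline <- function(config = generator_config(), cohort = NULL,
                         seed = config$seed, out_dir = NULL,
                         pool_groups = TRUE, cutoffs = list()) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(cohort)) {
    config$seed <- as.integer(seed)
    cohort <- generate_cohort(config)
  }

  # --- densitometry -> per-animal ΔHSP70 ---------------------------------
  norm <- normalize_run(cohort$densitometry)
  delta <- delta_hsp70(norm, cohort$animals, allow_incomplete = TRUE)
  n_complete <- nrow(delta)
  n_incomplete <- length(attr(delta, "incomplete"))

  agg <- stats::aggregate(delta$delta,
                          by = list(group = delta$group, week = delta$week),
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  delta_summary <- data.frame(group = agg$group, week = agg$week,
                              mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                              n = agg$x[, "n"])
  delta_summary <- delta_summary[order(delta_summary$group,
                                       delta_summary$week), ]
  rownames(delta_summary) <- NULL

  delta_fits <- lapply(split(delta, delta$group), function(d) {
    fit <- fit_5pl(d$week, d$delta, seed = seed)
    if (nrow(d) != sum(delta$group == d$group[1])) {
      stop("aggregation lost ΔHSP70 records", call. = FALSE)
    }
    list(fit = fit, times = characteristic_times(fit$params),
         gof = goodness_of_fit(fit))
  })

  # --- glycaemic indices and status --------------------------------------
  gly <- merge(cohort$animals, cohort$glycaemia, by = "animal_id",
               sort = FALSE)
  post <- cohort$ogtt[cohort$ogtt$minute == 120,
                      c("animal_id", "glycaemia_mm")]
  names(post)[2] <- "postload_mm"
  gly <- merge(gly, post, by = "animal_id", all.x = TRUE, sort = FALSE)
  panel <- glycaemic_panel(gly$animal_id, gly$glucose_mm, gly$insulin_uUml,
                           gly$postload_mm)
  panel$group <- gly$group
  panel$week <- gly$week
  status <- classify_status(panel, cutoffs)

  # --- tolerance-test areas ----------------------------------------------
  curves <- rbind(
    data.frame(animal_id = cohort$ogtt$animal_id, kind = "oGTT",
               minute = cohort$ogtt$minute,
               glycaemia_mm = cohort$ogtt$glycaemia_mm),
    data.frame(animal_id = cohort$ipitt$animal_id, kind = "ipITT",
               minute = cohort$ipitt$minute,
               glycaemia_mm = cohort$ipitt$glycaemia_mm))
  auc <- tolerance_auc(curves)
  auc <- merge(cohort$animals, auc, by = "animal_id", sort = FALSE)

  # --- linear trends over weeks with onset crossings ---------------------
  co <- utils::modifyList(list(ifg = 5.6, igt_fasting = 6.1, homa = 2.5,
                               quicki_normal_low = 0.339,
                               quicki_t2dm = 0.300, insulin_high = 15),
                          cutoffs)
  trend_spec <- list(
    glucose = list(y = panel$glucose_mm,
                   thresholds = c(T_IR = co$ifg, T_T2DM = co$igt_fasting)),
    insulin = list(y = panel$insulin_uUml,
                   thresholds = c(T_IR = co$insulin_high)),
    quicki = list(y = panel$quicki,
                  thresholds = c(T_IR = co$quicki_normal_low,
                                 T_T2DM = co$quicki_t2dm)),
    homa_ir = list(y = panel$homa_ir, thresholds = c(T_IR = co$homa)))
  trends <- lapply(trend_spec, function(sp) {
    by_group <- lapply(split(seq_len(nrow(panel)), panel$group), function(ix) {
      tr <- fit_linear_trend(panel$week[ix], sp$y[ix])
      crossings <- lapply(sp$thresholds, function(th) {
        tryCatch(crossing_time(tr, th), error = function(e) NULL)
      })
      list(trend = tr, crossings = crossings)
    })
    both <- fit_linear_trend(panel$week, sp$y, group = panel$group)
    c(by_group, list(slope_difference = both$slope_difference))
  })

  # --- index-versus-ΔHSP70 5PL fits and thresholds -----------------------
  wk_pos <- sort(unique(delta$week))
  mean_delta <- vapply(wk_pos, function(w) {
    mean(delta$delta[delta$week == w])  # pooled across groups (n = 12)
  }, numeric(1))

  index_values <- list(
    glucose = panel$glucose_mm, insulin = panel$insulin_uUml,
    quicki = panel$quicki, homa_ir = panel$homa_ir,
    postload = panel$postload_mm)
  index_week <- panel$week
  auc_by_kind <- split(auc, auc$kind)
  index_values$iauc_ogtt <- auc_by_kind$oGTT$auc_mm_min
  index_values$inv_iauc_ipitt <- auc_by_kind$ipITT$auc_mm_min
  index_weeks <- list(default = index_week,
                      iauc_ogtt = auc_by_kind$oGTT$week,
                      inv_iauc_ipitt = auc_by_kind$ipITT$week)

  mean_at <- function(v, w) {
    vapply(wk_pos, function(x) mean(v[w == x], na.rm = TRUE), numeric(1))
  }
  index_fits <- lapply(names(index_values), function(nm) {
    w <- if (nm %in% names(index_weeks)) index_weeks[[nm]] else
      index_weeks$default
    ybar <- mean_at(index_values[[nm]], w)
    fit <- tryCatch(fit_5pl(mean_delta, ybar, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(fit = fit, gof = goodness_of_fit(fit))
  })
  names(index_fits) <- names(index_values)

  thr_spec <- list(
    glucose = list(cutoffs = c(co$ifg, co$igt_fasting),
                   labels = c("normal fasting limit", "IGT onset"),
                   healthy_low = TRUE),
    postload = list(cutoffs = c(7.8, 11.1),
                    labels = c("IGT onset", "T2DM onset"),
                    healthy_low = TRUE),
    quicki = list(cutoffs = c(co$quicki_normal_low, co$quicki_t2dm),
                  labels = c("IR onset", "T2DM onset"),
                  healthy_low = FALSE),
    homa_ir = list(cutoffs = co$homa, labels = "IR onset",
                   healthy_low = TRUE),
    insulin = list(cutoffs = c(5, co$insulin_high),
                   labels = c("low limit", "IR onset"),
                   healthy_low = TRUE))
  thresholds <- lapply(names(thr_spec), function(nm) {
    f <- index_fits[[nm]]
    if (is.null(f)) return(NULL)
    sp <- thr_spec[[nm]]
    tm <- derive_thresholds(f$fit, sp$cutoffs, sp$labels, sp$healthy_low)
    # direction coherence: decreasing harmful-high index => healthy above
    if (f$fit$params$a > f$fit$params$d && sp$healthy_low) {
      stopifnot(all(tm$healthy_side == "above"))
    }
    tm
  })
  names(thresholds) <- names(thr_spec)

  log <- list(seed = as.integer(seed),
              package_version = as.character(utils::packageVersion("hsrglyc")),
              config_hash = config_hash(unclass(config)),
              n_animals = nrow(cohort$animals),
              n_delta_complete = n_complete,
              n_delta_incomplete = n_incomplete)

  run <- structure(list(
    delta_records = delta, delta_summary = delta_summary,
    delta_fits = delta_fits, panel = panel, status = status, auc = auc,
    trends = trends, mean_delta = data.frame(week = wk_pos,
                                             mean_delta = mean_delta),
    index_fits = index_fits, thresholds = thresholds,
    counts = list(complete = n_complete, incomplete = n_incomplete),
    log = log, config = config), class = "hsr_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.hsr_run <- function(x, ...) {
  cat("ΔHSP70 / glycaemic-status pipeline run (seed", x$log$seed, ")\n")
  for (g in names(x$delta_fits)) {
    df <- x$delta_fits[[g]]
    cat(sprintf(
      "  %s: half-decline t1/2 = %.2f weeks, R2 = %.3f, P = %.3g\n",
      g, df$times$x50, df$gof$r2_normalized, df$gof$p_value))
  }
  gl <- x$thresholds$glucose
  if (!is.null(gl) && all(gl$resolved)) {
    cat(sprintf(
      "  ΔHSP70 thresholds (fasting glycaemia): %s\n",
      paste(sprintf("%s %.4f", gl$label, gl$delta_threshold),
            collapse = ", ")))
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(run$delta_records,
                   file.path(out_dir, "delta_hsp70.csv"), row.names = FALSE)
  utils::write.csv(run$delta_summary,
                   file.path(out_dir, "delta_summary.csv"), row.names = FALSE)
  st <- run$status[, -1, drop = FALSE]
  names(st) <- paste0("status_", names(st))
  utils::write.csv(cbind(run$panel, st),
                   file.path(out_dir, "indices.csv"), row.names = FALSE)
  utils::write.csv(run$auc, file.path(out_dir, "auc.csv"), row.names = FALSE)

  fits <- lapply(run$delta_fits, function(df) {
    c(df$fit$params,
      list(rss = df$fit$rss, n = df$fit$n, x50 = df$times$x50,
           x_inf = df$times$x_inf, r2 = df$gof$r2_normalized,
           r2_maddala = df$gof$r2_maddala, chi2 = df$gof$chi2,
           p_value = df$gof$p_value))
  })
  jsonlite::write_json(fits, file.path(out_dir, "delta_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  thr <- lapply(run$thresholds, function(tm) {
    if (is.null(tm)) return(NULL)
    as.list(as.data.frame(tm))
  })
  jsonlite::write_json(thr, file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  rep <- c(
    "ΔHSP70 / glycaemic status pipeline report",
    sprintf("seed %d, config %s, package %s", run$log$seed,
            run$log$config_hash, run$log$package_version),
    sprintf("animals: %d; complete ΔHSP70 pairs: %d; incomplete: %d",
            run$log$n_animals, run$counts$complete, run$counts$incomplete),
    vapply(names(run$delta_fits), function(g) {
      df <- run$delta_fits[[g]]
      sprintf("%s ΔHSP70 half-decline t1/2 = %.2f weeks (R2 = %.3f)",
              g, df$times$x50, df$gof$r2_normalized)
    }, character(1)))
  writeLines(rep, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
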