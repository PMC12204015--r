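#' Baseline crossing of a glycaemic curve segment
#'
#' Where a linear curve segment crosses the fasting baseline, obtained from
#' the similarity of the two triangles the baseline cuts the segment into
#' (Thales construction):
#' \deqn{t^* = t_1 + (t_2 - t_1)\frac{base - v_1}{v_2 - v_1}.}
#' The excursions `v1 - baseline` and `v2 - baseline` must have strictly
#' opposite signs; a segment touching the baseline at an endpoint has no
#' crossing to resolve.
#'
#' @param t1,v1 time (min) and glycaemia (mM) at the segment start.
#' @param t2,v2 time and glycaemia at the segment end, `t2 > t1`.
#' @param baseline fasting glycaemia, mM.
#' @return the crossing time, strictly inside `(t1, t2)`.
#' @examples
#' segment_crossing(15, 7, 30, 3, baseline = 5)  # 22.5
#' @export
segment_crossing <- function(t1, v1, t2, v2, baseline) {
  if (t2 <= t1) stop("'t2' must exceed 't1'", call. = FALSE)
  d1 <- v1 - baseline; d2 <- v2 - baseline
  if (d1 == 0 || d2 == 0 || sign(d1) == sign(d2)) {
    stop("segment excursions must have strictly opposite signs ",
         "(no baseline crossing)", call. = FALSE)
  }
  t1 + (t2 - t1) * (baseline - v1) / (v2 - v1)
}

check_curve <- function(times, values) {
  if (length(times) != length(values) || length(times) < 2) {
    stop("a tolerance curve needs matching times/values of length >= 2",
         call. = FALSE)
  }
  if (times[1] != 0) stop("the first sample must be at time zero (baseline)",
                          call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (any(!is.finite(values))) stop("glycaemia values must be finite",
                                    call. = FALSE)
  invisible(TRUE)
}

#' Incremental area under a tolerance-test curve (iAUC)
#'
#' Trapezoid-method area of the glycaemic excursion above the fasting
#' baseline (the t = 0 value of the same animal), in mM·min. Area beneath
#' the baseline is ignored; segments that cross the baseline are split at
#' the geometric crossing point ([segment_crossing()]) and only the
#' above-baseline triangle is counted. Samples exactly at baseline
#' contribute zero-height trapezoid edges and synthesize no crossing.
#' This is the oGTT summary statistic, computed per animal.
#'
#' @param times sampling times in minutes, strictly increasing, first = 0.
#' @param values glycaemia in mM at each time.
#' @param baseline fasting baseline, mM; defaults to `values[1]`.
#' @return non-negative area, mM·min; zero iff the curve never strictly
#'   exceeds the baseline.
#' @examples
#' incremental_auc(c(0, 15, 30), c(5, 7, 5))  # 30
#' incremental_auc(c(0, 15, 30), c(5, 7, 3))  # 22.5
#' @export
incremental_auc <- function(times, values, baseline = values[1]) {
  check_curve(times, values)
  total <- 0
  for (i in seq_len(length(times) - 1)) {
    t1 <- times[i]; t2 <- times[i + 1]
    d1 <- values[i] - baseline; d2 <- values[i + 1] - baseline
    if (d1 >= 0 && d2 >= 0) {
      total <- total + (d1 + d2) / 2 * (t2 - t1)
    } else if (d1 <= 0 && d2 <= 0) {
      # fully at or below baseline: ignored
    } else {
      ts <- segment_crossing(t1, values[i], t2, values[i + 1], baseline)
      if (d1 > 0) {
        total <- total + d1 / 2 * (ts - t1)
      } else {
        total <- total + d2 / 2 * (t2 - ts)
      }
    }
  }
  total
}

#' Inverted incremental area under an insulin-tolerance curve (inv-iAUC)
#'
#' Mirror of [incremental_auc()]: the area of the glycaemic drop below the
#' fasting baseline during an ipITT, discarding any portion above the
#' baseline, with baseline-crossing segments resolved by the same triangle
#' construction. Implemented exactly as the incremental area of the curve
#' reflected about its baseline, so the mirror identity
#' `inv_iAUC(v) == iAUC(2 * baseline - v)` holds by construction.
#'
#' @inheritParams incremental_auc
#' @return non-negative area, mM·min; zero iff the curve never strictly
#'   falls below the baseline.
#' @examples
#' inverted_incremental_auc(c(0, 15, 30, 45), c(8, 5, 4, 5))  # 127.5
#' @export
inverted_incremental_auc <- function(times, values, baseline = values[1]) {
  incremental_auc(times, 2 * baseline - values, baseline)
}

#' Per-animal AUCs from a long-format curve table
#'
#' @param curves data frame with columns `animal_id`, `kind` ("oGTT" or
#'   "ipITT"), `minute`, `glycaemia_mm`. Each animal/kind series must start
#'   at minute 0; that sample is the baseline. oGTT series yield the
#'   incremental area, ipITT series the inverted incremental area.
#' @return data frame `animal_id`, `kind`, `auc_mm_min`.
#' @export
tolerance_auc <- function(curves) {
  need <- c("animal_id", "kind", "minute", "glycaemia_mm")
  miss <- setdiff(need, names(curves))
  if (length(miss)) {
    stop("missing curve columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(curves$kind %in% c("oGTT", "ipITT"))) {
    stop("'kind' must be 'oGTT' or 'ipITT'", call. = FALSE)
  }
  keys <- unique(curves[, c("animal_id", "kind")])
  keys$auc_mm_min <- vapply(seq_len(nrow(keys)), function(i) {
    sub <- curves[curves$animal_id == keys$animal_id[i] &
                    curves$kind == keys$kind[i], , drop = FALSE]
    sub <- sub[order(sub$minute), , drop = FALSE]
    if (keys$kind[i] == "oGTT") {
      incremental_auc(sub$minute, sub$glycaemia_mm)
    } else {
      inverted_incremental_auc(sub$minute, sub$glycaemia_mm)
    }
  }, numeric(1))
  rownames(keys) <- NULL
  keys
}
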