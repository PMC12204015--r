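#' Concentration unit conversions for insulin and glucose
#'
#' Conversions used when moving between assay units and index units:
#' \describe{
#'   \item{`insulin_ngml_to_pM_mouse`}{mouse insulin mass concentration to
#'     molar: pM = ng/mL × 1000 / 5.8 (5.8 pg per fmol of mouse insulin).}
#'   \item{`insulin_uUml_to_pM_human`}{human insulin activity units to
#'     molar: pM = μU/mL × 5.975 (5.975 fmol per μU).}
#'   \item{`insulin_ngml_to_uUml`}{the full mouse chain ng/mL → pM → μU/mL
#'     (divide the molar value by 5.975), the form entering HOMA-IR and
#'     QUICKI when assays report ng/mL.}
#'   \item{`glucose_mM_to_mgdl` / `glucose_mgdl_to_mM`}{molar mass of
#'     glucose, 18.0182 mg/dL per mM.}
#' }
#'
#' @param value non-negative concentration value(s).
#' @param kind one of the conversion names above.
#' @return converted value(s).
#' @examples
#' convert_units(1, "insulin_uUml_to_pM_human")  # 5.975
#' convert_units(1, "insulin_ngml_to_pM_mouse")  # 172.41...
#' convert_units(5.6, "glucose_mM_to_mgdl")
#' @export
convert_units <- function(value,
                          kind = c("insulin_ngml_to_pM_mouse",
                                   "insulin_uUml_to_pM_human",
                                   "insulin_ngml_to_uUml",
                                   "glucose_mM_to_mgdl",
                                   "glucose_mgdl_to_mM")) {
  kind <- match.arg(kind)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("'value' must be finite and >= 0", call. = FALSE)
  }
  switch(kind,
         insulin_ngml_to_pM_mouse = value * 1000 / 5.8,
         insulin_uUml_to_pM_human = value * 5.975,
         insulin_ngml_to_uUml = (value * 1000 / 5.8) / 5.975,
         glucose_mM_to_mgdl = value * 18.0182,
         glucose_mgdl_to_mM = value / 18.0182)
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = I0 (μU/mL) × G0 (mM) / 22.5`.
#'
#' @param I0 fasting insulin in μU/mL, > 0.
#' @param G0 fasting glucose in mM, > 0.
#' @return dimensionless HOMA-IR value(s).
#' @examples
#' homa_ir(10, 5.625)  # 2.5
#' @export
homa_ir <- function(I0, G0) {
  if (any(!is.finite(I0)) || any(I0 <= 0) ||
      any(!is.finite(G0)) || any(G0 <= 0)) {
    stop("fasting insulin and glucose must be finite and > 0", call. = FALSE)
  }
  I0 * G0 / 22.5
}

#' Quantitative insulin sensitivity check index (QUICKI)
#'
#' `QUICKI = 1 / [log10(I0) + log10(G0)]` with insulin in μU/mL and glucose
#' in mg/dL (base-10 logarithms, the convention of the index). Supply
#' glycaemia in mM via [convert_units()] first.
#'
#' @param I0 fasting insulin in μU/mL, > 0.
#' @param G0_mgdl fasting glucose in mg/dL, > 0.
#' @return dimensionless QUICKI value(s).
#' @examples
#' quicki(10, 100)  # 1/3
#' @export
quicki <- function(I0, G0_mgdl) {
  if (any(!is.finite(I0)) || any(I0 <= 0) ||
      any(!is.finite(G0_mgdl)) || any(G0_mgdl <= 0)) {
    stop("fasting insulin and glucose must be finite and > 0", call. = FALSE)
  }
  den <- log10(I0) + log10(G0_mgdl)
  if (any(den == 0)) {
    stop("degenerate input: log10(I0) + log10(G0) is zero", call. = FALSE)
  }
  1 / den
}

#' Build a glycaemic panel with derived indices
#'
#' Computes HOMA-IR and QUICKI for per-animal fasting measurements.
#'
#' @param animal_id identifiers.
#' @param glucose_mm fasting glycaemia, mM.
#' @param insulin_uUml fasting insulinaemia, μU/mL.
#' @param postload_mm optional 2-hour post-glucose-load glycaemia, mM.
#' @return data frame with `animal_id`, `glucose_mm`, `insulin_uUml`,
#'   `postload_mm`, `homa_ir`, `quicki`.
#' @export
glycaemic_panel <- function(animal_id, glucose_mm, insulin_uUml,
                            postload_mm = NA_real_) {
  data.frame(
    animal_id = as.character(animal_id),
    glucose_mm = glucose_mm,
    insulin_uUml = insulin_uUml,
    postload_mm = postload_mm,
    homa_ir = homa_ir(insulin_uUml, glucose_mm),
    quicki = quicki(insulin_uUml, convert_units(glucose_mm,
                                                "glucose_mM_to_mgdl")),
    stringsAsFactors = FALSE)
}

#' Classify glycaemic status against clinical cutoffs
#'
#' Assigns, per animal, one label per glycaemic axis using the cutoffs the
#' analysis adopts (human-derived values applied to mice; all of them are
#' arguments, not constants). Boundary conventions:
#' \itemize{
#'   \item fasting glycaemia: normal < 5.6 mM; IFG in \[5.6, 6.1); T2DM-range
#'     at and above 6.1 mM.
#'   \item 2-h postload glycaemia: normal < 7.8; IGT in \[7.8, 11.1);
#'     T2DM-range at and above 11.1 mM.
#'   \item HOMA-IR: insulin resistance strictly above 2.5 (2.5 itself is
#'     normal).
#'   \item QUICKI: normal at and above 0.339 (0.450 is the nominal upper
#'     end of the normal band; higher values are also labelled normal);
#'     IR in \[0.300, 0.339); T2DM-range below 0.300.
#'   \item fasting insulin: low < 5, normal in \[5, 15\], high > 15 μU/mL.
#' }
#'
#' @param panel a data frame from [glycaemic_panel()] (columns
#'   `glucose_mm`, `insulin_uUml`, `homa_ir`, `quicki`, optionally
#'   `postload_mm`).
#' @param cutoffs named list overriding any of `ifg`, `igt_fasting`,
#'   `postload_igt`, `postload_t2dm`, `homa`, `quicki_normal_low`,
#'   `quicki_t2dm`, `insulin_low`, `insulin_high`.
#' @return data frame of factor labels: `fasting`, `postload`, `homa`,
#'   `quicki`, `insulin` (one row per panel row).
#' @examples
#' p <- glycaemic_panel("m1", glucose_mm = 5.9, insulin_uUml = 10)
#' classify_status(p)
#' @export
classify_status <- function(panel, cutoffs = list()) {
  co <- utils::modifyList(list(
    ifg = 5.6, igt_fasting = 6.1,
    postload_igt = 7.8, postload_t2dm = 11.1,
    homa = 2.5,
    quicki_normal_low = 0.339, quicki_t2dm = 0.300,
    insulin_low = 5, insulin_high = 15), cutoffs)

  cut_labels <- function(v, breaks, labels) {
    # breaks are lower-closed: label i applies on [breaks[i], breaks[i+1])
    out <- labels[findInterval(v, breaks) + 1L]
    factor(out, levels = labels)
  }
  fasting <- cut_labels(panel$glucose_mm, c(co$ifg, co$igt_fasting),
                        c("normal", "IFG", "T2DM-range"))
  postload <- if ("postload_mm" %in% names(panel)) {
    cut_labels(panel$postload_mm, c(co$postload_igt, co$postload_t2dm),
               c("normal", "IGT", "T2DM-range"))
  } else factor(rep(NA_character_, nrow(panel)),
                levels = c("normal", "IGT", "T2DM-range"))
  homa <- factor(ifelse(panel$homa_ir > co$homa, "IR", "normal"),
                 levels = c("normal", "IR"))
  qk <- ifelse(panel$quicki >= co$quicki_normal_low, "normal",
               ifelse(panel$quicki >= co$quicki_t2dm, "IR", "T2DM-range"))
  quicki_lab <- factor(qk, levels = c("normal", "IR", "T2DM-range"))
  ins <- ifelse(panel$insulin_uUml < co$insulin_low, "low",
                ifelse(panel$insulin_uUml > co$insulin_high, "high", "normal"))
  insulin <- factor(ins, levels = c("low", "normal", "high"))

  data.frame(animal_id = panel$animal_id, fasting = fasting,
             postload = postload, homa = homa, quicki = quicki_lab,
             insulin = insulin, stringsAsFactors = FALSE)
}

#' Lee index of rodent adiposity
#'
#' `(body weight in g)^(1/3) / (nasoanal length in cm)`.
#'
#' @param weight_g body weight, grammes, > 0.
#' @param length_cm nasoanal length, centimetres, > 0.
#' @return Lee index value(s), g^(1/3) cm^-1.
#' @examples
#' lee_index(27, 9)  # 1/3
#' @export
lee_index <- function(weight_g, length_cm) {
  if (any(!is.finite(weight_g)) || any(weight_g <= 0) ||
      any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop("weight and length must be finite and > 0", call. = FALSE)
  }
  weight_g^(1 / 3) / length_cm
}

#' Weekly metabolic efficiency
#'
#' Energy intake over one week divided by body-weight gain over that week,
#' kJ per gramme gained. Weeks with zero or negative weight gain have no
#' defined efficiency: they propagate as `NA` (flagged-undefined, not an
#' error), since the quotient is meaningless rather than exceptional there.
#'
#' @param intake_kj energy intake over the week, kJ, >= 0.
#' @param gain_g body-weight gain over the same week, g.
#' @return kJ/g, with `NA` where `gain_g <= 0`.
#' @examples
#' metabolic_efficiency(100, 2)  # 50
#' metabolic_efficiency(100, 0)  # NA
#' @export
metabolic_efficiency <- function(intake_kj, gain_g) {
  if (any(!is.finite(intake_kj)) || any(intake_kj < 0)) {
    stop("energy intake must be finite and >= 0", call. = FALSE)
  }
  ifelse(gain_g > 0, intake_kj / gain_g, NA_real_)
}
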