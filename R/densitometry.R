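#' Two-stage densitometry normalization
#'
#' Normalizes immunoblot lane intensities in two stages: (1) each HSP70
#' band intensity is divided by the GAPDH loading-control intensity of the
#' same lane; (2) within each experimental round, every ratio is divided by
#' the highest ratio observed among all lanes of that round (both
#' temperature arms jointly), so that the maximum normalized value of each
#' round is exactly unity and every value lies in \[0, 1\]. Normalization
#' never crosses round boundaries; one gel per round is the expected usage.
#'
#' @param lanes data frame with columns `animal_id`, `round_id`,
#'   `arm_c` (37 or 42), `hsp70_intensity` (>= 0), `gapdh_intensity` (> 0).
#' @return the input data frame with columns `ratio` (stage 1) and
#'   `norm` (stage 2, in \[0, 1\]) appended.
#' @examples
#' lanes <- data.frame(animal_id = c("m1", "m1"), round_id = "T01",
#'                     arm_c = c(37, 42),
#'                     hsp70_intensity = c(200, 400),
#'                     gapdh_intensity = c(100, 100))
#' normalize_run(lanes)
#' @export
normalize_run <- function(lanes) {
  need <- c("animal_id", "round_id", "arm_c", "hsp70_intensity",
            "gapdh_intensity")
  miss <- setdiff(need, names(lanes))
  if (length(miss)) {
    stop("missing lane columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(lanes) == 0) stop("empty densitometry run", call. = FALSE)
  if (!all(lanes$arm_c %in% c(37, 42))) {
    stop("'arm_c' must be 37 or 42", call. = FALSE)
  }
  bad <- which(!is.finite(lanes$gapdh_intensity) | lanes$gapdh_intensity <= 0)
  if (length(bad)) {
    stop(sprintf(
      "non-positive GAPDH loading intensity in lane(s): %s",
      paste(sprintf("animal %s round %s arm %s",
                    lanes$animal_id[bad], lanes$round_id[bad],
                    lanes$arm_c[bad]), collapse = "; ")), call. = FALSE)
  }
  if (any(!is.finite(lanes$hsp70_intensity) | lanes$hsp70_intensity < 0)) {
    stop("HSP70 intensities must be finite and >= 0", call. = FALSE)
  }
  lanes$ratio <- lanes$hsp70_intensity / lanes$gapdh_intensity
  round_max <- stats::ave(lanes$ratio, lanes$round_id, FUN = max)
  if (any(round_max <= 0)) {
    stop("a round has no positive HSP70 signal; cannot normalize",
         call. = FALSE)
  }
  lanes$norm <- lanes$ratio / round_max
  lanes
}

#' Per-animal heat shock response statistic (ΔHSP70)
#'
#' Pairs, for every animal, its normalized 42 °C (heat-challenged) and
#' 37 °C (control) values from the same experimental round and computes
#' \deqn{\Delta HSP70 = HSP70_{42} - HSP70_{37}} on the round-normalized
#' scale, so every delta lies in \[-1, 1\]. Each animal must contribute
#' exactly one lane per arm; animals with a missing or duplicated arm are
#' reported in the `incomplete` attribute and raise an error unless
#' `allow_incomplete = TRUE` (they are then excluded from the result but
#' never silently dropped).
#'
#' @param normalized output of [normalize_run()].
#' @param animals optional data frame with `animal_id`, `group`, `week`
#'   metadata to attach to the records.
#' @param allow_incomplete if `TRUE`, animals without a complete 37/42 pair
#'   are excluded and listed in `attr(result, "incomplete")` instead of
#'   raising an error.
#' @return data frame with columns `animal_id`, `group`, `week`, `norm37`,
#'   `norm42`, `delta` (one row per complete animal).
#' @export
delta_hsp70 <- function(normalized, animals = NULL, allow_incomplete = FALSE) {
  if (!all(c("norm", "arm_c") %in% names(normalized))) {
    stop("'normalized' must come from normalize_run()", call. = FALSE)
  }
  ids <- unique(normalized$animal_id)
  rows <- vector("list", length(ids))
  incomplete <- character(0)
  for (i in seq_along(ids)) {
    sub <- normalized[normalized$animal_id == ids[i], , drop = FALSE]
    n37 <- sum(sub$arm_c == 37); n42 <- sum(sub$arm_c == 42)
    if (n37 != 1 || n42 != 1 ||
        sub$round_id[sub$arm_c == 37] != sub$round_id[sub$arm_c == 42]) {
      incomplete <- c(incomplete, as.character(ids[i]))
      next
    }
    rows[[i]] <- data.frame(
      animal_id = as.character(ids[i]),
      norm37 = sub$norm[sub$arm_c == 37],
      norm42 = sub$norm[sub$arm_c == 42],
      stringsAsFactors = FALSE)
  }
  if (length(incomplete) && !allow_incomplete) {
    stop("animals without exactly one 37 °C and one 42 °C lane ",
         "in the same round: ", paste(incomplete, collapse = ", "),
         call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(animal_id = character(0), norm37 = numeric(0),
                      norm42 = numeric(0))
  }
  out$delta <- out$norm42 - out$norm37
  if (!is.null(animals)) {
    meta <- animals[, intersect(c("animal_id", "group", "week"),
                                names(animals)), drop = FALSE]
    out <- merge(meta, out, by = "animal_id", sort = FALSE)
  }
  attr(out, "incomplete") <- incomplete
  out
}
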