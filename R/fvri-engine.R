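# Fractional vessel remodeling index.
#
# FVRI compares the measured vessel area of a cross-section against the area
# it would need to accommodate its plaque with complete compensatory
# enlargement: eem_actual / (eem_predicted + plaque). An index of 1 means the
# vessel grew by exactly the plaque load; above the band the vessel is
# ectatic; below it, enlargement was insufficient — with absolute shrinkage
# (eem_actual < eem_predicted) distinguished as negative remodeling.

remodeling_levels <- c("negative", "incomplete_compensatory",
                       "complete_compensatory", "ectatic", "trivial_plaque")

#' FVRI configuration
#'
#' Bundles the interpretation constants: the complete-compensatory band
#' (default 0.83--1.17, one standard deviation of the lesion-level index
#' around 1), the trivial-plaque burden cutoff (20%), and the algebraic
#' variant of the index.
#'
#' @param band_low,band_high Inclusive band bounds for complete compensatory
#'   remodeling; must satisfy `0 < band_low < 1 < band_high`.
#' @param trivial_burden Plaque-burden percentage below which a frame is
#'   classified `trivial_plaque` rather than by its index.
#' @param formula_variant `"compensation_ratio"` (default),
#'   `eem_actual / (eem_predicted + plaque)`, or `"lumen_ratio"`,
#'   `(eem_actual - plaque) / eem_predicted`. The two agree exactly at 1 and
#'   always agree on the sign of `FVRI - 1`.
#'
#' @return A list of class `fvri_config`.
#' @export
fvri_config <- function(band_low = 0.83, band_high = 1.17,
                        trivial_burden = 20,
                        formula_variant = c("compensation_ratio",
                                            "lumen_ratio")) {
  formula_variant <- match.arg(formula_variant)
  check_number(band_low, "band_low", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(band_high, "band_high", lower = 1, strict_lower = TRUE)
  check_number(trivial_burden, "trivial_burden", lower = 0, upper = 100,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(
    list(band_low = band_low, band_high = band_high,
         trivial_burden = trivial_burden, formula_variant = formula_variant),
    class = "fvri_config"
  )
}

#' Derive the complete-compensatory band from an index standard deviation
#'
#' The band is symmetric around complete compensation:
#' `(1 - sd, 1 + sd)`. With the published lesion-level standard deviation of
#' 0.17 this yields the default band (0.83, 1.17).
#'
#' @param sd Standard deviation of the index at plaque level; must satisfy
#'   `0 < sd < 1` (a zero width would make the band degenerate).
#'
#' @return Named numeric vector `c(band_low, band_high)`.
#' @examples
#' derive_band_from_sd(0.17)
#' @export
derive_band_from_sd <- function(sd) {
  check_number(sd, "sd", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  c(band_low = 1 - sd, band_high = 1 + sd)
}

#' Compute the fractional vessel remodeling index
#'
#' @param eem_actual Measured EEM area, mm^2. Vectorised.
#' @param eem_predicted Model-inferred normal EEM area, mm^2.
#' @param plaque_area Plaque + media area, mm^2; frames with zero plaque have
#'   no index (NA) and take the trivial-plaque classification path.
#' @param formula_variant See [fvri_config()].
#'
#' @return Numeric vector of the index; NA where `plaque_area` is 0.
#' @examples
#' compute_fvri(18, 12, 6) # complete compensation: exactly 1
#' compute_fvri(11, 12, 6) # shrinkage
#' @export
compute_fvri <- function(eem_actual, eem_predicted, plaque_area,
                         formula_variant = c("compensation_ratio",
                                             "lumen_ratio")) {
  formula_variant <- match.arg(formula_variant)
  bad <- which(!is.finite(eem_actual) | !is.finite(eem_predicted) |
                 eem_actual <= 0 | eem_predicted <= 0 |
                 !is.finite(plaque_area) | plaque_area < 0)
  if (length(bad) > 0L) {
    stop_fvri(sprintf(
      "FVRI needs positive EEM areas and non-negative plaque area; offending position(s): %s.",
      paste(head(bad, 5L), collapse = ", ")
    ), class = "fvri_validation_error")
  }
  out <- switch(formula_variant,
    compensation_ratio = eem_actual / (eem_predicted + plaque_area),
    lumen_ratio = (eem_actual - plaque_area) / eem_predicted
  )
  out[plaque_area == 0] <- NA_real_
  out
}

#' Classify the remodeling pattern of frames
#'
#' Frames with plaque burden below the trivial cutoff are `trivial_plaque`.
#' Otherwise: index above the band is `ectatic`; inside the band (inclusive)
#' `complete_compensatory`; below the band, `negative` when the measured EEM
#' is smaller than the predicted normal EEM (absolute shrinkage) and
#' `incomplete_compensatory` otherwise (enlargement insufficient for the
#' plaque load).
#'
#' @param fvri Index values (NA allowed where burden is trivial).
#' @param plaque_burden_pct Plaque burden, percent.
#' @param eem_actual,eem_predicted EEM areas, mm^2, for the shrinkage branch.
#' @param config An [fvri_config()].
#'
#' @return Factor with levels negative, incomplete_compensatory,
#'   complete_compensatory, ectatic, trivial_plaque.
#' @export
classify_remodeling <- function(fvri, plaque_burden_pct, eem_actual,
                                eem_predicted, config = fvri_config()) {
  n <- length(plaque_burden_pct)
  out <- rep(NA_character_, n)
  trivial <- plaque_burden_pct < config$trivial_burden
  out[trivial] <- "trivial_plaque"
  est <- !trivial
  if (any(est & !is.finite(fvri))) {
    stop_fvri("frames with established plaque must carry a finite index.")
  }
  out[est & fvri > config$band_high] <- "ectatic"
  out[est & fvri >= config$band_low & fvri <= config$band_high] <-
    "complete_compensatory"
  low <- est & fvri < config$band_low
  out[low & eem_actual < eem_predicted] <- "negative"
  out[low & eem_actual >= eem_predicted] <- "incomplete_compensatory"
  factor(out, levels = remodeling_levels)
}

#' Score frames: predicted normal EEM, FVRI and remodeling class
#'
#' The per-frame engine: derives geometry if absent, attaches the predicted
#' normal EEM area, computes the index and classifies the remodeling pattern.
#' If the frames already carry an `eem_pred_mm2` column and `model` is NULL,
#' that column is used unchanged (e.g. simulator ground-truth normal areas).
#'
#' @param frames Frame tibble (as from [read_pullbacks()] or
#'   [simulate_cohort()]).
#' @param model A `fvri_normal_model`, or NULL to reuse an existing
#'   `eem_pred_mm2` column.
#' @param config An [fvri_config()].
#'
#' @return The input tibble with `eem_pred_mm2`, `fvri`, `remodeling_class`
#'   and `formula_variant` columns added.
#' @export
score_frames <- function(frames, model = packaged_normal_model(),
                         config = fvri_config()) {
  if (!all(c("plaque_media_area_mm2", "plaque_burden_pct") %in% names(frames))) {
    frames <- add_geometry(frames)
  }
  if (is.null(model)) {
    check_columns(frames, "eem_pred_mm2",
                  "`frames` (scoring without a model)")
  } else {
    frames <- add_predicted_eem(frames, model)
  }
  frames$fvri <- compute_fvri(frames$eem_area_mm2, frames$eem_pred_mm2,
                              frames$plaque_media_area_mm2,
                              config$formula_variant)
  frames$remodeling_class <- classify_remodeling(
    frames$fvri, frames$plaque_burden_pct,
    frames$eem_area_mm2, frames$eem_pred_mm2, config
  )
  frames$formula_variant <- config$formula_variant
  tibble::as_tibble(frames)
}

#' Mean FVRI by plaque-burden bin
#'
#' Summarises scored frames into the burden bins `<20`, `20-30`, `30-40`,
#' `40-50`, `50-60`, `>60` (ordered), with the bin mean index and its
#' standard error.
#'
#' @param scored Scored frame tibble from [score_frames()].
#'
#' @return Tibble with `burden_bin`, `n`, `mean_fvri`, `sem_fvri`.
#' @export
fvri_by_burden <- function(scored) {
  check_columns(scored, c("fvri", "plaque_burden_pct"), "`scored`")
  bins <- c("<20", "20-30", "30-40", "40-50", "50-60", ">60")
  b <- cut(scored$plaque_burden_pct, breaks = c(-Inf, 20, 30, 40, 50, 60, Inf),
           labels = bins, right = FALSE)
  # right-open except the final bin; ">60" means strictly above 60
  df <- tibble::tibble(burden_bin = b, fvri = scored$fvri)
  df <- df[is.finite(df$fvri), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$burden_bin, .drop = FALSE),
    n = dplyr::n(),
    mean_fvri = mean(.data$fvri),
    sem_fvri = sd(.data$fvri) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  out$burden_bin <- factor(out$burden_bin, levels = bins, ordered = TRUE)
  out
}
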