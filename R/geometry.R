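#' Derived IVUS cross-section geometry
#'
#' Plaque + media area is the external elastic membrane (EEM) area minus the
#' lumen area; plaque burden is the plaque + media area as a percentage of the
#' EEM area. These two quantities drive every downstream stage (training-frame
#' selection, lesion detection, remodeling classification).
#'
#' @param eem_area_mm2 EEM cross-sectional area, mm^2. Vectorised.
#' @param lumen_area_mm2 Lumen cross-sectional area, mm^2. Vectorised.
#'
#' @return A tibble with columns `plaque_media_area_mm2` and
#'   `plaque_burden_pct`.
#' @examples
#' derive_geometry(eem_area_mm2 = 14.2, lumen_area_mm2 = 8.2)
#' @export
derive_geometry <- function(eem_area_mm2, lumen_area_mm2) {
  if (!is.numeric(eem_area_mm2) || !is.numeric(lumen_area_mm2)) {
    stop_fvri("areas must be numeric.")
  }
  bad <- which(!is.finite(eem_area_mm2) | !is.finite(lumen_area_mm2) |
                 lumen_area_mm2 <= 0 | eem_area_mm2 < lumen_area_mm2)
  if (length(bad) > 0L) {
    stop_fvri(sprintf(
      "invalid frame geometry (need 0 < lumen <= EEM) at position(s): %s.",
      paste(head(bad, 5L), collapse = ", ")
    ), class = "fvri_validation_error")
  }
  plaque <- eem_area_mm2 - lumen_area_mm2
  tibble::tibble(
    plaque_media_area_mm2 = plaque,
    plaque_burden_pct = 100 * plaque / eem_area_mm2
  )
}

#' Add derived geometry columns to a frame table
#'
#' @param frames A data frame of IVUS frames with columns `eem_area_mm2` and
#'   `lumen_area_mm2` (the layout produced by [read_pullbacks()] or
#'   [simulate_cohort()]).
#'
#' @return The input tibble with `plaque_media_area_mm2` and
#'   `plaque_burden_pct` columns added (recomputed if already present).
#' @export
add_geometry <- function(frames) {
  check_columns(frames, c("eem_area_mm2", "lumen_area_mm2"), "`frames`")
  bad <- which(!is.finite(frames$eem_area_mm2) | !is.finite(frames$lumen_area_mm2) |
                 frames$lumen_area_mm2 <= 0 |
                 frames$eem_area_mm2 < frames$lumen_area_mm2)
  if (length(bad) > 0L) {
    lab <- if (all(c("patient_id", "artery_id", "frame_index") %in% names(frames))) {
      paste0(frames$patient_id[bad], "/", frames$artery_id[bad],
             " frame ", frames$frame_index[bad])
    } else {
      paste("row", bad)
    }
    stop_fvri(sprintf(
      "invalid frame geometry (need 0 < lumen <= EEM): %s%s.",
      paste(head(lab, 5L), collapse = "; "),
      if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else ""
    ), class = "fvri_validation_error")
  }
  geom <- derive_geometry(frames$eem_area_mm2, frames$lumen_area_mm2)
  frames$plaque_media_area_mm2 <- geom$plaque_media_area_mm2
  frames$plaque_burden_pct <- geom$plaque_burden_pct
  tibble::as_tibble(frames)
}

#' Add virtual-histology composition percentages
#'
#' Converts the four tissue-component areas (fibrous, fibrofatty, necrotic
#' core, dense calcium) into percentages of their sum — the confluent-plaque
#' convention, under which the four percentages always total 100 wherever any
#' component area is positive.
#'
#' @param frames A data frame with columns `fibrous_mm2`, `fibrofatty_mm2`,
#'   `necrotic_mm2`, `dense_calcium_mm2` (NAs allowed).
#'
#' @return The input tibble with `fibrous_pct`, `fibrofatty_pct`,
#'   `necrotic_pct`, `dense_calcium_pct` added (NA where the component sum is
#'   zero or composition is missing).
#' @export
add_composition_pct <- function(frames) {
  comp_cols <- c("fibrous_mm2", "fibrofatty_mm2", "necrotic_mm2", "dense_calcium_mm2")
  check_columns(frames, comp_cols, "`frames`")
  areas <- as.matrix(frames[comp_cols])
  if (any(areas < 0, na.rm = TRUE)) {
    stop_fvri("composition areas must be non-negative.",
              class = "fvri_validation_error")
  }
  total <- rowSums(areas)
  total[!is.na(total) & total <= 0] <- NA_real_
  pct <- 100 * areas / total
  colnames(pct) <- sub("_mm2$", "_pct", comp_cols)
  dplyr::bind_cols(
    tibble::as_tibble(frames[setdiff(names(frames), colnames(pct))]),
    tibble::as_tibble(pct)
  )
}
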