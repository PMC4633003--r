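# Lesion detection and lesion-level remodeling assessment.
#
# A lesion is any maximal run of at least three consecutive frames with
# plaque burden > 40%. Its representative cross-section is the frame with
# minimal lumen area (MLA). The classical remodeling index divides the MLA
# frame's EEM area by the mean EEM area of the immediate out-of-run
# neighbours (the proximal and distal references, which by maximality have
# burden <= 40%); lesions touching a pullback boundary lack a reference and
# are excluded from classical-index analysis.

classical_levels <- c("negative", "intermediate", "positive")

#' Detect lesions in scored pullbacks
#'
#' Scans each artery (frames sorted by distance) for maximal runs of plaque
#' burden strictly above `burden_threshold` of length at least `min_run`.
#' Runs are reported proximal-to-distal and never overlap. Lesion length is
#' the distance span between the first and last in-run frame.
#'
#' @param frames Frame tibble with geometry (per artery, sorted by distance).
#' @param burden_threshold Plaque-burden cutoff, percent (exclusive).
#' @param min_run Minimum run length in frames.
#'
#' @return Tibble with one row per lesion: `lesion_id`, `patient_id`,
#'   `artery_id`, `start_pos`/`end_pos` (row positions within the artery),
#'   `start_frame`/`end_frame` (frame indices), `n_frames`, `start_mm`,
#'   `end_mm`, `length_mm`.
#' @export
detect_lesions <- function(frames, burden_threshold = 40, min_run = 3) {
  check_columns(frames, c("patient_id", "artery_id", "frame_index",
                          "distance_mm", "plaque_burden_pct"), "`frames`")
  per_artery <- function(df) {
    df <- df[order(df$distance_mm), , drop = FALSE]
    r <- rle(df$plaque_burden_pct > burden_threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    s <- starts[keep]; e <- ends[keep]
    tibble::tibble(
      patient_id = df$patient_id[1], artery_id = df$artery_id[1],
      start_pos = s, end_pos = e,
      start_frame = df$frame_index[s], end_frame = df$frame_index[e],
      n_frames = e - s + 1L,
      start_mm = df$distance_mm[s], end_mm = df$distance_mm[e],
      length_mm = df$distance_mm[e] - df$distance_mm[s]
    )
  }
  out <- dplyr::bind_rows(lapply(
    split(frames, paste(frames$patient_id, frames$artery_id, sep = "\r")),
    per_artery
  ))
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      lesion_id = character(), patient_id = character(),
      artery_id = character(), start_pos = integer(), end_pos = integer(),
      start_frame = integer(), end_frame = integer(), n_frames = integer(),
      start_mm = numeric(), end_mm = numeric(), length_mm = numeric()
    ))
  }
  out <- dplyr::arrange(out, .data$patient_id, .data$artery_id,
                        .data$start_mm)
  out$lesion_id <- paste0(out$patient_id, "/", out$artery_id, "/L",
                          stats::ave(seq_len(nrow(out)),
                                     out$patient_id, out$artery_id,
                                     FUN = seq_along))
  dplyr::relocate(out, "lesion_id")
}

#' Representative (minimal lumen area) frame of a lesion
#'
#' Returns the in-run row position of the frame with minimal lumen area;
#' ties are broken towards the smallest distance (most proximal frame).
#'
#' @param lumen_areas Lumen areas of the in-lesion frames, ordered
#'   proximal-to-distal.
#'
#' @return Integer position of the MLA frame within the lesion span.
#' @export
select_mla <- function(lumen_areas) {
  if (length(lumen_areas) == 0L) stop_fvri("lesion span is empty.")
  which.min(lumen_areas) # which.min returns the first (most proximal) tie
}

#' Reference frames adjacent to a lesion
#'
#' The proximal and distal references are the immediate neighbour frames on
#' each side of the lesion run; by maximality of the run their burden is at
#' most the lesion threshold. A lesion touching the pullback boundary has the
#' corresponding reference missing (NA).
#'
#' @param start_pos,end_pos Row positions of the lesion span within its
#'   artery.
#' @param n_artery_frames Number of frames in the artery.
#'
#' @return Integer vector `c(proximal, distal)` of row positions, NA where
#'   missing.
#' @export
find_references <- function(start_pos, end_pos, n_artery_frames) {
  prox <- if (start_pos > 1L) start_pos - 1L else NA_integer_
  dist <- if (end_pos < n_artery_frames) end_pos + 1L else NA_integer_
  c(proximal = prox, distal = dist)
}

#' Classical remodeling index
#'
#' EEM area at the lesion's MLA frame divided by the mean EEM area of the
#' proximal and distal reference frames. Invariant to swapping the two
#' references.
#'
#' @param eem_mla,eem_prox,eem_dist EEM areas, mm^2. Vectorised.
#'
#' @return Numeric vector of the classical index.
#' @examples
#' classical_index(13, 14, 14)
#' @export
classical_index <- function(eem_mla, eem_prox, eem_dist) {
  bad <- which(!(eem_mla > 0 & eem_prox > 0 & eem_dist > 0))
  if (length(bad) > 0L) {
    stop_fvri(sprintf(
      "classical index needs positive EEM areas; offending position(s): %s.",
      paste(head(bad, 5L), collapse = ", ")
    ), class = "fvri_validation_error")
  }
  eem_mla / ((eem_prox + eem_dist) / 2)
}

#' Classify the classical remodeling index
#'
#' Negative below 0.88, intermediate in the inclusive band 0.88--1.00,
#' positive above 1.00.
#'
#' @param index Classical index values (NA allowed).
#' @param cuts Length-2 numeric, the lower and upper cutoffs.
#'
#' @return Factor with levels negative, intermediate, positive.
#' @export
classify_classical <- function(index, cuts = c(0.88, 1.00)) {
  if (any(index <= 0, na.rm = TRUE)) {
    stop_fvri("classical index must be positive.")
  }
  out <- rep(NA_character_, length(index))
  out[index < cuts[1]] <- "negative"
  out[index >= cuts[1] & index <= cuts[2]] <- "intermediate"
  out[index > cuts[2]] <- "positive"
  factor(out, levels = classical_levels)
}

#' Assess lesions under both remodeling schemes
#'
#' Detects lesions, takes each lesion's index and FVRI class from its MLA
#' frame, finds the adjacent references, and computes the classical index and
#' class where both references exist. Lesions missing a reference are kept in
#' the output with NA classical columns and reported via a message; they are
#' excluded from agreement analysis.
#'
#' @param scored Scored frame tibble from [score_frames()].
#' @param burden_threshold,min_run Lesion definition; see [detect_lesions()].
#' @param classical_cuts Classical classification cutoffs; see
#'   [classify_classical()].
#'
#' @return Tibble with one row per lesion: span and length, MLA geometry,
#'   `fvri`, `fvri_class`, reference EEM areas, `classical_index`,
#'   `classical_class`, `has_references`, and the four composition
#'   percentages at the MLA frame (NA where composition is absent).
#' @export
assess_lesions <- function(scored, burden_threshold = 40, min_run = 3,
                           classical_cuts = c(0.88, 1.00)) {
  check_columns(scored, c("fvri", "remodeling_class", "eem_pred_mm2"),
                "`scored` (run score_frames() first)")
  lesions <- detect_lesions(scored, burden_threshold, min_run)
  if (nrow(lesions) == 0L) {
    return(dplyr::mutate(
      lesions,
      mla_frame = integer(), mla_distance_mm = numeric(),
      mla_lumen_mm2 = numeric(), mla_eem_mm2 = numeric(),
      plaque_burden_pct = numeric(), eem_pred_mm2 = numeric(),
      fvri = numeric(),
      fvri_class = factor(character(), levels = remodeling_levels),
      eem_prox_mm2 = numeric(), eem_dist_mm2 = numeric(),
      classical_index = numeric(),
      classical_class = factor(character(), levels = classical_levels),
      has_references = logical(),
      fibrous_pct = numeric(), fibrofatty_pct = numeric(),
      necrotic_pct = numeric(), dense_calcium_pct = numeric()
    ))
  }

  has_comp <- all(c("fibrous_mm2", "fibrofatty_mm2", "necrotic_mm2",
                    "dense_calcium_mm2") %in% names(scored))
  if (has_comp) scored <- add_composition_pct(scored)

  arteries <- split(scored, paste(scored$patient_id, scored$artery_id,
                                  sep = "\r"))
  arteries <- lapply(arteries, function(df) df[order(df$distance_mm), ,
                                               drop = FALSE])
  one <- function(i) {
    les <- lesions[i, ]
    art <- arteries[[paste(les$patient_id, les$artery_id, sep = "\r")]]
    span <- les$start_pos:les$end_pos
    mla_rel <- select_mla(art$lumen_area_mm2[span])
    mla <- span[mla_rel]
    refs <- find_references(les$start_pos, les$end_pos, nrow(art))
    eem_prox <- if (is.na(refs["proximal"])) NA_real_ else
      art$eem_area_mm2[refs["proximal"]]
    eem_dist <- if (is.na(refs["distal"])) NA_real_ else
      art$eem_area_mm2[refs["distal"]]
    has_refs <- is.finite(eem_prox) && is.finite(eem_dist)
    ci <- if (has_refs) {
      classical_index(art$eem_area_mm2[mla], eem_prox, eem_dist)
    } else {
      NA_real_
    }
    comp <- if (has_comp) {
      art[mla, c("fibrous_pct", "fibrofatty_pct", "necrotic_pct",
                 "dense_calcium_pct")]
    } else {
      tibble::tibble(fibrous_pct = NA_real_, fibrofatty_pct = NA_real_,
                     necrotic_pct = NA_real_, dense_calcium_pct = NA_real_)
    }
    dplyr::bind_cols(
      les,
      tibble::tibble(
        mla_frame = art$frame_index[mla],
        mla_distance_mm = art$distance_mm[mla],
        mla_lumen_mm2 = art$lumen_area_mm2[mla],
        mla_eem_mm2 = art$eem_area_mm2[mla],
        plaque_burden_pct = art$plaque_burden_pct[mla],
        eem_pred_mm2 = art$eem_pred_mm2[mla],
        fvri = art$fvri[mla],
        fvri_class = art$remodeling_class[mla],
        eem_prox_mm2 = eem_prox, eem_dist_mm2 = eem_dist,
        classical_index = ci,
        has_references = has_refs
      ),
      comp
    )
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(lesions)), one))
  out$classical_class <- classify_classical(out$classical_index,
                                            classical_cuts)
  out <- dplyr::relocate(out, "classical_class", .after = "classical_index")
  n_excl <- sum(!out$has_references)
  if (n_excl > 0L) {
    rlang::inform(sprintf(
      "%d of %d lesion(s) touch a pullback boundary and lack a reference; excluded from classical-index analysis.",
      n_excl, nrow(out)
    ))
  }
  out
}
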