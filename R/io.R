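# Table I/O for pullbacks.
#
# frames.csv : patient_id, artery_id, vessel in {LM,LAD,LCX,RCA}, frame_index,
#              distance_mm, lumen_area_mm2, eem_area_mm2, fibrous_mm2,
#              fibrofatty_mm2, necrotic_mm2, dense_calcium_mm2 (last four
#              optional, blank allowed).
# patients.csv : patient_id, weight_kg, height_cm, bsa_m2 (optional; computed
#              when blank), dominance in {right,left,balanced}.

frame_cols_required <- c(
  "patient_id", "artery_id", "vessel", "frame_index",
  "distance_mm", "lumen_area_mm2", "eem_area_mm2"
)
frame_cols_composition <- c(
  "fibrous_mm2", "fibrofatty_mm2", "necrotic_mm2", "dense_calcium_mm2"
)
known_vessels <- c("LM", "LAD", "LCX", "RCA")

#' Read and validate IVUS pullback tables
#'
#' Reads a per-frame measurement table and a per-patient covariate table,
#' validates every structural invariant (positive areas, lumen not exceeding
#' EEM, strictly increasing distances within an artery, known vessel labels,
#' known dominance levels), joins patient covariates onto the frames, computes
#' body surface area where absent, and derives plaque geometry. Rows for
#' vessels outside LM/LAD/LCX/RCA are dropped with a warning. Validation
#' failures are reported with the offending file row numbers.
#'
#' @param frames_path Path to `frames.csv`.
#' @param patients_path Path to `patients.csv`.
#' @param bsa_formula BSA formula used when `bsa_m2` is blank; see
#'   [compute_bsa()].
#'
#' @return A tibble of frames sorted by patient, artery and distance, with
#'   patient covariates (`weight_kg`, `height_cm`, `bsa_m2`, `dominance`) and
#'   derived geometry columns attached.
#' @export
read_pullbacks <- function(frames_path, patients_path,
                           bsa_formula = c("mosteller", "dubois")) {
  bsa_formula <- match.arg(bsa_formula)
  patients <- readr::read_csv(patients_path, show_col_types = FALSE,
                              progress = FALSE)
  check_columns(patients, c("patient_id", "weight_kg", "height_cm", "dominance"),
                "patients table")
  patients$patient_id <- as.character(patients$patient_id)
  if (!"bsa_m2" %in% names(patients)) patients$bsa_m2 <- NA_real_
  bad_dom <- which(!patients$dominance %in% c("right", "left", "balanced"))
  if (length(bad_dom) > 0L) {
    stop_fvri(sprintf(
      "patients table: unknown dominance level(s) %s at row(s) %s.",
      paste(unique(patients$dominance[bad_dom]), collapse = ", "),
      paste(bad_dom + 1L, collapse = ", ")
    ), class = "fvri_validation_error")
  }
  bad_anthro <- which(!is.finite(patients$weight_kg) | patients$weight_kg <= 0 |
                        !is.finite(patients$height_cm) | patients$height_cm <= 0)
  if (length(bad_anthro) > 0L) {
    stop_fvri(sprintf(
      "patients table: nonpositive weight or height at row(s) %s.",
      paste(bad_anthro + 1L, collapse = ", ")
    ), class = "fvri_validation_error")
  }
  fill <- is.na(patients$bsa_m2)
  patients$bsa_m2[fill] <- compute_bsa(patients$weight_kg[fill],
                                       patients$height_cm[fill],
                                       formula = bsa_formula)

  frames <- readr::read_csv(frames_path, show_col_types = FALSE,
                            progress = FALSE)
  check_columns(frames, frame_cols_required, "frames table")
  frames$patient_id <- as.character(frames$patient_id)
  frames$artery_id <- as.character(frames$artery_id)
  frames$vessel <- toupper(as.character(frames$vessel))
  for (col in frame_cols_composition) {
    if (!col %in% names(frames)) frames[[col]] <- NA_real_
  }
  frames$.row <- seq_len(nrow(frames)) + 1L # header is file row 1

  unknown <- !frames$vessel %in% known_vessels
  if (any(unknown)) {
    rlang::warn(sprintf(
      "dropping %d frame(s) from unsupported vessel label(s): %s.",
      sum(unknown), paste(unique(frames$vessel[unknown]), collapse = ", ")
    ))
    frames <- frames[!unknown, , drop = FALSE]
  }
  if (nrow(frames) == 0L) {
    stop_fvri("frames table contains no usable rows.",
              class = "fvri_validation_error")
  }

  bad_geom <- which(!is.finite(frames$lumen_area_mm2) |
                      !is.finite(frames$eem_area_mm2) |
                      frames$lumen_area_mm2 <= 0 |
                      frames$eem_area_mm2 < frames$lumen_area_mm2)
  if (length(bad_geom) > 0L) {
    stop_fvri(sprintf(
      "frames table: lumen/EEM geometry invalid (need 0 < lumen <= EEM) at file row(s) %s.",
      paste(head(frames$.row[bad_geom], 10L), collapse = ", ")
    ), class = "fvri_validation_error")
  }
  if (any(frames$distance_mm < 0)) {
    stop_fvri(sprintf(
      "frames table: negative distance at file row(s) %s.",
      paste(head(frames$.row[frames$distance_mm < 0], 10L), collapse = ", ")
    ), class = "fvri_validation_error")
  }

  missing_pat <- setdiff(unique(frames$patient_id), patients$patient_id)
  if (length(missing_pat) > 0L) {
    stop_fvri(sprintf(
      "frames reference patient(s) absent from the patients table: %s.",
      paste(missing_pat, collapse = ", ")
    ), class = "fvri_validation_error")
  }

  frames <- dplyr::arrange(frames, .data$patient_id, .data$artery_id,
                           .data$frame_index)
  # within an artery, frame_index order must coincide with strictly
  # increasing distance
  mono <- dplyr::summarise(
    dplyr::group_by(frames, .data$patient_id, .data$artery_id),
    bad_row = {
      d <- diff(.data$distance_mm)
      i <- which(d <= 0)
      if (length(i) > 0L) .data$.row[i[1] + 1L] else NA_integer_
    },
    .groups = "drop"
  )
  if (any(!is.na(mono$bad_row))) {
    stop_fvri(sprintf(
      "frames table: distances not strictly increasing with frame_index within an artery; first offence at file row(s) %s.",
      paste(mono$bad_row[!is.na(mono$bad_row)], collapse = ", ")
    ), class = "fvri_validation_error")
  }

  frames$.row <- NULL
  frames <- dplyr::left_join(
    frames,
    patients[c("patient_id", "weight_kg", "height_cm", "bsa_m2", "dominance")],
    by = "patient_id"
  )
  add_geometry(tibble::as_tibble(frames))
}

#' Write pullback tables
#'
#' Writes `frames.csv` and `patients.csv` in the schemas read by
#' [read_pullbacks()]. Numeric fields are serialised at 6 decimal places, so a
#' read/write/read round trip preserves them exactly at that precision.
#'
#' @param frames Frame tibble (as from [read_pullbacks()] or
#'   [simulate_cohort()]); derived and joined columns are not written.
#' @param patients Patient tibble with `patient_id`, `weight_kg`, `height_cm`,
#'   `bsa_m2`, `dominance`.
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the paths of the two files written.
#' @export
write_pullbacks <- function(frames, patients, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  round6 <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) round(x, 6) else x)
    df
  }
  fr <- frames[intersect(c(frame_cols_required, frame_cols_composition),
                         names(frames))]
  pt <- patients[intersect(c("patient_id", "weight_kg", "height_cm",
                             "bsa_m2", "dominance"), names(patients))]
  frames_path <- file.path(dir, "frames.csv")
  patients_path <- file.path(dir, "patients.csv")
  readr::write_csv(round6(fr), frames_path, progress = FALSE)
  readr::write_csv(round6(pt), patients_path, progress = FALSE)
  invisible(c(frames = frames_path, patients = patients_path))
}
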