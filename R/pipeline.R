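# End-to-end pipeline: read -> (fit | packaged model) -> score -> lesions ->
# agreement -> report.

#' Pipeline configuration
#'
#' Aggregates every stage threshold with the published defaults: trivial
#' burden 20%, lesion burden 40% over at least 3 frames, FVRI band
#' 0.83--1.17, classical cutoffs 0.88/1.00, training lumen range
#' 3.1--19.6 mm^2.
#'
#' @param trivial_burden,band_low,band_high,formula_variant See
#'   [fvri_config()].
#' @param lesion_burden,min_run See [detect_lesions()].
#' @param classical_cuts See [classify_classical()].
#' @param lumen_range See [select_training_frames()].
#' @param model_source `"packaged"` (use [packaged_normal_model()]) or
#'   `"fit"` (bootstrap-fit the model on the input's own near-normal frames).
#' @param n_bootstrap,resample Bootstrap settings when `model_source` is
#'   `"fit"`.
#' @param seed Integer seed used for any stochastic stage.
#'
#' @return A list of class `fvri_run_config`.
#' @export
run_config <- function(trivial_burden = 20, lesion_burden = 40, min_run = 3,
                       band_low = 0.83, band_high = 1.17,
                       classical_cuts = c(0.88, 1.00),
                       lumen_range = c(3.1, 19.6),
                       formula_variant = c("compensation_ratio",
                                           "lumen_ratio"),
                       model_source = c("packaged", "fit"),
                       n_bootstrap = 5000, resample = "patient",
                       seed = 1L) {
  formula_variant <- match.arg(formula_variant)
  model_source <- match.arg(model_source)
  stopifnot(
    classical_cuts[1] < classical_cuts[2], all(classical_cuts > 0),
    lumen_range[1] > 0, lumen_range[1] < lumen_range[2],
    trivial_burden < lesion_burden
  )
  fvri_cfg <- fvri_config(band_low, band_high, trivial_burden,
                          formula_variant)
  structure(
    list(trivial_burden = trivial_burden, lesion_burden = lesion_burden,
         min_run = min_run, band_low = band_low, band_high = band_high,
         classical_cuts = classical_cuts, lumen_range = lumen_range,
         formula_variant = formula_variant, model_source = model_source,
         n_bootstrap = n_bootstrap, resample = resample,
         seed = as.integer(seed), fvri_config = fvri_cfg),
    class = "fvri_run_config"
  )
}

#' Run the full remodeling analysis pipeline
#'
#' Scores every frame, detects and assesses lesions, tabulates scheme
#' agreement and composition contrasts, and logs the counts surviving each
#' filter. Deterministic for a given input and config seed.
#'
#' @param frames Frame tibble (from [read_pullbacks()] or
#'   [simulate_cohort()]`$frames`), or a path to `frames.csv` if
#'   `patients` is a path to `patients.csv`.
#' @param patients Optional path to `patients.csv` when `frames` is a path.
#' @param config A [run_config()].
#' @param model Optional pre-built `fvri_normal_model`; overrides
#'   `config$model_source`.
#'
#' @return A list of class `fvri_results`: `config` (with hash), `model`,
#'   `frames_scored`, `lesions`, `agreement` (NULL when no lesion has both
#'   references), `composition_fvri` / `composition_classical` (NULL without
#'   composition data), and `log` (named counts at each filter).
#' @export
run_pipeline <- function(frames, patients = NULL, config = run_config(),
                         model = NULL) {
  if (is.character(frames)) {
    if (is.null(patients)) {
      stop_fvri("when `frames` is a path, `patients` must be the patients.csv path.")
    }
    frames <- read_pullbacks(frames, patients)
  }
  frames <- if (all(c("plaque_media_area_mm2", "plaque_burden_pct") %in%
                      names(frames))) {
    tibble::as_tibble(frames)
  } else {
    add_geometry(frames)
  }
  log <- c(frames_read = nrow(frames))

  if (is.null(model)) {
    model <- if (config$model_source == "packaged") {
      packaged_normal_model()
    } else {
      training <- select_training_frames(frames, config$lumen_range,
                                         config$trivial_burden)
      log <- c(log, training_frames = nrow(training))
      bootstrap_normal_model(training, n_bootstrap = config$n_bootstrap,
                             seed = config$seed,
                             resample = config$resample)
    }
  }

  scored <- score_frames(frames, model, config$fvri_config)
  log <- c(log, frames_classified = sum(
    scored$remodeling_class != "trivial_plaque", na.rm = TRUE
  ))

  lesions <- assess_lesions(scored, config$lesion_burden, config$min_run,
                            config$classical_cuts)
  log <- c(log, lesions = nrow(lesions),
           lesions_with_references = sum(lesions$has_references))

  agreement <- if (any(lesions$has_references &
                         lesions$fvri_class %in% fvri_agreement_rows)) {
    agreement_table(lesions)
  } else {
    NULL
  }

  has_comp <- nrow(lesions) > 0L && any(is.finite(lesions$fibrous_pct))
  comp_fvri <- comp_classical <- NULL
  if (has_comp) {
    comp_fvri <- tryCatch(composition_by_class(lesions, "fvri"),
                          error = function(e) NULL, warning = function(w) NULL)
    comp_classical <- tryCatch(composition_by_class(lesions, "classical"),
                               error = function(e) NULL,
                               warning = function(w) NULL)
  }

  cfg_out <- config
  cfg_out$hash <- rlang::hash(config)
  structure(
    list(config = cfg_out, model = model, frames_scored = scored,
         lesions = lesions, agreement = agreement,
         composition_fvri = comp_fvri,
         composition_classical = comp_classical, log = log),
    class = "fvri_results"
  )
}

#' @export
print.fvri_results <- function(x, ...) {
  cat("<fvri_results>\n")
  cat(paste0("  ", names(x$log), ": ", x$log, collapse = "\n"), "\n")
  if (!is.null(x$agreement)) {
    cat(sprintf("  concordance (named pairs): %.1f%%\n",
                x$agreement$concordance_named_pct))
  }
  invisible(x)
}

class_frequency <- function(cls, drop_trivial = FALSE) {
  cls <- cls[!is.na(cls)]
  if (drop_trivial) cls <- cls[cls != "trivial_plaque"]
  tab <- table(droplevels(factor(cls)))
  tibble::tibble(
    class = names(tab),
    n = as.integer(tab),
    pct = 100 * as.integer(tab) / sum(tab)
  )
}

#' Render a Markdown report of pipeline results
#'
#' Five sections mirroring the headline outputs of a remodeling study:
#' frame-class frequencies (among frames with established plaque),
#' lesion-class frequencies under both schemes, the agreement matrix with
#' marginals, mean FVRI by plaque-burden bin, and composition by class.
#' Every number in the report is recomputable from the result tables. The
#' config hash and seed are embedded.
#'
#' @param results A `fvri_results` from [run_pipeline()].
#' @param path Optional file path; when given the report is written there.
#'
#' @return The report as a character vector of lines (invisibly when `path`
#'   is given).
#' @export
render_report <- function(results, path = NULL) {
  stopifnot(inherits(results, "fvri_results"))
  ln <- c(
    "# Coronary remodeling report",
    "",
    sprintf("- config hash: `%s`; seed: %d", results$config$hash,
            results$config$seed),
    sprintf("- model: %s (adjusted R^2 %.2f)", results$model$name,
            results$model$adjusted_r2),
    paste0("- ", names(results$log), ": ", results$log),
    "",
    "## Frame remodeling classes (plaque burden >= trivial cutoff)",
    ""
  )
  ln <- c(ln, md_table(class_frequency(
    results$frames_scored$remodeling_class, drop_trivial = TRUE
  )))

  ln <- c(ln, "", "## Lesion remodeling classes", "")
  if (nrow(results$lesions) == 0L) {
    ln <- c(ln, "Zero lesions detected; no lesion-level analysis.")
  } else {
    ln <- c(ln, "FVRI-based:", "",
            md_table(class_frequency(results$lesions$fvri_class)), "",
            "Classical (lesions with both references):", "",
            md_table(class_frequency(results$lesions$classical_class)))
  }

  ln <- c(ln, "", "## Scheme agreement", "")
  if (is.null(results$agreement)) {
    ln <- c(ln, "No lesions with both references; no agreement analysis.")
  } else {
    a <- results$agreement
    counts <- tibble::as_tibble(cbind(
      data.frame(fvri_class = rownames(a$counts)),
      as.data.frame.matrix(a$counts),
      total = unname(a$row_marginals)
    ))
    ln <- c(ln, md_table(counts), "",
            sprintf("Column totals: %s; n = %d.",
                    paste(sprintf("%s %d (%.1f%%)", colnames(a$counts),
                                  a$col_marginals, a$col_marginals_pct),
                          collapse = ", "), a$n),
            sprintf("Concordance (named pairs) %.1f%%; overall agreement incl. ectatic/positive %.1f%%; kappa (3x3 collapse, added diagnostic) %.3f.",
                    a$concordance_named_pct, a$overall_agreement_pct, a$kappa))
  }

  ln <- c(ln, "", "## Mean FVRI by plaque-burden bin", "",
          md_table(fvri_by_burden(results$frames_scored)))

  ln <- c(ln, "", "## Plaque composition by remodeling class", "")
  if (is.null(results$composition_fvri)) {
    ln <- c(ln, "No composition data.")
  } else {
    ln <- c(ln, "FVRI classes:", "", md_table(results$composition_fvri))
    if (!is.null(results$composition_classical)) {
      ln <- c(ln, "", "Classical classes:", "",
              md_table(results$composition_classical))
    }
  }

  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}

#' Write pipeline result tables
#'
#' Emits `frames_scored.csv`, `lesions.csv`, `agreement.json`, `model.json`
#' and `report.md` into a directory.
#'
#' @param results A `fvri_results`.
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    frames_scored = file.path(dir, "frames_scored.csv"),
    lesions = file.path(dir, "lesions.csv"),
    model = file.path(dir, "model.json"),
    report = file.path(dir, "report.md")
  )
  readr::write_csv(results$frames_scored, paths["frames_scored"],
                   progress = FALSE, na = "")
  readr::write_csv(results$lesions, paths["lesions"], progress = FALSE,
                   na = "")
  write_normal_model(results$model, paths["model"])
  render_report(results, paths["report"])
  if (!is.null(results$agreement)) {
    a <- results$agreement
    paths <- c(paths, agreement = file.path(dir, "agreement.json"))
    jsonlite::write_json(
      list(
        counts = a$counts, n = a$n,
        row_marginals = a$row_marginals, col_marginals = a$col_marginals,
        row_marginals_pct = a$row_marginals_pct,
        col_marginals_pct = a$col_marginals_pct,
        concordance_named_pct = a$concordance_named_pct,
        overall_agreement_pct = a$overall_agreement_pct,
        kappa = a$kappa,
        mean_fvri_by_classical_class = a$mean_fvri_by_col,
        mean_classical_by_fvri_class = a$mean_classical_by_row,
        config_hash = results$config$hash, seed = results$config$seed
      ),
      paths["agreement"], auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(paths)
}
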