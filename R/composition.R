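# Virtual-histology plaque composition across remodeling classes.

tissue_pct_cols <- c("fibrous_pct", "fibrofatty_pct", "necrotic_pct",
                     "dense_calcium_pct")

#' Compare plaque composition across remodeling classes
#'
#' For each of the four virtual-histology tissue percentages (fibrous,
#' fibrofatty, necrotic core, dense calcium) at the lesion MLA frame,
#' computes group means per remodeling class and a classic one-way ANOVA
#' (equal-variance F test) across classes under the chosen scheme. A tissue
#' with missing composition is skipped with a warning. At least two classes
#' with at least two lesions each are required.
#'
#' @param assessments Lesion tibble from [assess_lesions()] with composition
#'   percentages.
#' @param grouping `"fvri"` (four classes) or `"classical"` (three classes).
#'
#' @return Tibble with one row per tissue and class: `tissue`, `class`, `n`,
#'   `mean_pct`, `sd_pct`, plus the tissue-level `statistic` (F), `df`,
#'   `df_resid` and `p_value` repeated within tissue.
#' @export
composition_by_class <- function(assessments,
                                 grouping = c("fvri", "classical")) {
  grouping <- match.arg(grouping)
  class_col <- if (grouping == "fvri") "fvri_class" else "classical_class"
  check_columns(assessments, c(class_col, tissue_pct_cols), "`assessments`")

  cls <- assessments[[class_col]]
  keep <- !is.na(cls) & as.character(cls) != "trivial_plaque"
  out <- list()
  for (tissue in tissue_pct_cols) {
    y <- assessments[[tissue]][keep]
    g <- droplevels(factor(cls[keep]))
    ok <- is.finite(y)
    y <- y[ok]; g <- droplevels(g[ok])
    # classes represented by a single lesion carry no within-group variance
    # information; drop them from the contrast
    tab <- table(g)
    keep_cls <- names(tab)[tab >= 2L]
    y <- y[g %in% keep_cls]
    g <- droplevels(g[g %in% keep_cls])
    tab <- table(g)
    if (length(tab) < 2L) {
      rlang::warn(sprintf(
        "tissue %s skipped: need >= 2 classes with >= 2 lesions each.",
        tissue
      ))
      next
    }
    fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
    means <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(y = y, class = g), .data$class),
      n = dplyr::n(), mean_pct = mean(.data$y), sd_pct = sd(.data$y),
      .groups = "drop"
    )
    means$tissue <- sub("_pct$", "", tissue)
    means$statistic <- unname(fit$statistic)
    means$df <- unname(fit$parameter[1])
    means$df_resid <- unname(fit$parameter[2])
    means$p_value <- unname(fit$p.value)
    out[[tissue]] <- means
  }
  if (length(out) == 0L) {
    stop_fvri("no tissue had usable composition data.",
              class = "fvri_validation_error")
  }
  dplyr::relocate(dplyr::bind_rows(out), "tissue")
}
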