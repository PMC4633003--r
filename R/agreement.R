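# Agreement between the FVRI-based and classical remodeling classifications.
#
# The 4x3 cross-tabulation (FVRI classes negative / incomplete / complete /
# ectatic against classical negative / intermediate / positive) is summarised
# by the percentage of lesions in concordant cells. Negative pairs with
# negative and incomplete with intermediate; both complete compensatory and
# ectatic denote expansion and pair with positive. The headline
# `concordance_named_pct` counts the three concordant pairs
# negative/negative, incomplete/intermediate and complete/positive;
# `overall_agreement_pct` additionally counts ectatic/positive. Cohen's
# kappa (an added diagnostic, not part of the original scheme) is computed
# on the 3x3 collapse with ectatic merged into complete.

fvri_agreement_rows <- c("negative", "incomplete_compensatory",
                         "complete_compensatory", "ectatic")

new_agreement <- function(counts, mean_fvri_by_col = NULL,
                          mean_classical_by_row = NULL) {
  total <- sum(counts)
  if (total < 1) stop_fvri("agreement table needs at least one lesion.")
  row_marg <- rowSums(counts)
  col_marg <- colSums(counts)
  named <- counts["negative", "negative"] +
    counts["incomplete_compensatory", "intermediate"] +
    counts["complete_compensatory", "positive"]
  concordant <- named + counts["ectatic", "positive"]

  # kappa on the 3x3 collapse (ectatic merged into complete_compensatory),
  # with FVRI rows mapped onto the classical columns they pair with
  collapsed <- rbind(
    counts["negative", ],
    counts["incomplete_compensatory", ],
    counts["complete_compensatory", ] + counts["ectatic", ]
  )
  po <- sum(diag(collapsed)) / total
  pe <- sum(rowSums(collapsed) * colSums(collapsed)) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_

  structure(
    list(
      counts = counts, n = total,
      row_marginals = row_marg, col_marginals = col_marg,
      row_marginals_pct = 100 * row_marg / total,
      col_marginals_pct = 100 * col_marg / total,
      cell_pct = 100 * counts / total,
      concordance_named_pct = 100 * named / total,
      overall_agreement_pct = 100 * concordant / total,
      kappa = kappa,
      mean_fvri_by_col = mean_fvri_by_col,
      mean_classical_by_row = mean_classical_by_row
    ),
    class = "fvri_agreement"
  )
}

#' Cross-tabulate the two remodeling classifications
#'
#' Builds the 4x3 agreement table over lesions that have both references
#' (trivial-plaque lesions and lesions lacking a reference are dropped), with
#' marginals, concordance percentages, Cohen's kappa on the 3x3 collapse, and
#' the mean index of each scheme within the other scheme's classes.
#'
#' @param assessments Lesion tibble from [assess_lesions()].
#'
#' @return An object of class `fvri_agreement`.
#' @export
agreement_table <- function(assessments) {
  check_columns(assessments, c("fvri_class", "classical_class", "fvri",
                               "classical_index"), "`assessments`")
  keep <- !is.na(assessments$classical_class) &
    assessments$fvri_class %in% fvri_agreement_rows
  df <- assessments[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop_fvri("no lesions with both references to tabulate.")
  }
  counts <- table(
    factor(as.character(df$fvri_class), levels = fvri_agreement_rows),
    factor(as.character(df$classical_class), levels = classical_levels)
  )
  counts <- unclass(counts)
  mean_fvri_by_col <- tapply(df$fvri, df$classical_class, mean)
  mean_classical_by_row <- tapply(
    df$classical_index,
    factor(as.character(df$fvri_class), levels = fvri_agreement_rows),
    mean
  )
  new_agreement(counts, mean_fvri_by_col[classical_levels],
                mean_classical_by_row[fvri_agreement_rows])
}

#' Agreement table from a printed counts matrix
#'
#' Builds the same summaries as [agreement_table()] directly from a 4x3
#' matrix of lesion counts (FVRI classes in rows ordered negative,
#' incomplete, complete, ectatic; classical classes in columns ordered
#' negative, intermediate, positive), e.g. a published contingency table.
#'
#' @param counts 4x3 numeric matrix of lesion counts.
#'
#' @return An object of class `fvri_agreement`.
#' @export
agreement_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 3L))) {
    stop_fvri("`counts` must be a 4x3 matrix (FVRI classes x classical classes).")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_fvri("`counts` must contain non-negative integers.")
  }
  dimnames(counts) <- list(fvri_agreement_rows, classical_levels)
  new_agreement(counts)
}

#' @export
print.fvri_agreement <- function(x, ...) {
  cat(sprintf("<fvri_agreement: %d lesions>\n", x$n))
  print(x$counts)
  cat(sprintf("FVRI-class marginals (%%): %s\n",
              paste(sprintf("%s %.1f", rownames(x$counts),
                            x$row_marginals_pct), collapse = "; ")))
  cat(sprintf("classical-class marginals (%%): %s\n",
              paste(sprintf("%s %.1f", colnames(x$counts),
                            x$col_marginals_pct), collapse = "; ")))
  cat(sprintf("concordance (named pairs) = %.1f%%; overall agreement (incl. ectatic/positive) = %.1f%%; kappa (3x3 collapse) = %.3f\n",
              x$concordance_named_pct, x$overall_agreement_pct, x$kappa))
  invisible(x)
}

#' @describeIn agreement_table Tidy cell-level view: one row per cell with
#'   counts, percentages and a concordance flag.
#' @param x A `fvri_agreement`.
#' @param ... Unused.
#' @export
tidy.fvri_agreement <- function(x, ...) {
  grid <- expand.grid(fvri_class = fvri_agreement_rows,
                      classical_class = classical_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  concord <- c("negative.negative", "incomplete_compensatory.intermediate",
               "complete_compensatory.positive", "ectatic.positive")
  tibble::tibble(
    fvri_class = grid$fvri_class,
    classical_class = grid$classical_class,
    n = as.vector(x$counts[cbind(grid$fvri_class, grid$classical_class)]),
    pct = as.vector(x$cell_pct[cbind(grid$fvri_class, grid$classical_class)]),
    concordant = paste(grid$fvri_class, grid$classical_class, sep = ".") %in%
      concord
  )
}

#' @export
glance.fvri_agreement <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    concordance_named_pct = x$concordance_named_pct,
    overall_agreement_pct = x$overall_agreement_pct,
    kappa = x$kappa
  )
}
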