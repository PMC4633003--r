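#' Body surface area from weight and height
#'
#' Computes body surface area (BSA, m^2), the constitutional covariate of the
#' normal vessel dimension model. The Mosteller formula
#' \eqn{\sqrt{wh/3600}} is the default; the Du Bois formula
#' \eqn{0.007184\,w^{0.425}h^{0.725}} is selectable.
#'
#' @param weight_kg Body weight in kilograms. Vectorised.
#' @param height_cm Body height in centimetres. Vectorised.
#' @param formula `"mosteller"` (default) or `"dubois"`.
#'
#' @return Numeric vector of BSA in m^2.
#' @examples
#' compute_bsa(72, 161.6)
#' compute_bsa(80, 175, formula = "dubois")
#' @export
compute_bsa <- function(weight_kg, height_cm, formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  if (!is.numeric(weight_kg) || !is.numeric(height_cm)) {
    stop_fvri("`weight_kg` and `height_cm` must be numeric.")
  }
  bad <- which(!is.finite(weight_kg) | !is.finite(height_cm) |
                 weight_kg <= 0 | height_cm <= 0)
  if (length(bad) > 0L) {
    stop_fvri(sprintf(
      "weight and height must be positive; offending position(s): %s.",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  switch(formula,
    mosteller = sqrt(weight_kg * height_cm / 3600),
    dubois = 0.007184 * weight_kg^0.425 * height_cm^0.725
  )
}
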