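# Normal vessel dimension model.
#
# The remodeling index needs the EEM area each cross-section would have had
# before plaque formed. In early disease the lumen is preserved, and on IVUS
# the lumen and EEM coincide when plaque is absent; so frames with plaque
# burden < 20% supply observations of the normal vessel calibre, and a
# multivariable linear model maps constitutional/anatomical covariates
# (coronary dominance, vessel, log distance from the ostium, body surface
# area) to that normal lumen area. The fit is stabilised by bootstrap
# resampling, with the final equation taken from the bootstrapped
# B-coefficients.

default_vessel_coding <- c(LM = 0, LAD = 1, LCX = 2, RCA = 3)
model_terms <- c("intercept", "dominance", "vessel", "log_distance", "bsa")
default_lumen_range <- c(3.1, 19.6)

#' Select near-normal training frames
#'
#' Frames assumed to retain their normal lumen dimensions: plaque burden
#' below 20% and lumen area within 3.1--19.6 mm^2 (average vessel diameter
#' 2.0--5.0 mm; bounds inclusive), the window of clinically relevant coronary
#' calibres.
#'
#' @param frames Frame tibble with geometry and patient covariates (from
#'   [read_pullbacks()] or [simulate_cohort()]).
#' @param lumen_range Inclusive lumen-area bounds, mm^2.
#' @param trivial_burden Plaque-burden cutoff, percent; frames strictly below
#'   it are treated as near-normal.
#'
#' @return The selected frames as a tibble.
#' @export
select_training_frames <- function(frames,
                                   lumen_range = default_lumen_range,
                                   trivial_burden = 20) {
  check_columns(frames, c("lumen_area_mm2", "plaque_burden_pct"), "`frames`")
  keep <- frames$plaque_burden_pct < trivial_burden &
    frames$lumen_area_mm2 >= lumen_range[1] &
    frames$lumen_area_mm2 <= lumen_range[2]
  out <- tibble::as_tibble(frames[keep, , drop = FALSE])
  if (nrow(out) == 0L) {
    stop_fvri(paste0(
      "no training frames satisfy plaque burden < ", trivial_burden,
      "% with lumen in [", lumen_range[1], ", ", lumen_range[2],
      "] mm^2; supply a larger or less diseased input."
    ), class = "fvri_empty_selection")
  }
  out
}

#' Covariate design matrix for the normal dimension model
#'
#' Builds the (dominance indicator, vessel code, log distance, BSA) design.
#' Dominance is a binary indicator (0 = right-dominant reference, 1 = left or
#' balanced). The vessel enters as a single ordinal code (default LM 0, LAD 1,
#' LCX 2, RCA 3). Distance from the ostium enters as its natural logarithm,
#' clamped below at 1 mm so the ostium itself maps to 0.
#'
#' @param frames Frame tibble with `dominance`, `vessel`, `distance_mm`,
#'   `bsa_m2`.
#' @param vessel_coding Named numeric map from vessel label to code.
#' @param log_clamp_mm Distances below this value (mm) are clamped before the
#'   logarithm.
#'
#' @return Numeric matrix with columns `dominance`, `vessel`, `log_distance`,
#'   `bsa`.
#' @export
normal_design_matrix <- function(frames,
                                 vessel_coding = default_vessel_coding,
                                 log_clamp_mm = 1) {
  check_columns(frames, c("dominance", "vessel", "distance_mm", "bsa_m2"),
                "`frames`")
  unknown <- setdiff(unique(frames$vessel), names(vessel_coding))
  if (length(unknown) > 0L) {
    stop_fvri(sprintf("vessel label(s) outside the coding map: %s.",
                      paste(unknown, collapse = ", ")))
  }
  if (any(frames$distance_mm < 0)) {
    stop_fvri("distances must be non-negative.")
  }
  cbind(
    dominance = as.numeric(frames$dominance != "right"),
    vessel = unname(vessel_coding[frames$vessel]),
    log_distance = log(pmax(frames$distance_mm, log_clamp_mm)),
    bsa = frames$bsa_m2
  )
}

new_normal_model <- function(coefficients, ci_low, ci_high, adjusted_r2,
                             sigma = NA_real_, n_train = NA_integer_,
                             n_bootstrap = NA_integer_, seed = NA_integer_,
                             resample = NA_character_, redraws = 0L,
                             vessel_coding = default_vessel_coding,
                             log_clamp_mm = 1, bsa_formula = "mosteller",
                             name = "fitted") {
  stopifnot(identical(names(coefficients), model_terms))
  if (!all(is.na(ci_low))) {
    if (any(ci_low > coefficients + 1e-12 | ci_high < coefficients - 1e-12)) {
      stop_fvri("each coefficient must lie inside its confidence interval.")
    }
  }
  structure(
    list(
      coefficients = coefficients, ci_low = ci_low, ci_high = ci_high,
      adjusted_r2 = adjusted_r2, sigma = sigma, n_train = n_train,
      n_bootstrap = n_bootstrap, seed = seed, resample = resample,
      redraws = redraws, vessel_coding = vessel_coding,
      log_base = "natural", log_clamp_mm = log_clamp_mm,
      bsa_formula = bsa_formula, name = name
    ),
    class = "fvri_normal_model"
  )
}

#' Packaged default normal-vessel model
#'
#' The built-in prediction model for normal EEM area, with coefficients and
#' 95% confidence intervals as published from a 67-patient three-vessel IVUS
#' cohort (bootstrap multivariable linear model on 3,520 near-normal
#' cross-sections; adjusted R^2 0.46): intercept 12.20 mm^2, dominance
#' pattern -1.14, coronary vessel -1.73, log distance from ostium -1.28, body
#' surface area +2.60. The covariate encodings behind the published fit are
#' not recoverable from the publication; the conventions packaged here
#' (vessel coding LM 0 / LAD 1 / LCX 2 / RCA 3, right-dominant reference,
#' natural log clamped at 1 mm, Mosteller BSA) are this package's defaults,
#' so numeric agreement with the original per-frame predictions cannot be
#' asserted.
#'
#' @return A `fvri_normal_model` object usable directly with
#'   [score_frames()] and [predict()].
#' @examples
#' m <- packaged_normal_model()
#' tidy(m)
#' @export
packaged_normal_model <- function() {
  new_normal_model(
    coefficients = c(intercept = 12.20, dominance = -1.14, vessel = -1.73,
                     log_distance = -1.28, bsa = 2.60),
    ci_low = c(intercept = 11.07, dominance = -1.46, vessel = -1.80,
               log_distance = -1.39, bsa = 1.99),
    ci_high = c(intercept = 13.33, dominance = -0.82, vessel = -1.66,
                log_distance = -1.18, bsa = 3.20),
    adjusted_r2 = 0.46, n_train = 3520L, n_bootstrap = 5000L,
    name = "packaged-default"
  )
}

adjusted_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

ols_fit <- function(X, y) {
  # X includes the intercept column; returns coefficients + fit summaries
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    stop_fvri(sprintf("design is rank deficient; collinear column(s): %s.",
                      paste(dropped, collapse = ", ")),
              class = "fvri_rank_error")
  }
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  p <- ncol(X) - 1L
  list(
    coefficients = fit$coefficients,
    r2 = 1 - rss / tss,
    adjusted_r2 = adjusted_r2(1 - rss / tss, n, p),
    sigma = sqrt(rss / (n - p - 1L))
  )
}

#' Ordinary least-squares fit of the normal dimension model
#'
#' Point fit of lumen area on the four covariates over a set of near-normal
#' training frames.
#'
#' @param training Training frames, as from [select_training_frames()].
#' @param vessel_coding,log_clamp_mm Design conventions; see
#'   [normal_design_matrix()].
#' @param bsa_formula Recorded provenance of the BSA covariate.
#'
#' @return A `fvri_normal_model` (confidence intervals absent).
#' @export
fit_normal_model <- function(training,
                             vessel_coding = default_vessel_coding,
                             log_clamp_mm = 1,
                             bsa_formula = "mosteller") {
  X <- cbind(intercept = 1, normal_design_matrix(training, vessel_coding,
                                                 log_clamp_mm))
  if (nrow(X) < 6L) {
    stop_fvri("at least 6 training frames are required.")
  }
  y <- training$lumen_area_mm2
  fit <- ols_fit(X, y)
  coefs <- setNames(fit$coefficients, model_terms)
  new_normal_model(
    coefficients = coefs,
    ci_low = setNames(rep(NA_real_, 5L), model_terms),
    ci_high = setNames(rep(NA_real_, 5L), model_terms),
    adjusted_r2 = fit$adjusted_r2, sigma = fit$sigma,
    n_train = nrow(X), vessel_coding = vessel_coding,
    log_clamp_mm = log_clamp_mm, bsa_formula = bsa_formula
  )
}

#' Bootstrap fit of the normal dimension model
#'
#' Fits the normal-lumen prediction model on bootstrap replicates and takes
#' the final equation from the bootstrapped B-coefficients: coefficients are
#' the replicate means, confidence intervals the 2.5/97.5 percentiles.
#' Resampling is by patient by default, respecting within-patient clustering
#' of frames; frame-level resampling is available. The adjusted R^2 reported
#' is that of the point fit on the full training set. A replicate whose design
#' is rank deficient is redrawn (counted in `redraws`); more than 10% redraws
#' aborts.
#'
#' @param training Training frames, as from [select_training_frames()].
#' @param n_bootstrap Number of bootstrap replicates (default 5000).
#' @param seed Integer seed; the same seed reproduces the model exactly.
#' @param resample `"patient"` (default), `"frame"`, or `"none"` (every
#'   replicate is the full sample; useful for smoke tests).
#' @inheritParams fit_normal_model
#'
#' @return A `fvri_normal_model` with percentile confidence intervals.
#' @export
bootstrap_normal_model <- function(training, n_bootstrap = 5000, seed,
                                   resample = c("patient", "frame", "none"),
                                   vessel_coding = default_vessel_coding,
                                   log_clamp_mm = 1,
                                   bsa_formula = "mosteller") {
  resample <- match.arg(resample)
  if (missing(seed)) stop_fvri("a `seed` is required for the bootstrap.")
  check_number(n_bootstrap, "n_bootstrap", lower = 1)
  n_bootstrap <- as.integer(n_bootstrap)

  point <- fit_normal_model(training, vessel_coding, log_clamp_mm, bsa_formula)
  X <- cbind(intercept = 1, normal_design_matrix(training, vessel_coding,
                                                 log_clamp_mm))
  y <- training$lumen_area_mm2
  n <- nrow(X)
  p <- ncol(X)

  unit_rows <- switch(resample,
    patient = {
      check_columns(training, "patient_id", "`training`")
      split(seq_len(n), training$patient_id)
    },
    frame = ,
    none = NULL
  )
  n_units <- if (resample == "patient") length(unit_rows) else n

  draw_rows <- function() {
    switch(resample,
      patient = unlist(unit_rows[sample.int(n_units, n_units, replace = TRUE)],
                       use.names = FALSE),
      frame = sample.int(n, n, replace = TRUE),
      none = seq_len(n)
    )
  }

  boot <- matrix(NA_real_, n_bootstrap, p)
  redraws <- 0L
  max_redraws <- ceiling(0.10 * n_bootstrap)
  withr::with_seed(seed, {
    b <- 1L
    while (b <= n_bootstrap) {
      rows <- draw_rows()
      fit <- stats::.lm.fit(X[rows, , drop = FALSE], y[rows])
      if (fit$rank < p) {
        redraws <- redraws + 1L
        if (redraws > max_redraws) {
          stop_fvri(sprintf(
            "more than 10%% of bootstrap replicates (%d of %d) were rank deficient.",
            redraws, n_bootstrap
          ), class = "fvri_rank_error")
        }
        next
      }
      boot[b, ] <- fit$coefficients
      b <- b + 1L
    }
  })

  coefs <- setNames(colMeans(boot), model_terms)
  ci <- apply(boot, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  new_normal_model(
    coefficients = coefs,
    ci_low = setNames(pmin(ci[1L, ], coefs), model_terms),
    ci_high = setNames(pmax(ci[2L, ], coefs), model_terms),
    adjusted_r2 = point$adjusted_r2, sigma = point$sigma, n_train = n,
    n_bootstrap = n_bootstrap, seed = as.integer(seed), resample = resample,
    redraws = redraws, vessel_coding = vessel_coding,
    log_clamp_mm = log_clamp_mm, bsa_formula = bsa_formula
  )
}

#' Predict normal EEM area for frames
#'
#' Evaluates the linear prediction equation for each frame. Predictions
#' outside the clinically relevant calibre window 3.1--19.6 mm^2 are flagged
#' with a warning but never clamped.
#'
#' @param object A `fvri_normal_model`.
#' @param frames Frame tibble with `dominance`, `vessel`, `distance_mm`,
#'   `bsa_m2`.
#' @param ... Unused.
#'
#' @return Numeric vector of predicted normal EEM areas, mm^2.
#' @export
predict.fvri_normal_model <- function(object, frames, ...) {
  X <- cbind(intercept = 1,
             normal_design_matrix(frames, object$vessel_coding,
                                  object$log_clamp_mm))
  pred <- drop(X %*% object$coefficients)
  out_of_range <- sum(pred < default_lumen_range[1] |
                        pred > default_lumen_range[2])
  if (out_of_range > 0L) {
    rlang::warn(sprintf(
      "%d predicted normal EEM area(s) fall outside the %g-%g mm^2 calibre window (not clamped).",
      out_of_range, default_lumen_range[1], default_lumen_range[2]
    ))
  }
  unname(pred)
}

#' Attach predicted normal EEM areas to a frame table
#'
#' @param frames Frame tibble.
#' @param model A `fvri_normal_model` (default: the packaged model).
#'
#' @return The input tibble with an `eem_pred_mm2` column.
#' @export
add_predicted_eem <- function(frames, model = packaged_normal_model()) {
  frames$eem_pred_mm2 <- predict(model, frames)
  tibble::as_tibble(frames)
}

#' @export
print.fvri_normal_model <- function(x, ...) {
  cat(sprintf("<fvri_normal_model: %s>\n", x$name))
  cat(sprintf("  EEM_predicted (mm^2) = %s\n", paste(
    sprintf("%+.3f*%s", x$coefficients, c("1", model_terms[-1])),
    collapse = " "
  )))
  cat(sprintf("  adjusted R^2 = %.3f; n_train = %s; bootstrap = %s\n",
              x$adjusted_r2, x$n_train, x$n_bootstrap))
  invisible(x)
}

#' @describeIn packaged_normal_model Tidy coefficient table for a normal
#'   vessel model (term, estimate, 95% interval bounds).
#' @param x A `fvri_normal_model`.
#' @param ... Unused.
#' @export
tidy.fvri_normal_model <- function(x, ...) {
  tibble::tibble(
    term = model_terms,
    estimate = unname(x$coefficients),
    conf.low = unname(x$ci_low),
    conf.high = unname(x$ci_high)
  )
}

#' @export
glance.fvri_normal_model <- function(x, ...) {
  tibble::tibble(
    adj.r.squared = x$adjusted_r2, sigma = x$sigma,
    nobs = x$n_train, n_bootstrap = x$n_bootstrap,
    redraws = x$redraws, seed = x$seed, name = x$name
  )
}

#' Serialise / restore a normal vessel model
#'
#' The JSON records coefficients, intervals, fit summaries and every
#' convention needed to reproduce predictions (vessel coding, log clamp, BSA
#' formula, bootstrap settings).
#'
#' @param model A `fvri_normal_model`.
#' @param path File path for the model JSON.
#'
#' @return `write_normal_model` returns `path` invisibly;
#'   `read_normal_model` returns the restored `fvri_normal_model`.
#' @export
write_normal_model <- function(model, path) {
  x <- unclass(model)
  # named vectors must serialise as JSON objects, not bare arrays
  for (f in c("coefficients", "ci_low", "ci_high", "vessel_coding")) {
    x[[f]] <- as.list(x[[f]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_normal_model
#' @export
read_normal_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_num <- function(v) setNames(vapply(v, as.numeric, numeric(1))[model_terms],
                                 model_terms)
  new_normal_model(
    coefficients = as_num(x$coefficients),
    ci_low = as_num(x$ci_low), ci_high = as_num(x$ci_high),
    adjusted_r2 = as.numeric(x$adjusted_r2),
    sigma = as.numeric(x$sigma %||% NA_real_),
    n_train = as.integer(x$n_train %||% NA_integer_),
    n_bootstrap = as.integer(x$n_bootstrap %||% NA_integer_),
    seed = as.integer(x$seed %||% NA_integer_),
    resample = as.character(x$resample %||% NA_character_),
    redraws = as.integer(x$redraws %||% 0L),
    vessel_coding = setNames(as.numeric(x$vessel_coding),
                             names(x$vessel_coding)),
    log_clamp_mm = as.numeric(x$log_clamp_mm),
    bsa_formula = as.character(x$bsa_formula),
    name = as.character(x$name)
  )
}
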