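test_that("the index equals 1 exactly under complete compensation", {
  expect_equal(compute_fvri(18, 12, 6), 1.0)
  expect_equal(compute_fvri(18, 12, 6, "lumen_ratio"), 1.0)
  expect_equal(compute_fvri(11, 12, 6), 11 / 18)
  expect_equal(compute_fvri(22, 12, 6), 22 / 18)
  expect_true(is.na(compute_fvri(10, 10, 0))) # trivial plaque: no index
  expect_error(compute_fvri(10, -1, 2), "positive",
               class = "fvri_validation_error")
})

test_that("the two formula variants agree at 1 and on the sign of FVRI - 1", {
  withr::with_seed(7, {
    pred <- runif(2000, 4, 18)
    plaque <- runif(2000, 0.5, 10)
    actual <- runif(2000, 3, 30)
  })
  f1 <- compute_fvri(actual, pred, plaque, "compensation_ratio")
  f2 <- compute_fvri(actual, pred, plaque, "lumen_ratio")
  expect_equal(sign(f1 - 1), sign(f2 - 1))
  at_one <- abs(actual - (pred + plaque)) < 1e-12
  expect_equal(f1[at_one], f2[at_one])
})

test_that("compensation-ratio FVRI is monotone in each argument", {
  withr::with_seed(8, {
    pred <- runif(300, 4, 18)
    plaque <- runif(300, 0.5, 10)
    actual <- runif(300, 3, 30)
  })
  h <- 1e-4
  base <- compute_fvri(actual, pred, plaque)
  expect_true(all(compute_fvri(actual + h, pred, plaque) > base))
  expect_true(all(compute_fvri(actual, pred + h, plaque) < base))
  expect_true(all(compute_fvri(actual, pred, plaque + h) < base))
})

test_that("the complete-compensatory band derives from the index sd", {
  expect_equal(derive_band_from_sd(0.17),
               c(band_low = 0.83, band_high = 1.17))
  expect_equal(derive_band_from_sd(0.5), c(band_low = 0.5, band_high = 1.5))
  expect_error(derive_band_from_sd(0), "range")   # degenerate band
  expect_error(derive_band_from_sd(1), "range")
  expect_error(fvri_config(band_low = 0), "range")
})

test_that("classification follows the band, the burden cutoff and the shrinkage branch", {
  cls <- function(actual, pred, plaque, burden) {
    classify_remodeling(compute_fvri(actual, pred, plaque), burden, actual,
                        pred)
  }
  expect_equal(as.character(cls(18, 12, 6, 40)), "complete_compensatory")
  expect_equal(as.character(cls(11, 12, 6, 40)), "negative")
  expect_equal(as.character(cls(13.5, 12, 6, 40)), "incomplete_compensatory")
  expect_equal(as.character(cls(25, 12, 6, 40)), "ectatic")
  expect_equal(as.character(cls(18, 12, 6, 19.99)), "trivial_plaque")

  # boundaries: band endpoints inclusive, burden cutoff exclusive below
  expect_equal(as.character(cls(0.83 * 18, 12, 6, 40)),
               "complete_compensatory")
  expect_equal(as.character(cls(1.17 * 18, 12, 6, 40)),
               "complete_compensatory")
  expect_equal(as.character(cls(18, 12, 6, 20)), "complete_compensatory")
})

test_that("every valid frame receives exactly one class", {
  withr::with_seed(9, {
    n <- 5000
    pred <- runif(n, 4, 18)
    burden <- runif(n, 0, 95)
    actual <- runif(n, 3, 30)
  })
  plaque <- actual * burden / 100
  fvri <- compute_fvri(actual, pred, plaque)
  fvri[plaque == 0] <- NA
  cls <- classify_remodeling(fvri, burden, actual, pred)
  expect_false(any(is.na(cls)))
  expect_setequal(
    as.character(unique(cls)),
    c("negative", "incomplete_compensatory", "complete_compensatory",
      "ectatic", "trivial_plaque")
  )
})

test_that("shrinkage nests inside the sub-band region except on a measure-zero sliver", {
  # For burden >= 20 and eem_actual < eem_predicted the index is bounded by
  # 1/(1 + burden/100); this is below 0.83 whenever burden exceeds ~20.5%,
  # and in the residual [20, 20.5) window a violation additionally needs
  # eem_actual within 0.4% of eem_predicted.
  withr::with_seed(10, {
    n <- 1e5
    actual <- runif(n, 3, 30)
    burden <- runif(n, 20, 95)
    pred <- actual * runif(n, 1.0000001, 2.5)
  })
  plaque <- actual * burden / 100
  fvri <- compute_fvri(actual, pred, plaque)
  viol <- which(fvri >= 0.83)
  expect_true(all(burden[viol] < 20.5))
  expect_true(all(actual[viol] / pred[viol] > 0.996))
  strict <- burden >= 20.5
  expect_true(all(fvri[strict] < 0.83))
})

test_that("scoring attaches prediction, index and class to every frame", {
  sc <- small_scored_cohort(seed = 3, n_patients = 3,
                            include_composition = FALSE)
  scored <- sc$scored
  expect_true(all(c("eem_pred_mm2", "fvri", "remodeling_class",
                    "formula_variant") %in% names(scored)))
  est <- scored$plaque_burden_pct >= 20
  expect_false(any(is.na(scored$fvri[est])))
  expect_true(all(scored$remodeling_class[!est] == "trivial_plaque"))

  # an existing prediction column is honoured when no model is given
  pre <- scored
  pre$eem_pred_mm2 <- 10
  re <- score_frames(pre, model = NULL)
  expect_equal(re$fvri[est],
               scored$eem_area_mm2[est] /
                 (10 + scored$plaque_media_area_mm2[est]))
})
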