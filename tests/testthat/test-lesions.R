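test_that("lesions are maximal runs of at least three high-burden frames", {
  fr <- add_geometry(toy_artery(c(30, 45, 50, 41, 35, 42, 43, 60, 20)))
  les <- detect_lesions(fr)
  expect_equal(nrow(les), 2)
  expect_equal(les$start_pos, c(2, 6))
  expect_equal(les$end_pos, c(4, 8))
  expect_equal(les$n_frames, c(3, 3))
  expect_equal(les$length_mm, c(1, 1)) # 0.5 mm spacing, 3-frame span

  expect_equal(nrow(detect_lesions(add_geometry(toy_artery(c(45, 50))))), 0)

  all41 <- detect_lesions(add_geometry(toy_artery(rep(41, 10))))
  expect_equal(nrow(all41), 1)
  expect_equal(c(all41$start_pos, all41$end_pos), c(1, 10))

  # threshold is exclusive: exactly 40 does not belong to a lesion
  at40 <- detect_lesions(add_geometry(toy_artery(c(41, 40, 41, 41, 41))))
  expect_equal(at40$start_pos, 3)
})

test_that("detected runs match exhaustive enumeration on random sequences", {
  withr::with_seed(11, {
    for (i in 1:200) {
      n <- sample(3:40, 1)
      burdens <- runif(n, 20, 70)
      fr <- add_geometry(toy_artery(burdens))
      les <- detect_lesions(fr)
      oracle <- oracle_runs(burdens > 40, min_run = 3)
      expect_equal(nrow(les), nrow(oracle))
      if (nrow(oracle) > 0) {
        expect_equal(les$start_pos, oracle[, 1])
        expect_equal(les$end_pos, oracle[, 2])
        # maximality: neighbours of every span are at or below threshold
        for (k in seq_len(nrow(les))) {
          if (les$start_pos[k] > 1) {
            expect_lte(burdens[les$start_pos[k] - 1], 40)
          }
          if (les$end_pos[k] < n) expect_lte(burdens[les$end_pos[k] + 1], 40)
        }
      }
    }
  })
})

test_that("the representative frame is the minimal lumen area, ties proximal", {
  expect_equal(select_mla(c(5.0, 4.2, 4.8)), 2)
  expect_equal(select_mla(c(4.2, 4.2, 5.0)), 1)
  withr::with_seed(12, {
    for (i in 1:100) {
      lumens <- runif(sample(3:30, 1), 2, 9)
      expect_equal(lumens[select_mla(lumens)], min(lumens))
    }
  })
  expect_error(select_mla(numeric()), "empty")
})

test_that("references are the immediate out-of-span neighbours or missing", {
  expect_equal(find_references(2, 4, 9),
               c(proximal = 1L, distal = 5L))
  expect_equal(find_references(1, 3, 9)[["proximal"]], NA_integer_)
  expect_equal(find_references(7, 9, 9)[["distal"]], NA_integer_)
})

test_that("the classical index averages the references and classifies by 0.88/1.00", {
  expect_equal(classical_index(13, 14, 14), 13 / 14)
  expect_equal(classical_index(14, 14, 14), 1.0)
  expect_equal(classical_index(14, 12, 16), 1.0)
  expect_equal(classical_index(14, 16, 12), classical_index(14, 12, 16))
  expect_error(classical_index(0, 14, 14), "positive",
               class = "fvri_validation_error")

  expect_equal(as.character(classify_classical(c(0.87, 0.88, 1.00, 1.0001))),
               c("negative", "intermediate", "intermediate", "positive"))
  expect_error(classify_classical(-0.1), "positive")
})

test_that("lesion assessment joins MLA scoring with reference comparison", {
  # a flat artery whose EEM never changes: classical index is exactly 1
  burdens <- c(10, 10, 45, 50, 55, 50, 45, 10, 10)
  eem <- rep(12, 9)
  fr <- tibble::tibble(
    patient_id = "P1", artery_id = "P1_LAD", vessel = "LAD",
    frame_index = 1:9, distance_mm = (1:9) * 0.5,
    eem_area_mm2 = eem, lumen_area_mm2 = eem * (1 - burdens / 100),
    dominance = "right", bsa_m2 = 1.8
  )
  scored <- score_frames(add_geometry(fr), packaged_normal_model())
  les <- assess_lesions(scored)
  expect_equal(nrow(les), 1)
  expect_equal(les$mla_frame, 5) # highest burden = smallest lumen here
  expect_equal(les$classical_index, 1.0)
  expect_equal(as.character(les$classical_class), "intermediate")
  expect_true(les$has_references)

  # a lesion running to the pullback end has no distal reference
  fr2 <- fr
  fr2$lumen_area_mm2 <- fr2$eem_area_mm2 *
    (1 - c(10, 10, 10, 10, 10, 10, 45, 50, 55) / 100)
  scored2 <- score_frames(add_geometry(fr2), packaged_normal_model())
  expect_message(les2 <- assess_lesions(scored2), "boundary")
  expect_false(les2$has_references)
  expect_true(is.na(les2$classical_index))
})

test_that("a vessel with no EEM response scores far below the band", {
  # theta = 0: EEM stays at its normal size while plaque grows to 55% burden
  n_area <- 10
  plaque <- 0.55 * n_area
  fr <- tibble::tibble(
    patient_id = "P1", artery_id = "P1_LAD", vessel = "LAD",
    frame_index = 1:5, distance_mm = (1:5) * 0.5,
    eem_area_mm2 = n_area,
    lumen_area_mm2 = n_area - c(0, plaque, plaque, plaque, 0),
    dominance = "right", bsa_m2 = 1.8
  )
  fr <- add_geometry(fr)
  fr$eem_pred_mm2 <- n_area
  scored <- score_frames(fr, model = NULL)
  les <- assess_lesions(scored)
  expect_equal(nrow(les), 1)
  expect_lt(les$fvri, 0.83)
  expect_equal(as.character(les$fvri_class), "incomplete_compensatory")
})

test_that("simulated lesion spans never overlap and classical swaps are stable", {
  sc <- small_scored_cohort(seed = 6, n_patients = 4,
                            include_composition = FALSE)
  les <- suppressMessages(assess_lesions(sc$scored))
  by_artery <- split(les, les$artery_id)
  for (a in by_artery) {
    if (nrow(a) > 1) {
      a <- a[order(a$start_pos), ]
      expect_true(all(a$start_pos[-1] > a$end_pos[-nrow(a)]))
    }
  }
  ok <- les$has_references
  expect_equal(
    classical_index(les$mla_eem_mm2[ok], les$eem_dist_mm2[ok],
                    les$eem_prox_mm2[ok]),
    les$classical_index[ok]
  )
})
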