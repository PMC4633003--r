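test_that("the same seed reproduces a cohort exactly", {
  cfg <- simulation_config(n_patients = 3)
  a <- simulate_cohort(cfg, seed = 77)
  b <- simulate_cohort(cfg, seed = 77)
  expect_identical(a$frames, b$frames)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(a$frames, c$frames))
  expect_error(simulate_cohort(cfg), "seed")
})

test_that("written cohorts are byte-identical across runs of the same seed", {
  cfg <- simulation_config(n_patients = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg, seed = 5), d1)
  write_cohort(simulate_cohort(cfg, seed = 5), d2)
  for (f in c("patients.csv", "frames.csv", "ground_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a zero lesion rate produces disease-free pullbacks", {
  cfg <- simulation_config(n_patients = 2, lesion_rate = 0)
  co <- simulate_cohort(cfg, seed = 9)
  expect_true(all(co$frames$plaque_burden_pct == 0 |
                    abs(co$frames$plaque_burden_pct) < 1e-12))
  expect_equal(nrow(detect_lesions(co$frames)), 0)
  expect_equal(nrow(co$lesion_truth), 0)
})

test_that("complete compensation with zero noise yields an index of exactly 1", {
  cfg <- simulation_config(
    n_patients = 3, lumen_noise_sd = 0, measurement_noise_sd = 0,
    theta_weights = c(negative = 0, incomplete = 0, complete = 1,
                      ectatic = 0),
    theta_ranges = list(negative = c(-1, -1), incomplete = c(0.5, 0.5),
                        complete = c(1, 1), ectatic = c(1.5, 1.5)),
    include_composition = FALSE
  )
  co <- simulate_cohort(cfg, seed = 10)
  scored <- score_frames(co$frames, packaged_normal_model())
  with_plaque <- scored$plaque_media_area_mm2 > 0
  expect_true(any(with_plaque))
  expect_equal(scored$fvri[with_plaque], rep(1, sum(with_plaque)),
               tolerance = 1e-9)
})

test_that("ground truth satisfies its defining identity", {
  co <- simulate_cohort(simulation_config(n_patients = 3), seed = 11)
  gt <- co$ground_truth
  est <- gt$plaque_mm2 > 0
  expect_equal(
    gt$true_fvri[est],
    (gt$normal_eem_mm2[est] + gt$theta_eff[est] * gt$plaque_mm2[est]) /
      (gt$normal_eem_mm2[est] + gt$plaque_mm2[est])
  )
  expect_true(all(is.na(gt$true_fvri[!est])))
  # observed frames follow the generative chain: lumen = EEM - plaque
  expect_equal(co$frames$eem_area_mm2 - co$frames$lumen_area_mm2,
               gt$plaque_mm2)
})

test_that("the intended remodeling taxonomy emerges from theta", {
  # fixed theta per run; higher theta must give higher mean lesion FVRI
  mean_fvri <- vapply(c(0.3, 0.7, 1.0, 1.3), function(th) {
    cfg <- simulation_config(
      n_patients = 3,
      theta_weights = c(negative = 0, incomplete = 1, complete = 0,
                        ectatic = 0),
      theta_ranges = list(negative = c(-1, -1), incomplete = c(th, th),
                          complete = c(1, 1), ectatic = c(1.5, 1.5)),
      include_composition = FALSE
    )
    co <- simulate_cohort(cfg, seed = 123)
    mean(co$lesion_truth$true_fvri)
  }, numeric(1))
  expect_true(all(diff(mean_fvri) > 0))

  # the mixture's intended class labels match the FVRI-derived truth at the
  # lesion core for the default margins
  co <- simulate_cohort(simulation_config(n_patients = 10,
                                          include_composition = FALSE),
                        seed = 19)
  lt <- co$lesion_truth
  map <- c(negative = "negative", incomplete = "incomplete_compensatory",
           complete = "complete_compensatory", ectatic = "ectatic")
  core <- lt$peak_burden_pct > 40 # bumps that grew into established lesions
  expect_gt(mean(map[lt$theta_class[core]] ==
                   as.character(lt$true_class[core])), 0.95)
})

test_that("cohort-scale defaults reproduce the intended study conditions", {
  co <- simulate_cohort(simulation_config(include_composition = FALSE),
                        seed = 20)
  low <- 100 * mean(co$frames$plaque_burden_pct < 20)
  expect_true(abs(low - 11.3) <= 5)
  expect_equal(nrow(co$patients), 67)
  expect_equal(length(unique(co$frames$artery_id)), 67 * 4)
  # pullback geometry: spacing and length windows
  spac <- diff(co$frames$distance_mm[co$frames$artery_id ==
                                       co$frames$artery_id[1]])
  expect_equal(spac, rep(0.3, length(spac)))
})

test_that("noise calibration hits its target and rejects degenerate ones", {
  cfg <- simulation_config(n_patients = 10, include_composition = FALSE)
  sd0 <- calibrate_noise(cfg, target_adjusted_r2 = 1, seed = 1)
  expect_equal(as.numeric(sd0), 0)
  expect_error(calibrate_noise(cfg, target_adjusted_r2 = 0, seed = 1),
               "range")
  sd <- calibrate_noise(cfg, target_adjusted_r2 = 0.46, seed = 2, tol = 0.03)
  expect_true(as.numeric(sd) > 0)
  # self-consistency on an independent simulation
  cfg2 <- simulation_config(n_patients = 25, lumen_noise_sd = as.numeric(sd),
                            include_composition = FALSE)
  co <- simulate_cohort(cfg2, seed = 3)
  m <- fit_normal_model(select_training_frames(co$frames))
  expect_true(m$adjusted_r2 > 0.38 && m$adjusted_r2 < 0.54)
})
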