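test_that("training frames are exactly the near-normal calibre window", {
  fr <- toy_artery(c(10, 19.9, 20, 35), lumens = c(8, 8, 8, 8))
  fr <- add_geometry(fr)
  sel <- select_training_frames(fr)
  expect_equal(sel$frame_index, 1:2) # burden strictly below 20

  fr2 <- add_geometry(toy_artery(c(5, 5, 5), lumens = c(2.9, 3.1, 19.6)))
  sel2 <- select_training_frames(fr2)
  expect_equal(sel2$lumen_area_mm2, c(3.1, 19.6)) # inclusive bounds

  fr3 <- add_geometry(toy_artery(c(50, 60), lumens = c(8, 8)))
  expect_error(select_training_frames(fr3), "larger",
               class = "fvri_empty_selection")
})

test_that("the design row encodes dominance, vessel, log distance and BSA", {
  fr <- tibble::tibble(
    dominance = c("right", "left", "balanced", "right"),
    vessel = c("LM", "LAD", "LCX", "RCA"),
    distance_mm = c(0, 1, exp(2), 50),
    bsa_m2 = c(2.0, 1.8, 1.6, 1.9)
  )
  X <- normal_design_matrix(fr)
  expect_equal(X[1, ], c(dominance = 0, vessel = 0, log_distance = 0,
                         bsa = 2.0)) # ostium clamped to ln 1 = 0
  expect_equal(unname(X[2, "log_distance"]), 0)
  expect_equal(X[3, ], c(dominance = 1, vessel = 2, log_distance = 2,
                         bsa = 1.6))
  expect_equal(unname(X[4, "vessel"]), 3)
  expect_error(normal_design_matrix(dplyr::mutate(fr, vessel = "OM1")),
               "coding map")
})

test_that("the point fit equals an independent normal-equations solution", {
  withr::with_seed(3, {
    fr <- tibble::tibble(
      patient_id = rep(c("A", "B"), length.out = 40),
      dominance = sample(c("right", "left"), 40, TRUE),
      vessel = sample(c("LM", "LAD", "LCX", "RCA"), 40, TRUE),
      distance_mm = runif(40, 0.5, 70),
      bsa_m2 = runif(40, 1.5, 2.2),
      lumen_area_mm2 = runif(40, 4, 18)
    )
  })
  m <- fit_normal_model(fr)
  X <- cbind(1, normal_design_matrix(fr))
  expect_equal(unname(m$coefficients), oracle_ols(X, fr$lumen_area_mm2),
               tolerance = 1e-10)

  # permutation invariance
  perm <- fr[sample(nrow(fr)), ]
  expect_equal(fit_normal_model(perm)$coefficients, m$coefficients,
               tolerance = 1e-12)

  # exactly linear responses give a perfect fit
  beta <- c(10, -1, -1.5, -1.2, 2.5)
  fr$lumen_area_mm2 <- drop(X %*% beta)
  m2 <- fit_normal_model(fr)
  expect_equal(unname(m2$coefficients), beta, tolerance = 1e-9)
  expect_equal(m2$adjusted_r2, 1, tolerance = 1e-9)

  # rank deficiency is reported with the collinear column
  fr$bsa_m2 <- 1.8
  fr$dominance <- "right"
  expect_error(fit_normal_model(fr), "bsa", class = "fvri_rank_error")
})

test_that("zero-noise simulation recovers the generating coefficients", {
  cfg <- simulation_config(n_patients = 4, lumen_noise_sd = 0,
                           measurement_noise_sd = 0,
                           include_composition = FALSE)
  co <- simulate_cohort(cfg, seed = 8)
  m <- fit_normal_model(select_training_frames(co$frames))
  expect_equal(m$coefficients, cfg$coefficients, tolerance = 1e-8)
})

test_that("bootstrap behaves as a resampled OLS", {
  # a balanced dominance mix keeps patient-resampled designs full rank
  sc <- small_scored_cohort(seed = 2, n_patients = 16,
                            include_composition = FALSE,
                            dominance_prev = 0.4)
  tr <- select_training_frames(sc$cohort$frames)
  point <- fit_normal_model(tr)

  # degenerate bootstrap: one full-sample replicate equals the point fit
  degen <- bootstrap_normal_model(tr, n_bootstrap = 1, seed = 1,
                                  resample = "none")
  expect_equal(degen$coefficients, point$coefficients, tolerance = 1e-12)

  b1 <- bootstrap_normal_model(tr, n_bootstrap = 50, seed = 10)
  b2 <- bootstrap_normal_model(tr, n_bootstrap = 50, seed = 10)
  expect_identical(b1$coefficients, b2$coefficients) # same seed, same model
  expect_identical(b1$ci_low, b2$ci_low)
  b3 <- bootstrap_normal_model(tr, n_bootstrap = 50, seed = 11)
  expect_false(identical(b1$coefficients, b3$coefficients))

  # replicate means approach the point estimates; intervals bracket them
  big <- bootstrap_normal_model(tr, n_bootstrap = 400, seed = 4)
  expect_true(all(big$ci_low <= big$coefficients &
                    big$coefficients <= big$ci_high))
  se <- (big$ci_high - big$ci_low) / (2 * 1.96)
  expect_true(all(abs(big$coefficients - point$coefficients) < 2 * se))

  # frame-level resampling is available
  bf <- bootstrap_normal_model(tr, n_bootstrap = 20, seed = 1,
                               resample = "frame")
  expect_s3_class(bf, "fvri_normal_model")
  expect_error(bootstrap_normal_model(tr, n_bootstrap = 10), "seed")
})

test_that("prediction is the documented linear combination and is affine", {
  m <- packaged_normal_model()
  ref <- tibble::tibble(dominance = "right", vessel = "LM",
                        distance_mm = 1, bsa_m2 = 0)
  expect_equal(predict(m, ref), 12.20) # constant at reference covariates
  expect_equal(predict(m, dplyr::mutate(ref, bsa_m2 = 2.0)),
               12.20 + 2 * 2.60)

  # affine in the covariates: f(a) + f(b) - f(0) = f(a + b)
  a <- tibble::tibble(dominance = "left", vessel = "LAD",
                      distance_mm = exp(1), bsa_m2 = 0.7)
  b <- tibble::tibble(dominance = "right", vessel = "LCX",
                      distance_mm = exp(2), bsa_m2 = 0.9)
  ab <- tibble::tibble(dominance = "left", vessel = "RCA",
                       distance_mm = exp(3), bsa_m2 = 1.6)
  expect_equal(predict(m, a) + predict(m, b) - predict(m, ref),
               predict(m, ab))

  flat <- m
  flat$coefficients[] <- c(10, 0, 0, 0, 0)
  any_frame <- tibble::tibble(dominance = "balanced", vessel = "RCA",
                              distance_mm = 33, bsa_m2 = 1.9)
  expect_equal(predict(flat, any_frame), 10)

  # out-of-window predictions are flagged, never clamped
  tiny <- dplyr::mutate(ref, vessel = "RCA", distance_mm = 80, bsa_m2 = 0.1)
  expect_warning(p <- predict(m, tiny), "calibre window")
  expect_lt(p, 3.1)
})

test_that("a refitted model on calibrated-noise output lands near the packaged fit quality", {
  co <- simulate_cohort(simulation_config(n_patients = 40,
                                          include_composition = FALSE),
                        seed = 31)
  tr <- select_training_frames(co$frames)
  expect_gt(nrow(tr), 3000)
  m <- fit_normal_model(tr)
  expect_true(abs(m$adjusted_r2 - 0.46) <= 0.08)
})

test_that("model JSON round-trips every convention", {
  m <- packaged_normal_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_normal_model(m, path)
  m2 <- read_normal_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$ci_low, m$ci_low)
  expect_equal(m2$vessel_coding, m$vessel_coding)
  expect_equal(m2$adjusted_r2, m$adjusted_r2)
  expect_equal(m2$log_clamp_mm, m$log_clamp_mm)
  expect_identical(m2$name, m$name)
})
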