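# Shared fixtures and independent oracles, built in code.

# minimal single-artery frame table from burden (%) and lumen (mm^2) vectors;
# eem is derived so that the requested burden holds exactly
toy_artery <- function(burdens, lumens = rep(8, length(burdens)),
                       patient_id = "P1", artery_id = "P1_LAD",
                       vessel = "LAD", spacing = 0.5,
                       dominance = "right", bsa = 1.8) {
  stopifnot(length(burdens) == length(lumens), all(burdens < 100))
  n <- length(burdens)
  tibble::tibble(
    patient_id = patient_id, artery_id = artery_id, vessel = vessel,
    frame_index = seq_len(n), distance_mm = spacing * seq_len(n),
    lumen_area_mm2 = lumens,
    eem_area_mm2 = lumens / (1 - burdens / 100),
    dominance = dominance, weight_kg = 72, height_cm = 161.6, bsa_m2 = bsa
  )
}

# published 4x3 lesion cross-classification used as a worked example
# (FVRI rows: negative, incomplete, complete, ectatic;
#  classical columns: negative, intermediate, positive; n = 618)
example_lesion_counts <- function() {
  matrix(c(51, 49, 38,
           57, 79, 119,
           28, 84, 105,
           0, 2, 6),
         nrow = 4, byrow = TRUE,
         dimnames = list(
           c("negative", "incomplete_compensatory",
             "complete_compensatory", "ectatic"),
           c("negative", "intermediate", "positive")
         ))
}

# independent OLS oracle: explicit normal equations
oracle_ols <- function(X, y) {
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# independent run finder: exhaustive scan over all [i, j] windows
oracle_runs <- function(above, min_run) {
  n <- length(above)
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(above[i:j]) &&
          (i == 1 || !above[i - 1]) &&
          (j == n || !above[j + 1]) &&
          (j - i + 1) >= min_run) {
        runs[[length(runs) + 1]] <- c(i, j)
      }
    }
  }
  if (length(runs) == 0L) matrix(integer(), ncol = 2) else
    do.call(rbind, runs)
}

# a small scored cohort reused across pipeline tests
small_scored_cohort <- function(seed = 42, n_patients = 5, ...) {
  co <- simulate_cohort(simulation_config(n_patients = n_patients, ...),
                        seed = seed)
  list(cohort = co,
       scored = score_frames(co$frames, packaged_normal_model()))
}
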