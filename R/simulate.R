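# Synthetic IVUS pullback cohorts with known ground truth.
#
# Generative chain, per frame at distance d from the ostium:
#   normal lumen  N   = X beta + e,  e ~ N(0, lumen_noise_sd)
#   plaque        P   = b N / (1 - b theta)  where b is the target plaque
#                       burden fraction of a raised-cosine-tapered plateau
#                       ("Tukey window") bump and theta is the lesion's
#                       remodeling response
#   true EEM          = N + theta P         (true FVRI = (N+theta P)/(N+P))
#   observed EEM      = true EEM + m,  m ~ N(0, measurement_noise_sd)
#   observed lumen    = observed EEM - P
# With burden fraction b = P/(N + theta P) this reproduces the target burden
# profile exactly in the noise-free limit. theta = 1 is complete compensatory
# enlargement; theta > 1 ectasia; 0 < theta < 1 insufficient enlargement;
# theta < 0 shrinkage.

#' Simulation configuration
#'
#' Defaults emulate the published study conditions: 67 patients, weight
#' 72.0 +/- 11.6 kg, height 161.6 +/- 7.9 cm, four imaged arteries per
#' patient with 40--80 mm pullbacks (the left main shorter, 5--15 mm),
#' 0.3 mm frame spacing, normal-lumen profiles generated from the packaged
#' prediction coefficients with noise calibrated so the refitted model's
#' adjusted R^2 is about 0.46, and plaque bumps dense enough that about 11%
#' of frames remain at trivial (<20%) burden. The remodeling response
#' `theta` is drawn from a four-component mixture spanning the remodeling
#' taxonomy with weights echoing the published lesion-class mix.
#'
#' @param n_patients Number of patients.
#' @param artery_length_range,lm_length_range Pullback length ranges, mm, for
#'   LAD/LCX/RCA and for the left main.
#' @param frame_spacing Frame spacing, mm.
#' @param coefficients Named generating coefficients
#'   (intercept, dominance, vessel, log_distance, bsa).
#' @param vessel_coding Vessel code map; see [normal_design_matrix()].
#' @param weight_mean,weight_sd,height_mean,height_sd Anthropometrics, kg/cm.
#' @param dominance_prev Prevalence of left/balanced dominance.
#' @param bsa_formula BSA formula name.
#' @param lumen_noise_sd Normal-lumen noise sd, mm^2 (calibrated default;
#'   see [calibrate_noise()]).
#' @param lumen_noise_corr_mm Correlation length, mm, of the normal-lumen
#'   deviations along an artery (vessel calibre varies smoothly, not frame
#'   by frame); 0 gives white noise.
#' @param measurement_noise_sd EEM measurement noise sd, mm^2, for a vessel
#'   of the cohort-mean EEM area (14.2 mm^2); the default follows the
#'   reported interobserver reproducibility of EEM tracings. Per frame the
#'   sd scales with the square root of the true EEM area, i.e. with the
#'   contour perimeter, as expected for radial tracing jitter.
#' @param measurement_noise_corr_mm Correlation length, mm, of the tracing
#'   noise along the pullback (semi-automatic contours propagate between
#'   neighbouring frames, so their errors are smooth, not independent);
#'   0 gives white noise.
#' @param lesion_rate Mean number of plaque bumps attempted per artery
#'   (Poisson).
#' @param lesion_width_range Bump width range, mm.
#' @param peak_burden_range Peak plaque-burden range, percent.
#' @param ectatic_peak_cap Peak-burden cap, percent, for bumps drawn in the
#'   ectatic theta range (burden above `1/theta` is geometrically
#'   unattainable when the vessel outgrows its plaque).
#' @param taper_frac Fraction of each bump occupied by its two raised-cosine
#'   shoulders; `1` recovers a pure raised-cosine bump, smaller values give a
#'   flat plateau with steeper shoulders.
#' @param lesion_gap_mm Healthy gap between consecutive bumps, mm.
#' @param start_offset_range Healthy segment length at the ostium, mm.
#' @param theta_weights,theta_ranges Mixture weights and uniform ranges for
#'   the per-lesion remodeling response, named by intended pattern.
#' @param include_composition Generate virtual-histology tissue areas?
#' @param composition_base_pct Baseline tissue percentages
#'   (fibrous, fibrofatty, necrotic, dense calcium).
#' @param composition_effect Scale of the theta-linked composition shift
#'   (0 removes the class-composition association).
#' @param composition_lesion_sd,composition_frame_sd Log-scale composition
#'   noise per lesion and per frame.
#'
#' @return A list of class `fvri_sim_config`.
#' @export
simulation_config <- function(n_patients = 67,
                              artery_length_range = c(40, 80),
                              lm_length_range = c(5, 15),
                              frame_spacing = 0.3,
                              coefficients = packaged_normal_model()$coefficients,
                              vessel_coding = default_vessel_coding,
                              weight_mean = 72.0, weight_sd = 11.6,
                              height_mean = 161.6, height_sd = 7.9,
                              dominance_prev = 0.15,
                              bsa_formula = "mosteller",
                              lumen_noise_sd = 2.95,
                              lumen_noise_corr_mm = 5,
                              measurement_noise_sd = 0.8,
                              measurement_noise_corr_mm = 5,
                              lesion_rate = 6,
                              lesion_width_range = c(20, 45),
                              peak_burden_range = c(45, 75),
                              ectatic_peak_cap = 50,
                              taper_frac = 0.10,
                              lesion_gap_mm = 2,
                              start_offset_range = c(0.5, 4),
                              theta_weights = c(negative = 0.22,
                                                incomplete = 0.41,
                                                complete = 0.35,
                                                ectatic = 0.02),
                              theta_ranges = list(negative = c(-0.9, -0.4),
                                                  incomplete = c(0.2, 0.45),
                                                  complete = c(0.9, 1.1),
                                                  ectatic = c(1.45, 1.7)),
                              include_composition = TRUE,
                              composition_base_pct = c(fibrous = 55,
                                                       fibrofatty = 20,
                                                       necrotic = 15,
                                                       dense_calcium = 10),
                              composition_effect = 1,
                              composition_lesion_sd = 0.25,
                              composition_frame_sd = 0.1) {
  check_number(n_patients, "n_patients", lower = 1)
  check_number(frame_spacing, "frame_spacing", lower = 0, strict_lower = TRUE)
  check_number(lumen_noise_sd, "lumen_noise_sd", lower = 0)
  check_number(measurement_noise_sd, "measurement_noise_sd", lower = 0)
  check_number(lesion_rate, "lesion_rate", lower = 0)
  check_number(taper_frac, "taper_frac", lower = 0, upper = 1,
               strict_lower = TRUE)
  stopifnot(
    length(artery_length_range) == 2L, all(artery_length_range > 0),
    length(lesion_width_range) == 2L, all(lesion_width_range > 0),
    length(peak_burden_range) == 2L, all(peak_burden_range > 0),
    all(peak_burden_range < 100),
    identical(names(coefficients), model_terms),
    abs(sum(theta_weights) - 1) < 1e-8,
    identical(names(theta_weights), names(theta_ranges))
  )
  structure(
    as.list(environment()),
    class = "fvri_sim_config"
  )
}

# Tukey (raised-cosine-tapered plateau) bump shape on u in [-1, 1]
tukey_bump <- function(u, taper_frac) {
  t <- rep(0, length(u))
  inside <- abs(u) <= 1
  plateau <- 1 - taper_frac
  shoulder <- inside & abs(u) > plateau
  t[inside] <- 1
  t[shoulder] <- 0.5 * (1 + cos(pi * (abs(u[shoulder]) - plateau) / taper_frac))
  t
}

# stationary Gaussian noise with a Gaussian autocorrelation kernel; the
# marginal sd is preserved exactly
smooth_noise <- function(n, sd, corr_mm, spacing) {
  if (sd == 0) return(rep(0, n))
  if (corr_mm <= 0) return(rnorm(n, 0, sd))
  l <- corr_mm / spacing
  half <- ceiling(3 * l)
  w <- exp(-0.5 * (seq(-half, half) / l)^2)
  w <- w / sqrt(sum(w^2))
  z <- rnorm(n + 2 * half)
  sd * as.numeric(stats::filter(z, w, sides = 2))[(half + 1):(half + n)]
}

draw_theta <- function(config) {
  cls <- sample(names(config$theta_weights), 1L,
                prob = config$theta_weights)
  rng <- config$theta_ranges[[cls]]
  list(class = cls, theta = runif(1L, rng[1], rng[2]))
}

simulate_artery <- function(patient, vessel, config) {
  rng <- if (vessel == "LM") config$lm_length_range else
    config$artery_length_range
  len <- runif(1L, rng[1], rng[2])
  n <- max(3L, floor(len / config$frame_spacing))
  d <- config$frame_spacing * seq_len(n)

  frames <- tibble::tibble(
    patient_id = patient$patient_id,
    artery_id = paste0(patient$patient_id, "_", vessel),
    vessel = vessel,
    frame_index = seq_len(n),
    distance_mm = d,
    dominance = patient$dominance,
    weight_kg = patient$weight_kg,
    height_cm = patient$height_cm,
    bsa_m2 = patient$bsa_m2
  )
  X <- cbind(1, normal_design_matrix(frames, config$vessel_coding))
  mu <- drop(X %*% config$coefficients)

  # normal lumen with noise; a frame whose normal area falls below the
  # anatomical calibre floor (a 2 mm-diameter vessel, about the smallest an
  # IVUS catheter can image in the proximal segments modelled here) is
  # redrawn
  floor_mm2 <- 3.0
  rejected <- 0L
  eps <- smooth_noise(n, config$lumen_noise_sd, config$lumen_noise_corr_mm,
                      config$frame_spacing)
  N <- mu + eps
  for (i in which(N < floor_mm2)) {
    tries <- 0L
    while (N[i] < floor_mm2 && tries < 100L) {
      N[i] <- mu[i] + rnorm(1L, 0, config$lumen_noise_sd)
      tries <- tries + 1L
      rejected <- rejected + 1L
    }
    if (N[i] < floor_mm2) N[i] <- floor_mm2
  }

  # plaque bumps: sequential proximal-to-distal placement with fixed healthy
  # gaps; the final bump is truncated at the pullback end
  burden <- rep(0, n)
  theta <- rep(NA_real_, n)
  lesion_id <- rep(NA_character_, n)
  lesion_class <- rep(NA_character_, n)
  n_les <- rpois(1L, config$lesion_rate)
  pos <- runif(1L, config$start_offset_range[1], config$start_offset_range[2])
  placed <- 0L
  k <- 0L
  while (k < n_les) {
    k <- k + 1L
    width <- runif(1L, config$lesion_width_range[1],
                   config$lesion_width_range[2])
    if (pos + 2 >= len) break
    width <- min(width, len - pos)
    if (width < 3) break
    th <- draw_theta(config)
    peak <- if (th$class == "ectatic") {
      runif(1L, min(42, config$ectatic_peak_cap), config$ectatic_peak_cap)
    } else {
      runif(1L, config$peak_burden_range[1], config$peak_burden_range[2])
    }
    # geometric guard: burden * theta must stay well below 1
    if (th$theta > 0) peak <- min(peak, 90 / th$theta)
    centre <- pos + width / 2
    u <- (d - centre) / (width / 2)
    inb <- abs(u) <= 1
    b <- peak * tukey_bump(u, config$taper_frac)
    take <- inb & b > burden
    burden[take] <- b[take]
    placed <- placed + 1L
    this_id <- sprintf("%s_%s/L%d", patient$patient_id, vessel, placed)
    theta[inb & is.na(lesion_id)] <- th$theta
    lesion_class[inb & is.na(lesion_id)] <- th$class
    lesion_id[inb & is.na(lesion_id)] <- this_id
    pos <- pos + width + config$lesion_gap_mm
  }

  # compensation is complete at trivial burden and fails progressively as
  # plaque accumulates: the effective response ramps from 1 below 20% burden
  # to the lesion's theta by 35% burden, so near-normal frames really do
  # retain their normal lumen and established-plaque frames express the
  # lesion's full response
  bfrac <- burden / 100
  th_les <- ifelse(is.na(theta), 1, theta)
  ramp <- pmin(1, pmax(0, (burden - 20) / 15))
  th_num <- 1 - (1 - th_les) * ramp
  P <- ifelse(bfrac > 0, bfrac * N / (1 - bfrac * th_num), 0)
  eem_true <- N + th_num * P

  # tracing error scales with contour perimeter ~ sqrt(area); the sd
  # parameter refers to a vessel of the cohort-mean EEM area
  m <- smooth_noise(n, config$measurement_noise_sd,
                    config$measurement_noise_corr_mm, config$frame_spacing) *
    sqrt(pmax(eem_true, 0.5) / 14.2)
  eem_obs <- eem_true + m
  lumen_obs <- eem_obs - P
  for (i in which(lumen_obs <= 0.05)) {
    tries <- 0L
    while (lumen_obs[i] <= 0.05 && tries < 100L) {
      m[i] <- rnorm(1L, 0, config$measurement_noise_sd) *
        sqrt(max(eem_true[i], 0.5) / 14.2)
      eem_obs[i] <- eem_true[i] + m[i]
      lumen_obs[i] <- eem_obs[i] - P[i]
      tries <- tries + 1L
      rejected <- rejected + 1L
    }
    if (lumen_obs[i] <= 0.05) {
      eem_obs[i] <- eem_true[i] + (0.05 - (eem_true[i] - P[i]))
      lumen_obs[i] <- 0.05
    }
  }

  frames$lumen_area_mm2 <- lumen_obs
  frames$eem_area_mm2 <- eem_obs

  if (config$include_composition) {
    base <- log(config$composition_base_pct)
    direction <- c(fibrous = 0, fibrofatty = -0.6, necrotic = 0.35,
                   dense_calcium = 0.6)
    les_noise <- matrix(0, n, 4L)
    for (id in unique(lesion_id[!is.na(lesion_id)])) {
      rows <- which(lesion_id == id)
      les_noise[rows, ] <- matrix(
        rnorm(4L, 0, config$composition_lesion_sd), length(rows), 4L,
        byrow = TRUE
      )
    }
    shift <- outer(config$composition_effect * (1 - th_num), direction)
    logits <- matrix(base, n, 4L, byrow = TRUE) + shift + les_noise +
      matrix(rnorm(4L * n, 0, config$composition_frame_sd), n, 4L)
    pct <- exp(logits) / rowSums(exp(logits))
    areas <- pct * P
    areas[P == 0, ] <- NA_real_
    frames$fibrous_mm2 <- areas[, 1]
    frames$fibrofatty_mm2 <- areas[, 2]
    frames$necrotic_mm2 <- areas[, 3]
    frames$dense_calcium_mm2 <- areas[, 4]
  } else {
    frames$fibrous_mm2 <- NA_real_
    frames$fibrofatty_mm2 <- NA_real_
    frames$necrotic_mm2 <- NA_real_
    frames$dense_calcium_mm2 <- NA_real_
  }

  truth <- tibble::tibble(
    patient_id = frames$patient_id,
    artery_id = frames$artery_id,
    frame_index = frames$frame_index,
    distance_mm = d,
    normal_eem_mm2 = N,
    plaque_mm2 = P,
    lesion_id = lesion_id,
    theta = theta,
    theta_eff = ifelse(P > 0, th_num, NA_real_),
    theta_class = lesion_class,
    true_eem_mm2 = eem_true,
    true_burden_pct = 100 * P / eem_true,
    true_fvri = ifelse(P > 0, (N + th_num * P) / (N + P), NA_real_)
  )
  list(frames = frames, truth = truth, rejected = rejected)
}

#' Simulate a synthetic IVUS cohort
#'
#' Generates patients, per-artery frame tables and frame-level ground truth
#' under the generative model described in [simulation_config()]. The output
#' is byte-identical for a given seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (mandatory).
#'
#' @return A list of class `fvri_cohort` with elements `patients`, `frames`
#'   (schema of [read_pullbacks()], geometry included), `ground_truth`
#'   (per-frame normal area, plaque, theta, true FVRI and true class),
#'   `lesion_truth` (per generated bump: theta and the true class at its true
#'   MLA frame), `rejected_frames` (redraw count) and the config.
#' @export
simulate_cohort <- function(config = simulation_config(), seed) {
  if (missing(seed)) stop_fvri("a `seed` is required.")
  stopifnot(inherits(config, "fvri_sim_config"))
  withr::with_seed(seed, {
    n_pat <- as.integer(config$n_patients)
    weight <- rnorm(n_pat, config$weight_mean, config$weight_sd)
    height <- rnorm(n_pat, config$height_mean, config$height_sd)
    while (any(weight <= 30)) {
      weight[weight <= 30] <- rnorm(sum(weight <= 30), config$weight_mean,
                                    config$weight_sd)
    }
    while (any(height <= 100)) {
      height[height <= 100] <- rnorm(sum(height <= 100), config$height_mean,
                                     config$height_sd)
    }
    left <- runif(n_pat) < config$dominance_prev
    patients <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n_pat)),
      weight_kg = weight,
      height_cm = height,
      bsa_m2 = compute_bsa(weight, height, config$bsa_formula),
      dominance = ifelse(left,
                         sample(c("left", "balanced"), n_pat, replace = TRUE),
                         "right")
    )
    out <- vector("list", n_pat * length(config$vessel_coding))
    idx <- 0L
    for (i in seq_len(n_pat)) {
      for (vessel in names(config$vessel_coding)) {
        idx <- idx + 1L
        out[[idx]] <- simulate_artery(patients[i, ], vessel, config)
      }
    }
  })
  frames <- add_geometry(dplyr::bind_rows(lapply(out, `[[`, "frames")))
  truth <- dplyr::bind_rows(lapply(out, `[[`, "truth"))

  # true class of each frame with plaque, using the generating band
  cfg <- fvri_config()
  est <- truth$plaque_mm2 > 0
  truth$true_class <- factor("trivial_plaque", levels = remodeling_levels)
  truth$true_class[est] <- classify_remodeling(
    truth$true_fvri[est], truth$true_burden_pct[est],
    truth$true_eem_mm2[est], truth$normal_eem_mm2[est], cfg
  )

  # the lesion-level truth frame is the minimal true lumen among in-bump
  # frames with established (> 40%) true burden -- the shoulders of a fully
  # compensated bump have no stenosis, so an unrestricted minimum would land
  # on noise
  one_lesion_truth <- function(df) {
    zone <- which(df$true_burden_pct > 40)
    if (length(zone) == 0L) zone <- which.max(df$true_burden_pct)
    j <- zone[which.min(df$true_eem_mm2[zone] - df$plaque_mm2[zone])]
    tibble::tibble(
      patient_id = df$patient_id[1], artery_id = df$artery_id[1],
      lesion_id = df$lesion_id[1], theta = df$theta[1],
      theta_class = df$theta_class[1],
      start_mm = min(df$distance_mm), end_mm = max(df$distance_mm),
      peak_burden_pct = max(df$true_burden_pct),
      true_mla_frame = df$frame_index[j],
      true_fvri = df$true_fvri[j],
      true_class = df$true_class[j]
    )
  }
  in_bump <- truth[!is.na(truth$lesion_id), ]
  lesion_truth <- if (nrow(in_bump) == 0L) {
    tibble::tibble(
      patient_id = character(), artery_id = character(),
      lesion_id = character(), theta = numeric(), theta_class = character(),
      start_mm = numeric(), end_mm = numeric(), peak_burden_pct = numeric(),
      true_mla_frame = integer(), true_fvri = numeric(),
      true_class = factor(character(), levels = remodeling_levels)
    )
  } else {
    dplyr::bind_rows(lapply(split(in_bump, in_bump$lesion_id),
                            one_lesion_truth))
  }
  lesion_truth <- dplyr::arrange(lesion_truth, .data$patient_id,
                                 .data$artery_id, .data$start_mm)

  structure(
    list(
      patients = patients, frames = frames, ground_truth = truth,
      lesion_truth = lesion_truth,
      rejected_frames = sum(vapply(out, `[[`, integer(1), "rejected")),
      config = config, seed = as.integer(seed)
    ),
    class = "fvri_cohort"
  )
}

#' @export
print.fvri_cohort <- function(x, ...) {
  cat(sprintf(
    "<fvri_cohort: %d patients, %d arteries, %d frames (seed %d)>\n",
    nrow(x$patients), length(unique(x$frames$artery_id)),
    nrow(x$frames), x$seed
  ))
  cat(sprintf(
    "  low-burden (<20%%) frames: %.1f%%; generated bumps: %d; redrawn frames: %d\n",
    100 * mean(x$frames$plaque_burden_pct < 20), nrow(x$lesion_truth),
    x$rejected_frames
  ))
  invisible(x)
}

#' Write a simulated cohort to CSV
#'
#' Writes `patients.csv` and `frames.csv` (the [read_pullbacks()] schemas)
#' plus `ground_truth.csv` with the per-frame generative truth.
#'
#' @param cohort A `fvri_cohort`.
#' @param dir Output directory.
#'
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  paths <- write_pullbacks(cohort$frames, cohort$patients, dir)
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- cohort$ground_truth
  gt[] <- lapply(gt, function(x) if (is.numeric(x)) round(x, 6) else x)
  readr::write_csv(gt, gt_path, progress = FALSE, na = "")
  invisible(c(paths, ground_truth = gt_path))
}

#' Calibrate the normal-lumen noise to a target model fit
#'
#' Finds, by bisection, the lumen noise sd under which refitting the normal
#' dimension model on a simulated cohort's training frames yields a target
#' adjusted R^2 (default 0.46). A target of 1 corresponds to the noise-free
#' limit (sd 0); targets at or below 0 are rejected as degenerate. Each
#' candidate sd is evaluated on a cohort simulated from the same derived
#' seed, so the bisection is deterministic given `seed`.
#'
#' @param config A [simulation_config()]; its `n_patients` controls the
#'   calibration sample size.
#' @param target_adjusted_r2 Target adjusted R^2 in (0, 1].
#' @param seed Integer seed.
#' @param tol Acceptable |adjusted R^2 - target|.
#' @param sd_bracket Initial search bracket for the sd, mm^2.
#'
#' @return The calibrated lumen noise sd, mm^2, with the achieved adjusted
#'   R^2 as attribute `adjusted_r2`.
#' @export
calibrate_noise <- function(config = simulation_config(),
                            target_adjusted_r2 = 0.46, seed,
                            tol = 0.03, sd_bracket = c(0.05, 8)) {
  if (missing(seed)) stop_fvri("a `seed` is required.")
  check_number(target_adjusted_r2, "target_adjusted_r2", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (target_adjusted_r2 == 1) {
    return(structure(0, adjusted_r2 = 1))
  }
  eval_seed <- derive_seeds(seed, 1L)
  eval_r2 <- function(sd) {
    cfg <- config
    cfg$lumen_noise_sd <- sd
    cohort <- simulate_cohort(cfg, seed = eval_seed)
    training <- select_training_frames(cohort$frames)
    fit_normal_model(training, vessel_coding = config$vessel_coding)$adjusted_r2
  }
  lo <- sd_bracket[1]; hi <- sd_bracket[2]
  r2_lo <- eval_r2(lo); r2_hi <- eval_r2(hi)
  if (r2_lo < target_adjusted_r2 || r2_hi > target_adjusted_r2) {
    stop_fvri(sprintf(
      "target adjusted R^2 %.3f unreachable: bracket sd [%g, %g] gives R^2 [%.3f, %.3f].",
      target_adjusted_r2, lo, hi, r2_hi, r2_lo
    ))
  }
  r2_mid <- NA_real_
  for (i in seq_len(40L)) {
    mid <- (lo + hi) / 2
    r2_mid <- eval_r2(mid)
    if (abs(r2_mid - target_adjusted_r2) <= tol) break
    if (r2_mid > target_adjusted_r2) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, adjusted_r2 = r2_mid)
}
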