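#' Tri-exponential arterial input function parameters
#'
#' Feng-type bolus-plus-tail plasma input: after a delay `d`,
#' `Cp(t) = (A1 u - A2 - A3) exp(-l1 u) + A2 exp(-l2 u) + A3 exp(-l3 u)`
#' with `u = t - d`, and `Cp = 0` before the bolus arrives. Amplitudes are
#' calibrated for a nominal 370 MBq (10 mCi) injection; scale linearly for
#' other doses.
#'
#' @param A1 bolus amplitude slope (Bq/ml/s).
#' @param A2,A3 tail amplitudes (Bq/ml).
#' @param lambda1,lambda2,lambda3 decay rates (1/s), `lambda1 > lambda2 >
#'   lambda3 > 0`.
#' @param delay bolus arrival delay (s).
#' @return An object of class `"aif_params"`.
#' @export
aif_params <- function(A1 = 3000, A2 = 500, A3 = 200,
                       lambda1 = 0.035, lambda2 = 0.0025, lambda3 = 0.00015,
                       delay = 10) {
  p <- list(A1 = A1, A2 = A2, A3 = A3,
            lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            delay = delay)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE)))
    stop("all AIF parameters must be finite scalars")
  if (!(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 > 0))
    stop("AIF decay rates must satisfy lambda1 > lambda2 > lambda3 > 0")
  if (delay < 0) stop("delay must be >= 0")
  p <- structure(p, class = "aif_params")
  cp <- aif(seq(0, 3600, by = 1), p)
  if (min(cp) < -1e-9 * max(abs(cp)))
    stop("AIF parameters produce a negative plasma curve on [0, 3600 s]")
  p
}

#' Evaluate the arterial input function
#'
#' @param t times (s), >= 0.
#' @param params an [aif_params()].
#' @return Plasma activity Cp(t) in Bq/ml (0 before the bolus delay).
#' @export
aif <- function(t, params = aif_params()) {
  stopifnot(inherits(params, "aif_params"))
  if (any(t < 0)) stop("t must be >= 0")
  u <- t - params$delay
  cp <- ifelse(u < 0, 0,
               (params$A1 * u - params$A2 - params$A3) * exp(-params$lambda1 * u) +
                 params$A2 * exp(-params$lambda2 * u) +
                 params$A3 * exp(-params$lambda3 * u))
  pmax(cp, 0)
}

#' Reference-tissue kinetic parameters for one region
#'
#' @param R1 relative delivery (target K1 over reference K1), > 0.
#' @param k2 tissue efflux rate (1/min), > 0.
#' @param bpnd non-displaceable binding potential, >= 0.
#' @return An object of class `"region_kinetics"` with derived `k2a =
#'   k2/(1+bpnd)` and `dvr = 1 + bpnd`.
#' @export
region_kinetics <- function(R1, k2, bpnd) {
  if (R1 <= 0 || k2 <= 0 || bpnd < 0)
    stop("need R1 > 0, k2 > 0, bpnd >= 0")
  structure(list(R1 = R1, k2 = k2, bpnd = bpnd,
                 k2a = k2 / (1 + bpnd), dvr = 1 + bpnd),
            class = "region_kinetics")
}

# convolution of f (sampled on a uniform grid t) with exp(-k * t), trapezoid
# update y[i] = E y[i-1] + dt/2 (f[i] + E f[i-1]); exact for k = 0 too
conv_exp <- function(t, f, k) {
  n <- length(t)
  if (n < 2L) return(rep(0, n))
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) > 1e-9) stop("conv_exp requires a uniform grid")
  dt <- dt[1L]
  E <- exp(-k * dt)
  b <- c(0, dt / 2 * (f[-1L] + E * f[-n]))
  as.numeric(stats::filter(b, E, method = "recursive"))
}

#' One-tissue reference-region curve on a fine grid
#'
#' Solves the one-tissue compartment model
#' `C_ref(t) = K1_ref (Cp (x) exp(-k2_ref t))` by discrete convolution.
#'
#' @param t uniform fine time grid (s) starting at 0.
#' @param params an [aif_params()].
#' @param K1_ref delivery rate (ml/ml/min).
#' @param k2_ref efflux rate (1/min).
#' @param scale multiplicative plasma scale (e.g. dose_mbq / 370).
#' @return Numeric vector C_ref(t) in Bq/ml.
#' @export
reference_curve <- function(t, params = aif_params(), K1_ref = 0.3,
                            k2_ref = 0.15, scale = 1) {
  if (K1_ref < 0 || k2_ref <= 0) stop("need K1_ref >= 0 and k2_ref > 0")
  (K1_ref / 60) * conv_exp(t, aif(t, params) * scale, k2_ref / 60)
}

#' SRTM tissue curve from a reference curve
#'
#' Simplified reference tissue model used generatively:
#' `C_T = R1 C_ref + (k2 - R1 k2a) (C_ref (x) exp(-k2a t))` with
#' `k2a = k2 / (1 + BPND)`. With `R1 = 1` and `BPND = 0` the target equals
#' the reference exactly.
#'
#' @param t uniform fine time grid (s).
#' @param ref reference-region curve sampled on `t` (Bq/ml).
#' @param kinetics a [region_kinetics()].
#' @return Numeric vector C_T(t) in Bq/ml.
#' @export
srtm_curve <- function(t, ref, kinetics) {
  stopifnot(inherits(kinetics, "region_kinetics"))
  k2 <- kinetics$k2 / 60
  k2a <- kinetics$k2a / 60
  kinetics$R1 * ref + (k2 - kinetics$R1 * k2a) * conv_exp(t, ref, k2a)
}

#' Average a fine curve onto a frame schedule
#'
#' Frame values are the mean of the fine-grid curve over each frame interval,
#' mirroring how a scanner integrates counts over a frame.
#'
#' @param t uniform fine time grid (s).
#' @param y curve values on `t`.
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of per-frame means.
#' @export
frame_average <- function(t, y, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (max(schedule$end) > max(t) + 1e-9)
    stop("fine grid does not cover the schedule")
  vapply(seq_along(schedule$start), function(i) {
    ix <- t >= schedule$start[i] - 1e-9 & t <= schedule$end[i] + 1e-9
    mean(y[ix])
  }, numeric(1))
}

#' Simulate a framed reference-region TAC
#'
#' @inheritParams reference_curve
#' @param schedule a [frame_schedule()].
#' @param injected_dose dose in MBq (also sets the plasma scale relative to
#'   the 370 MBq nominal amplitude unless `scale` is given).
#' @param fine_step fine simulation grid step (s).
#' @param scale optional explicit plasma scale; default `injected_dose / 370`.
#' @return A [tac()] labelled `"cerebellar_cortex"`.
#' @export
reference_tac <- function(params = aif_params(), K1_ref = 0.3, k2_ref = 0.15,
                          schedule = pib_schedule(), injected_dose = 370,
                          fine_step = 0.5, scale = NULL) {
  t <- seq(0, max(schedule$end), by = fine_step)
  if (is.null(scale)) scale <- injected_dose / 370
  cref <- reference_curve(t, params, K1_ref, k2_ref, scale)
  tac("cerebellar_cortex", schedule, frame_average(t, cref, schedule), injected_dose)
}

#' Simulate a framed target-region TAC from a fine reference curve
#'
#' @param t uniform fine time grid (s).
#' @param ref reference curve on `t` (Bq/ml).
#' @param kinetics a [region_kinetics()].
#' @param schedule a [frame_schedule()].
#' @param injected_dose dose in MBq.
#' @param region region label.
#' @return A [tac()].
#' @export
srtm_tac <- function(t, ref, kinetics, schedule = pib_schedule(),
                     injected_dose = 370, region = "target") {
  ct <- srtm_curve(t, ref, kinetics)
  tac(region, schedule, frame_average(t, ct, schedule), injected_dose)
}

#' Add frame-duration-weighted Gaussian noise to a TAC
#'
#' Count-statistics-like heteroscedastic noise: each frame receives zero-mean
#' Gaussian noise with standard deviation
#' `noise_level * sqrt(max(S, 0) / duration)`, so shorter frames are noisier.
#' Negative resulting activities are kept, as in real reconstructions. Uses
#' the current RNG state; seed beforehand for determinism.
#'
#' @param tac a [tac()].
#' @param noise_level unitless noise magnitude, >= 0; 0 returns the TAC
#'   unchanged.
#' @return A [tac()] with noisy activities.
#' @export
add_noise <- function(tac, noise_level) {
  stopifnot(inherits(tac, "tac"))
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (noise_level == 0) return(tac)
  sdv <- noise_level * sqrt(pmax(tac$activity, 0) / tac$schedule$duration)
  tac(tac$region, tac$schedule,
      tac$activity + stats::rnorm(length(tac$activity), 0, sdv),
      tac$injected_dose)
}

#' Default per-region binding presets for the synthetic cohort
#'
#' Six regions: the cerebellar cortex reference (no specific binding in
#' either group), two featured regions carrying the group signal (caudal
#' anterior cingulate strongly, caudate weakly), and three cortical regions
#' with background-level binding in both groups.
#'
#' @return A data.frame with columns `region`, `reference`, `featured`,
#'   `bpnd_mean_hc`, `bpnd_sd_hc`, `bpnd_mean_ad`, `bpnd_sd_ad`.
#' @export
region_presets <- function() {
  data.frame(
    region = c("cerebellar_cortex", "caudal_anterior_cingulate", "caudate",
               "frontal_cortex", "parietal_cortex", "precuneus"),
    reference = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    featured = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    bpnd_mean_hc = c(0, 0.10, 0.05, 0.10, 0.10, 0.10),
    bpnd_sd_hc   = c(0, 0.05, 0.04, 0.05, 0.05, 0.05),
    bpnd_mean_ad = c(0, 0.90, 0.40, 0.10, 0.10, 0.10),
    bpnd_sd_ad   = c(0, 0.25, 0.15, 0.05, 0.05, 0.05),
    stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Settings for [simulate_cohort()]: group sizes, regions and their
#' group-wise binding distributions, delivery and reference kinetics, noise,
#' dose range and the clinical-score model.
#'
#' @param n_ad,n_hc group sizes (>= 0).
#' @param regions a data.frame as returned by [region_presets()].
#' @param aif an [aif_params()].
#' @param r1_mean_ad,r1_mean_hc,r1_sd relative-delivery distribution per
#'   group (AD delivery deficit: lower mean R1).
#' @param k1_ref,k2_ref reference-region kinetics (ml/ml/min, 1/min).
#' @param ref_scale_sd between-subject lognormal-ish variability of reference
#'   delivery (sd of a Gaussian gain around 1).
#' @param noise_level see [add_noise()].
#' @param dose_range_mci injected dose range in mCi (uniform draw; stored in
#'   MBq, 1 mCi = 37 MBq).
#' @param mmse_intercept,mmse_slope,mmse_sd MMSE generated as
#'   `intercept + slope * mean featured BPND + noise`, clipped to [0, 30].
#' @param cdr_slope,cdr_sd CDR-SOB for AD as `slope * mean featured BPND +
#'   noise`, clipped to [0, 9] in half-point steps; HC always 0.
#' @param schedule a [frame_schedule()].
#' @param fine_step fine simulation grid step (s).
#' @param seed integer seed; a fixed seed makes the cohort fully reproducible.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_ad = 50, n_hc = 50, regions = region_presets(),
                          aif = aif_params(),
                          r1_mean_ad = 0.85, r1_mean_hc = 1.0, r1_sd = 0.05,
                          k1_ref = 0.3, k2_ref = 0.15, ref_scale_sd = 0.05,
                          noise_level = 5, dose_range_mci = c(6, 20),
                          mmse_intercept = 29, mmse_slope = -8, mmse_sd = 1.2,
                          cdr_slope = 5, cdr_sd = 0.8,
                          schedule = pib_schedule(), fine_step = 0.5,
                          seed = 1L) {
  if (n_ad < 0 || n_hc < 0) stop("group sizes must be >= 0")
  need <- c("region", "reference", "featured", "bpnd_mean_hc", "bpnd_sd_hc",
            "bpnd_mean_ad", "bpnd_sd_ad")
  if (!is.data.frame(regions) || !all(need %in% names(regions)))
    stop("regions must be a data.frame like region_presets()")
  if (nrow(regions) < 3) stop("need at least 3 regions")
  if (!any(regions$reference)) stop("a reference region is required")
  if (anyDuplicated(regions$region)) stop("region labels must be unique")
  if (length(dose_range_mci) != 2 || dose_range_mci[1] <= 0 ||
      dose_range_mci[1] > dose_range_mci[2])
    stop("dose_range_mci must be an increasing positive pair")
  structure(list(n_ad = n_ad, n_hc = n_hc, regions = regions, aif = aif,
                 r1_mean_ad = r1_mean_ad, r1_mean_hc = r1_mean_hc,
                 r1_sd = r1_sd, k1_ref = k1_ref, k2_ref = k2_ref,
                 ref_scale_sd = ref_scale_sd, noise_level = noise_level,
                 dose_range_mci = dose_range_mci,
                 mmse_intercept = mmse_intercept, mmse_slope = mmse_slope,
                 mmse_sd = mmse_sd, cdr_slope = cdr_slope, cdr_sd = cdr_sd,
                 schedule = schedule, fine_step = fine_step,
                 seed = seed),
            class = "cohort_config")
}

#' Simulate a dynamic-PET cohort with known ground truth
#'
#' Generates `n_ad + n_hc` subjects on the configured frame schedule. Target
#' regions are SRTM curves over a shared one-tissue reference curve; AD
#' subjects draw higher binding in the featured regions and lower relative
#' delivery (slower clearance, greater retention), while the reference region
#' has the same kinetics distribution in both groups. Clinical scores are
#' monotone functions of the mean featured-region binding plus noise.
#'
#' @param config a [cohort_config()].
#' @return An object of class `"pet_cohort"`: a list with `subjects` (each of
#'   class `"pet_subject"`), the `schedule`, the `config`, and a
#'   `ground_truth` data.frame with per subject-region `R1`, `k2`, `bpnd` and
#'   `dvr_true = 1 + bpnd`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_ad = 2, n_hc = 2, seed = 7))
#' coh
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sch <- config$schedule
  t_fine <- seq(0, max(sch$end), by = config$fine_step)
  reg <- config$regions
  ref_region <- reg$region[reg$reference][1L]
  groups <- c(rep("AD", config$n_ad), rep("HC", config$n_hc))
  ids <- c(sprintf("AD_%03d", seq_len(config$n_ad)),
           sprintf("HC_%03d", seq_len(config$n_hc)))
  subjects <- vector("list", length(ids))
  gt <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ad <- groups[i] == "AD"
    dose <- stats::runif(1, config$dose_range_mci[1], config$dose_range_mci[2]) * 37
    ref_gain <- stats::rnorm(1, 1, config$ref_scale_sd)
    R1 <- stats::rnorm(1, if (ad) config$r1_mean_ad else config$r1_mean_hc,
                       config$r1_sd)
    cref <- reference_curve(t_fine, config$aif,
                            K1_ref = config$k1_ref * ref_gain,
                            k2_ref = config$k2_ref, scale = dose / 370)
    act <- matrix(NA_real_, nrow(reg), length(sch$start),
                  dimnames = list(reg$region, NULL))
    kin_rows <- vector("list", nrow(reg))
    for (r in seq_len(nrow(reg))) {
      if (reg$reference[r]) {
        bp <- 0
        tc <- tac(reg$region[r], sch, frame_average(t_fine, cref, sch), dose)
        kin <- region_kinetics(1, config$k2_ref, 0)
      } else {
        mu <- if (ad) reg$bpnd_mean_ad[r] else reg$bpnd_mean_hc[r]
        sdv <- if (ad) reg$bpnd_sd_ad[r] else reg$bpnd_sd_hc[r]
        bp <- max(stats::rnorm(1, mu, sdv), 0)
        kin <- region_kinetics(R1, R1 * config$k2_ref, bp)
        tc <- srtm_tac(t_fine, cref, kin, sch, dose, reg$region[r])
      }
      tc <- add_noise(tc, config$noise_level)
      act[r, ] <- tc$activity
      kin_rows[[r]] <- data.frame(subject_id = ids[i], group = groups[i],
                                  region = reg$region[r], R1 = kin$R1,
                                  k2 = kin$k2, bpnd = bp, dvr_true = 1 + bp,
                                  stringsAsFactors = FALSE)
    }
    gt_i <- do.call(rbind, kin_rows)
    mean_bp <- mean(gt_i$bpnd[reg$featured])
    mmse <- round(min(max(config$mmse_intercept + config$mmse_slope * mean_bp +
                            stats::rnorm(1, 0, config$mmse_sd), 0), 30))
    cdr <- if (ad)
      round(2 * min(max(config$cdr_slope * mean_bp +
                          stats::rnorm(1, 0, config$cdr_sd), 0), 9)) / 2
    else 0
    subjects[[i]] <- structure(list(subject_id = ids[i], group = groups[i],
                                    schedule = sch, injected_dose = dose,
                                    activity = act, mmse = mmse,
                                    cdr_sob = cdr),
                               class = "pet_subject")
    gt[[i]] <- gt_i
  }
  structure(list(subjects = subjects, schedule = sch, config = config,
                 ground_truth = do.call(rbind, c(gt, list(make.row.names = FALSE))),
                 reference_region = ref_region),
            class = "pet_cohort")
}

#' Extract one region's TAC from a simulated or imported subject
#'
#' @param subject a `"pet_subject"`.
#' @param region region label.
#' @return A [tac()].
#' @export
subject_tac <- function(subject, region) {
  stopifnot(inherits(subject, "pet_subject"))
  if (!region %in% rownames(subject$activity))
    stop(sprintf("subject '%s' has no region '%s'", subject$subject_id, region))
  tac(region, subject$schedule, subject$activity[region, ],
      subject$injected_dose)
}

#' Group labels of a cohort as 0/1 (HC = 0, AD = 1)
#'
#' @param cohort a `"pet_cohort"`.
#' @return Integer vector, NA for subjects with unknown group.
#' @export
cohort_labels <- function(cohort) {
  stopifnot(inherits(cohort, "pet_cohort"))
  g <- vapply(cohort$subjects, function(s) s$group, "")
  ifelse(g == "AD", 1L, ifelse(g == "HC", 0L, NA_integer_))
}

#' @export
print.pet_cohort <- function(x, ...) {
  g <- table(vapply(x$subjects, function(s) s$group, ""))
  cat(sprintf("pet_cohort: %d subjects (%s), %d regions, %d frames\n",
              length(x$subjects),
              paste(names(g), as.integer(g), sep = "=", collapse = ", "),
              nrow(x$subjects[[1]]$activity), length(x$schedule$start)))
  invisible(x)
}

#' @export
print.pet_subject <- function(x, ...) {
  cat(sprintf("pet_subject '%s' (%s): dose %.1f MBq, MMSE %s, CDR-SOB %s, %d regions\n",
              x$subject_id, x$group, x$injected_dose,
              format(x$mmse), format(x$cdr_sob), nrow(x$activity)))
  invisible(x)
}
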