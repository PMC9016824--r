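# Shared fixtures, all built in code.

# Piecewise-linear TAC on the PiB schedule: S(0) = 10, peak 100 at the
# 150 s frame, linear decline to 70 at 1650 s, flat afterwards.
worked_tac <- function(dose = 1) {
  sch <- pib_schedule()
  mid <- mid_times(sch)
  up <- approx(c(5, 150), c(10, 100), xout = pmin(mid, 150))$y
  dn <- approx(c(150, 1650), c(100, 70), xout = pmin(mid, 1650))$y
  tac("ctx", sch, ifelse(mid <= 150, up, dn), dose)
}

# Random plausible TAC on the PiB schedule: fast rise, exponential-ish decay.
random_tac <- function(dose = runif(1, 222, 740)) {
  sch <- pib_schedule()
  mid <- mid_times(sch)
  peak_t <- runif(1, 90, 230)
  peak <- runif(1, 1000, 5000)
  decay <- runif(1, 2e-4, 1e-3)
  act <- ifelse(mid <= peak_t, peak * mid / peak_t,
                peak * exp(-decay * (mid - peak_t)))
  tac("ctx", sch, act * (1 + runif(length(mid), -0.02, 0.02)), dose)
}

# Build a cohort object from per-subject activity matrices (regions x frames).
make_cohort <- function(activities, groups, schedule = pib_schedule(),
                        dose = 370) {
  n <- length(activities)
  dose <- rep_len(dose, n)
  subjects <- lapply(seq_len(n), function(i) {
    structure(list(subject_id = sprintf("S%03d", i), group = groups[i],
                   schedule = schedule, injected_dose = dose[i],
                   activity = activities[[i]], mmse = NA_real_,
                   cdr_sob = NA_real_),
              class = "pet_subject")
  })
  structure(list(subjects = subjects, schedule = schedule, config = NULL,
                 ground_truth = NULL,
                 reference_region = "cerebellar_cortex"),
            class = "pet_cohort")
}

# Fine-grid Riemann-sum integral of the piecewise-linear TAC interpolant,
# used as the independent oracle for trapezoid_integral.
riemann_integral <- function(tac, from, to, n = 10000) {
  tt <- seq(from, to, length.out = n + 1)
  yy <- interpolate_tac(tac, tt)
  sum((yy[-1] + yy[-length(yy)]) / 2) * (to - from) / n
}

# Exhaustive pairwise AUC with ties counted one half.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
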