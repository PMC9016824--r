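test_that("AQI matches hand arithmetic on the worked two-slope TAC", {
  # S(0) = 10, peak 100 at t_max = 150 s, S(1650) = 70, a = 0.5, dose 1 MBq
  expect_equal(compute_aqi(worked_tac()),
               0.5 * (70 - 10) / 1650 - 0.5 * (100 - 70) / (1650 - 150),
               tolerance = 1e-12)
})

test_that("a constant TAC has AQI zero and parameter bounds are enforced", {
  const <- tac("r", pib_schedule(), rep(900, 26), 500)
  expect_equal(compute_aqi(const), 0)
  expect_error(compute_aqi(worked_tac(), aqi_params(0.5, 1650, 100)),
               "t2 .* must exceed the peak")
  expect_error(compute_aqi(worked_tac(), aqi_params(0.5, 3500, 1650)),
               "last frame mid-time")
  expect_error(aqi_params(a = 1.2), "\\[0, 1\\]")
})

test_that("defaults reduce to the optimized two-slope special case", {
  set.seed(51)
  for (i in 1:50) {
    tc <- random_tac()
    tm <- find_tmax(tc)
    s0 <- tc$activity[1]
    s1650 <- interpolate_tac(tc, 1650)
    stm <- max(tc$activity)
    special <- (0.5 * (s1650 - s0) / 1650 -
                  0.5 * (stm - s1650) / (1650 - tm)) / tc$injected_dose
    expect_equal(compute_aqi(tc), special, tolerance = 1e-12)
  }
})

test_that("AQI is invariant to a common scaling of activity and dose", {
  set.seed(61)
  for (i in 1:10) {
    tc <- random_tac()
    c_ <- runif(1, 0.1, 10)
    scaled <- tac(tc$region, tc$schedule, c_ * tc$activity,
                  c_ * tc$injected_dose)
    expect_equal(compute_aqi(scaled), compute_aqi(tc), tolerance = 1e-10)
  }
})

test_that("AQI increases with binding potential in the noise-free SRTM family", {
  p <- aif_params()
  tt <- seq(0, 3600, 0.5)
  ref <- reference_curve(tt, p)
  vals <- vapply(seq(0, 1.5, 0.25), function(bp)
    compute_aqi(srtm_tac(tt, ref, region_kinetics(0.9, 0.9 * 0.15, bp))),
    0)
  expect_true(all(diff(vals) > 0))
})

test_that("SUVR is a late-window ratio with the expected frame selection", {
  sch <- pib_schedule()
  set.seed(71)
  ref <- random_tac()
  expect_equal(compute_suvr(ref, ref), 1.0)
  dbl <- tac("t", sch, 2 * ref$activity, ref$injected_dose)
  expect_equal(compute_suvr(dbl, ref), 2.0)
  # 30-60 min window takes exactly the six 5-min frames with mids 1950..3450
  w <- which(mid_times(sch) >= 1800 & mid_times(sch) <= 3600)
  expect_equal(mid_times(sch)[w], seq(1950, 3450, 300))
  tgt <- tac("t", sch, seq_len(26) * 100, ref$injected_dose)
  expect_equal(compute_suvr(tgt, ref),
               mean(tgt$activity[w]) / mean(ref$activity[w]))
  expect_error(compute_suvr(tgt, ref, quant_window(3400, 3600)),
               "fewer than 2 frames")
  neg <- tac("r", sch, rep(-1, 26), 370)
  expect_error(compute_suvr(tgt, neg), "reference mean")
})

test_that("SUVR and DVR are invariant to common scaling of both TACs", {
  set.seed(81)
  ref <- random_tac(dose = 370)
  tgt <- tac("t", ref$schedule, 1.6 * ref$activity + 50, 370)
  for (c_ in c(0.25, 3)) {
    refs <- tac("r", ref$schedule, c_ * ref$activity, 370)
    tgts <- tac("t", ref$schedule, c_ * tgt$activity, 370)
    expect_equal(compute_suvr(tgts, refs), compute_suvr(tgt, ref),
                 tolerance = 1e-12)
    expect_equal(logan_dvr(tgts, refs), logan_dvr(tgt, ref),
                 tolerance = 1e-10)
  }
})

test_that("Logan slope is exact for proportional curves", {
  set.seed(91)
  ref <- random_tac()
  expect_equal(logan_dvr(ref, ref), 1.0, tolerance = 1e-12)
  dbl <- tac("t", ref$schedule, 2 * ref$activity, ref$injected_dose)
  expect_equal(logan_dvr(dbl, ref), 2.0, tolerance = 1e-12)
})

test_that("Logan DVR recovers 1 + BPND on noise-free SRTM TACs", {
  p <- aif_params()
  tt <- seq(0, 3600, 0.5)
  refc <- reference_curve(tt, p)
  ref <- tac("cerebellar_cortex", pib_schedule(),
             frame_average(tt, refc, pib_schedule()), 370)
  for (bp in c(0.2, 0.5, 1.0)) {
    tgt <- srtm_tac(tt, refc, region_kinetics(1, 0.15, bp))
    expect_lt(abs(logan_dvr(tgt, ref) / (1 + bp) - 1), 0.05)
  }
})

test_that("Logan matches an independent fine-grid OLS oracle", {
  p <- aif_params()
  tt <- seq(0, 3600, 0.5)
  refc <- reference_curve(tt, p)
  sch <- pib_schedule()
  ref <- tac("cerebellar_cortex", sch, frame_average(tt, refc, sch), 370)
  tgt <- srtm_tac(tt, refc, region_kinetics(0.9, 0.9 * 0.15, 0.5))
  # oracle: integrals by dense Riemann sums of the frame-level interpolants
  mids <- mid_times(sch)[mid_times(sch) >= 1800]
  int_t <- vapply(mids, function(m) riemann_integral(tgt, 0, m), 0)
  int_r <- vapply(mids, function(m) riemann_integral(ref, 0, m), 0)
  ct <- interpolate_tac(tgt, mids)
  oracle <- unname(coef(lm(I(int_t / ct) ~ I(int_r / ct)))[2])
  expect_equal(logan_dvr(tgt, ref), oracle, tolerance = 1e-3)
})

test_that("cohort measures and composites are assembled consistently", {
  coh <- simulate_cohort(cohort_config(n_ad = 3, n_hc = 3, seed = 4))
  m <- cohort_measures(coh)
  expect_setequal(unique(m$measure), c("AQI", "SUVR", "DVR"))
  expect_equal(nrow(m), 6 * 5 * 3)   # subjects x target regions x measures
  cmp <- composite_measure(m, "SUVR", c("caudal_anterior_cingulate", "caudate"))
  expect_equal(nrow(cmp), 6)
  one <- m$value[m$subject_id == cmp$subject_id[1] & m$measure == "SUVR" &
                   m$region %in% c("caudal_anterior_cingulate", "caudate")]
  expect_equal(cmp$value[1], mean(one))
  expect_error(composite_measure(m, "SUVR", "not_a_region"), "missing region")
})
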