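test_that("TGK is the diameter-sum slope in mm per month", {
  expect_equal(tgk(50, 60, 0, 2), 5)
  expect_equal(tgk(50, 50, 0, 4), 0)
  expect_equal(tgk(60, 50, 0, 2), -5)  # shrinkage is negative
  expect_error(tgk(50, 60, 2, 2), class = "domain_error")
})

test_that("TGR is the volume-calibrated exponential rate", {
  # 3*ln(60/50)/2 = 0.27349 log-volume/month -> 31.45 %/month
  expect_equal(tgr(50, 60, 0, 2), 31.4534, tolerance = 1e-4)
  expect_equal(tgr(50, 50, 0, 2), 0)
  # diameter doubling over 3 months = volume doubling per month
  expect_equal(tgr(50, 100, 0, 3), 100, tolerance = 1e-9)
  expect_warning(out <- tgr(0, 50, 0, 1), "undefined")
  expect_true(is.na(out))
})

test_that("TGR/TGK are time-shift invariant and scale-covariant", {
  set.seed(42)
  for (i in 1:25) {
    s0 <- runif(1, 10, 80); s1 <- runif(1, 10, 80)
    t0 <- runif(1, -5, 5); dt <- runif(1, 0.3, 6)
    shift <- runif(1, -10, 10)
    expect_equal(tgr(s0, s1, t0, t0 + dt),
                 tgr(s0, s1, t0 + shift, t0 + shift + dt))
    expect_equal(tgk(s0, s1, t0, t0 + dt),
                 tgk(s0, s1, t0 + shift, t0 + shift + dt))
    # doubling both diameters: TGR unchanged, TGK doubled
    expect_equal(tgr(2 * s0, 2 * s1, t0, t0 + dt), tgr(s0, s1, t0, t0 + dt))
    expect_equal(tgk(2 * s0, 2 * s1, t0, t0 + dt),
                 2 * tgk(s0, s1, t0, t0 + dt))
    # signs of TGK, TGR and the diameter change agree
    expect_equal(sign(tgk(s0, s1, t0, t0 + dt)), sign(s1 - s0))
    expect_equal(sign(tgr(s0, s1, t0, t0 + dt)), sign(s1 - s0))
  }
})

test_that("growth ratios are on/pre folds, undefined for nonpositive pre", {
  # pre TGK = 2 mm/mo, on TGK = 15.82 mm/mo -> fold 7.91
  gr <- growth_ratios(pre = list(s_start = 48, s_end = 50,
                                 t_start = -1, t_end = 0),
                      on = list(s_start = 50, s_end = 50 + 15.82 * 2,
                                t_start = 0, t_end = 2))
  expect_equal(gr$tgk_ratio, 7.91, tolerance = 1e-9)
  # pre TGR = 10 %/mo, on TGR = 62 %/mo -> fold 6.2
  gr2 <- growth_ratios(
    pre = list(s_start = 50, s_end = 50 * 1.10^(1 / 3),
               t_start = -1, t_end = 0),
    on = list(s_start = 50, s_end = 50 * 1.62^(1 / 3),
              t_start = 0, t_end = 1))
  expect_equal(gr2$tgr_ratio, 6.2, tolerance = 1e-9)
  # identical windows give fold 1
  w <- list(s_start = 40, s_end = 52, t_start = 0, t_end = 2)
  gr3 <- growth_ratios(pre = w, on = w)
  expect_equal(gr3$tgk_ratio, 1)
  expect_equal(gr3$tgr_ratio, 1)
  # shrinking pre-treatment tumor: folds undefined with a reason code
  gr4 <- growth_ratios(pre = list(s_start = 50, s_end = 45,
                                  t_start = -2, t_end = 0),
                       on = w)
  expect_true(is.na(gr4$tgk_ratio) && is.na(gr4$tgr_ratio))
  expect_match(gr4$reason, "nonpositive pre-treatment")
})

test_that("tumor-burden increase is percent change over baseline", {
  expect_equal(tumor_burden_increase(50, 76.75), 53.5)
  expect_equal(tumor_burden_increase(50, 50), 0)
  expect_equal(tumor_burden_increase(50, 339.76), 579.52)
  expect_error(tumor_burden_increase(0, 10), class = "domain_error")
})

test_that("time to treatment failure is the interval from therapy start", {
  expect_equal(ttf(0, 1.6), 1.6)
  expect_equal(ttf(0, 1.3), 1.3)
  expect_error(ttf(2, 1), class = "domain_error")
})

test_that("the two-criterion HPD rule reproduces the case series", {
  cs <- read_case_series()
  out <- classify_hpd(cs$line, cs$ttf_months, cs$tbi_pct,
                      cs$tgk_ratio, cs$tgr_ratio)
  expect_equal(as.character(out$hpd), c("yes", "yes", "no", "no", "yes"))
})

test_that("HPD thresholds are inclusive except the strict TTF cutoff", {
  expect_equal(as.character(
    classify_hpd("first", 1.9, tbi_pct = 50)$hpd), "yes")
  expect_equal(as.character(
    classify_hpd("second", 1.9, tgk_ratio = 2, tgr_ratio = 2)$hpd), "yes")
  # TTF exactly at the cutoff fails criterion (1)
  expect_equal(as.character(
    classify_hpd("first", 2.0, tbi_pct = 300)$hpd), "no")
  # no treatment failure at all is never HPD
  expect_equal(as.character(
    classify_hpd("first", NA, tbi_pct = 300)$hpd), "no")
})

test_that("missing criterion inputs give not-evaluable, never silent no", {
  ne <- classify_hpd("second", 1.5, tbi_pct = 80)
  expect_true(is.na(ne$hpd))
  ne2 <- classify_hpd("first", 1.5)
  expect_true(is.na(ne2$hpd))
})

test_that("HPD classification is monotone in TBI and in the folds", {
  set.seed(7)
  for (i in 1:20) {
    tbi <- runif(1, 0, 120)
    base <- classify_hpd("first", 1.5, tbi_pct = tbi)$hpd
    more <- classify_hpd("first", 1.5, tbi_pct = tbi + runif(1, 0, 200))$hpd
    expect_false(base == "yes" && more == "no")
    rk <- runif(1, 0, 5); rr <- runif(1, 0, 5)
    b2 <- classify_hpd("second", 1.5, tgk_ratio = rk, tgr_ratio = rr)$hpd
    m2 <- classify_hpd("second", 1.5, tgk_ratio = rk + runif(1, 0, 4),
                       tgr_ratio = rr + runif(1, 0, 4))$hpd
    expect_false(b2 == "yes" && m2 == "no")
  }
})

test_that("assess_hpd derives TTF, TBI and folds from assessments", {
  # second-line patient: pre-baseline growth, then fast on-treatment growth
  les <- one_lesion_series(times = c(-1.5, 0, 1.4),
                           diameters = c(45, 50, 80))
  rec <- recist_outcomes(les)
  patients <- tibble::tibble(patient_id = "P1", line = "second")
  out <- assess_hpd(rec$assessments, patients)
  expect_equal(out$ttf_months, 1.4)
  expect_equal(out$tbi_pct, 100 * 30 / 50)
  k_pre <- (50 - 45) / 1.5
  k_on <- (80 - 50) / 1.4
  expect_equal(out$tgk_ratio, k_on / k_pre)
  expect_equal(as.character(out$hpd), "yes")
  # same trajectory in first line trips the TBI criterion instead
  out2 <- assess_hpd(rec$assessments,
                     tibble::tibble(patient_id = "P1", line = "first"))
  expect_equal(as.character(out2$hpd), "yes")
  expect_match(out2$criterion_used, "TBI")
})
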