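test_that("target selection keeps the largest lesions, capped per organ", {
  les <- dplyr::bind_rows(
    lesion_rows("P1", c("a", "b", "c"), 0, c(30, 25, 20), organ = "liver"),
    lesion_rows("P1", "d", 0, 28, organ = "lung"),
    lesion_rows("P1", "e", 0, 22, organ = "bone"),
    lesion_rows("P1", "f", 0, 18, organ = "adrenal"),
    lesion_rows("P1", "g", 0, 15, organ = "node"))
  sel <- select_target_lesions(les)
  # two largest liver lesions plus the three largest elsewhere
  expect_setequal(sel$lesion_id, c("a", "b", "d", "e", "f"))
})

test_that("six lesions in one organ yield only the two largest", {
  les <- lesion_rows("P1", letters[1:6], 0, c(40, 35, 30, 25, 20, 15))
  sel <- select_target_lesions(les)
  expect_setequal(sel$lesion_id, c("a", "b"))
})

test_that("a single lesion is its own target; ties break by lesion id", {
  expect_equal(select_target_lesions(lesion_rows("P1", "only", 0,
                                                 12))$lesion_id, "only")
  tie <- lesion_rows("P1", c("z", "a", "m"), 0, c(30, 30, 30))
  expect_setequal(select_target_lesions(tie)$lesion_id, c("a", "m"))
  expect_error(select_target_lesions(lesion_rows("P1", "x", 2, 10)),
               class = "evaluability_error")
})

test_that("burden series sums targets and flags missing reads as NE", {
  les <- dplyr::bind_rows(
    lesion_rows("P1", "a", c(0, 1, 2), c(30, 32, 35)),
    lesion_rows("P1", "b", c(0, 1), c(20, 21), organ = "lung"))
  s <- tumor_burden_series(les)
  expect_equal(s$s_mm[s$time_months == 0], 50)
  expect_equal(s$s_mm[s$time_months == 1], 53)
  expect_true(is.na(s$s_mm[s$time_months == 2]))  # lesion b unmeasured
  expect_equal(s$n_measured[s$time_months == 2], 1)
})

test_that("timepoint categories follow the RECIST 1.1 thresholds", {
  # -32% from baseline -> PR
  a1 <- recist_assessments(tumor_burden_series(
    one_lesion_series(c(0, 1), c(50, 34))))
  expect_equal(as.character(a1$response[a1$time_months == 1]), "PR")
  # +23.3% and +7 mm over the nadir of 30 -> PD
  a2 <- recist_assessments(tumor_burden_series(
    one_lesion_series(c(0, 1, 2), c(50, 30, 37))))
  expect_equal(as.character(a2$response[a2$time_months == 2]), "PD")
  # 20% up but under 5 mm absolute: small tumors stay SD
  a3 <- recist_assessments(tumor_burden_series(
    one_lesion_series(c(0, 1), c(10, 13))))
  expect_equal(as.character(a3$response[a3$time_months == 1]), "SD")
  # a new lesion forces PD regardless of burden
  a4 <- recist_assessments(tumor_burden_series(
    one_lesion_series(c(0, 1), c(50, 40), new_lesion_at = 1)))
  expect_equal(as.character(a4$response[a4$time_months == 1]), "PD")
  # complete disappearance -> CR
  a5 <- recist_assessments(tumor_burden_series(
    one_lesion_series(c(0, 1), c(50, 0))))
  expect_equal(as.character(a5$response[a5$time_months == 1]), "CR")
})

test_that("best overall response ranks CR > PR > SD > PD, NE ignored", {
  expect_equal(as.character(best_overall_response(c("SD", "PR", "PD"))),
               "PR")
  expect_equal(as.character(best_overall_response("PD")), "PD")
  expect_equal(as.character(best_overall_response(c("NE", "NE"))), "NE")
  expect_equal(as.character(best_overall_response(character())), "NE")
  expect_equal(as.character(best_overall_response(c("NE", "SD"))), "SD")
})

test_that("PFS is first progression or death, else censoring", {
  a_pd <- tibble::tibble(time_months = c(1.5, 3),
                         response = factor(c("PD", "PD")))
  expect_equal(derive_pfs(a_pd, NA, 16), list(pfs_months = 1.5,
                                              pfs_event = TRUE))
  a_sd <- tibble::tibble(time_months = 2, response = factor("SD"))
  expect_equal(derive_pfs(a_sd, 4.0, 16), list(pfs_months = 4.0,
                                               pfs_event = TRUE))
  expect_equal(derive_pfs(a_sd, NA, 16.0), list(pfs_months = 16.0,
                                                pfs_event = FALSE))
  expect_error(derive_pfs(a_sd, NA, 0), class = "domain_error")
})

test_that("primary resistance: initial PD, or PD after SD under 6 months", {
  pd_first <- tibble::tibble(time_months = 1.3, response = factor("PD"))
  expect_true(classify_primary_resistance(pd_first))
  sd_then_pd <- function(t_pd) tibble::tibble(
    time_months = c(1.5, t_pd), response = factor(c("SD", "PD")))
  expect_true(classify_primary_resistance(sd_then_pd(5.0)))
  expect_false(classify_primary_resistance(sd_then_pd(8.0)))
  # progression after a response is not primary resistance
  pr_then_pd <- tibble::tibble(time_months = c(1.5, 4),
                               response = factor(c("PR", "PD")))
  expect_false(classify_primary_resistance(pr_then_pd))
})

test_that("raising a post-nadir burden never improves a PD call", {
  set.seed(11)
  for (i in 1:15) {
    s <- c(50, round(runif(4, 25, 75)))
    t <- 0:4
    a <- recist_assessments(tumor_burden_series(one_lesion_series(t, s)))
    pd_at <- a$time_months[!is.na(a$response) & a$response == "PD"]
    if (length(pd_at) == 0) next
    j <- min(pd_at)
    s2 <- s
    s2[t == j] <- s2[t == j] + 10
    a2 <- recist_assessments(tumor_burden_series(one_lesion_series(t, s2)))
    expect_equal(as.character(a2$response[a2$time_months == j]), "PD")
  }
})

test_that("outcomes are invariant to lesion-row permutation", {
  coh <- simulate_cohort(cohort_config(n_patients = 12, seed = 21))
  out1 <- recist_outcomes(coh$lesions, coh$patients)$outcomes
  set.seed(1)
  shuffled <- coh$lesions[sample(nrow(coh$lesions)), ]
  out2 <- recist_outcomes(shuffled, coh$patients)$outcomes
  expect_equal(dplyr::arrange(out1, patient_id),
               dplyr::arrange(out2, patient_id))
})

test_that("monotone shrinkage beyond -30% always gives BOR of PR or CR", {
  times <- seq(0, 8, by = 1.5)
  for (g in c(-0.45, -0.8, -1.2)) {
    les <- purrr::map_dfr(1:5, function(i) {
      ser <- simulate_lesion_series(30 + 5 * i, g, times, rounding_mm = 0)
      lesion_rows(paste0("P", i), "L1", ser$time_months, ser$diameter_mm)
    })
    bor <- recist_outcomes(les)$outcomes$bor
    expect_true(all(as.character(bor) %in% c("PR", "CR")))
  }
})

test_that("NE assessments are skipped for nadir and BOR without ending
           evaluation", {
  les <- dplyr::bind_rows(
    lesion_rows("P1", "a", c(0, 1, 2, 3), c(30, 28, NA, 40)),
    lesion_rows("P1", "b", c(0, 1, 2, 3), c(20, 20, 21, 22),
                organ = "lung"))
  les <- les[!is.na(les$longest_diameter_mm), ]
  a <- recist_assessments(tumor_burden_series(les))
  expect_equal(as.character(a$response[a$time_months == 2]), "NE")
  # nadir is 48 from t=1, so 62 at t=3 is +29% and +14 mm -> PD
  expect_equal(as.character(a$response[a$time_months == 3]), "PD")
  expect_equal(as.character(best_overall_response(a$response)), "SD")
})
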