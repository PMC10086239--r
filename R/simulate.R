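#' Simulate one lesion's longest-diameter series
#'
#' Diameters follow volume-exponential growth: the longest diameter at time
#' `t` is `baseline_mm * exp(g * t / 3)`, so that lesion volume (proportional
#' to the cubed diameter) grows at log-rate `g` per month. Measurements are
#' then rounded to the acquisition grid, emulating radiology reads.
#'
#' @param baseline_mm Longest diameter at time 0, mm; must be positive.
#' @param g Log-volume growth rate per month (negative = shrinkage).
#' @param times Numeric vector of measurement times in months (negative =
#'   before therapy start); must be nondecreasing.
#' @param rounding_mm Round diameters to this grid; 0 disables rounding.
#' @return A tibble with columns `time_months` and `diameter_mm`.
#' @export
#' @examples
#' # volume doubling every month: diameter doubles by month 3
#' simulate_lesion_series(50, log(2), times = c(0, 3), rounding_mm = 0)
simulate_lesion_series <- function(baseline_mm, g, times, rounding_mm = 0) {
  if (!is.numeric(baseline_mm) || length(baseline_mm) != 1 || baseline_mm <= 0)
    abort("`baseline_mm` must be a single positive diameter",
          class = "domain_error")
  if (is.unsorted(times))
    abort("`times` must be nondecreasing", class = "domain_error")
  d <- baseline_mm * exp(g * times / 3)
  if (rounding_mm > 0) d <- round(d / rounding_mm) * rounding_mm
  tibble::tibble(time_months = as.numeric(times), diameter_mm = d)
}

#' Simulate a synthetic immunotherapy cohort
#'
#' Generates a patient table, a long-format lesion-measurement table, a
#' gene-level alteration table and a ground-truth sidecar with the
#' statistical structure the downstream analysis assumes: Bernoulli 11q13
#' amplification status, two treatment arms (PD-1 antibody first/second line
#' versus other systemic therapy), exponential progression-free survival with
#' per-stratum medians, independent exponential right-censoring, and
#' volume-exponential lesion trajectories sampled on a fixed scan schedule
#' with rounded reads.
#'
#' Patients who progress are given an on-treatment growth rate calibrated so
#' their target-lesion diameter sum crosses the RECIST progression threshold
#' (the larger of +20% and +5 mm over baseline) at the drawn progression
#' time, keeping the radiological and survival layers consistent.
#' 11q13-amplified patients on the PD-1 antibody arm are assigned
#' hyperprogressive growth (a high fixed rate from
#' `config$growth_rates$hyperprogressor`) with probability
#' `config$hpd_probability`; those whose progression is observed constitute
#' the intended-HPD ground truth. Censored patients receive stable or
#' shrinking trajectories.
#'
#' @param config A [cohort_config()] object.
#' @return A `synthetic_cohort` list with tibbles `patients`, `lesions`,
#'   `alterations`, `truth`, and the `config` used. Identical seeds give
#'   byte-identical tables.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 8, seed = 42))
#' coh$patients
simulate_cohort <- function(config = cohort_config()) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_patients
  if (n == 0) {
    return(structure(list(patients = empty_patients(),
                          lesions = empty_lesions(),
                          alterations = empty_alterations(),
                          truth = empty_truth(),
                          config = cfg),
                     class = "synthetic_cohort"))
  }
  ids <- sprintf("P%03d", seq_len(n))
  delta <- cfg$assessment_interval_months
  fu <- cfg$max_followup_months

  amp <- runif(n) < cfg$amp_prevalence
  arm_line <- sample(names(cfg$arm_fractions), n, replace = TRUE,
                     prob = cfg$arm_fractions)
  arm <- ifelse(arm_line == "nonPD1Ab", "nonPD1Ab", "PD1Ab")
  line <- ifelse(arm_line == "PD1Ab_line2", "second", "first")

  med <- purrr::map2_dbl(arm, amp, function(a, g) {
    m <- cfg$median_pfs_months
    m$median_months[m$arm == a & m$amp11q13 == g][1]
  })
  rate <- log(2) / med
  t_event <- rexp(n, rate)
  t_censor <- if (cfg$censoring_rate > 0) {
    rexp(n, rate * cfg$censoring_rate / (1 - cfg$censoring_rate))
  } else rep(Inf, n)
  pfs <- pmin(t_event, t_censor, fu)
  event <- t_event <= pmin(t_censor, fu)

  hpd_candidate <- amp & arm == "PD1Ab" & runif(n) < cfg$hpd_probability
  status <- ifelse(event,
                   ifelse(hpd_candidate, "hyperprogressor", "progressor"),
                   sample(c("responder", "stable"), n, replace = TRUE,
                          prob = c(0.4, 0.6)))
  intended_hpd <- event & hpd_candidate

  # clinical covariates, amplification-dependent where the cohort structure
  # calls for it (PVTT and DCP enrichment in amplified patients)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.84, 0.16))
  age_group <- ifelse(runif(n) < ifelse(amp, 0.80, 0.62), "<=60", ">60")
  pvtt <- ifelse(runif(n) < ifelse(amp, 0.53, 0.11), "yes", "no")
  dcp_group <- purrr::map_chr(amp, function(a) {
    p <- if (a) c(0.87, 0.13, 0.00) else c(0.47, 0.32, 0.21)
    sample(c(">=200", "<200", "NA"), 1, prob = p)
  })
  dcp_group[dcp_group == "NA"] <- NA_character_

  per_patient <- purrr::pmap(
    list(ids, amp, arm, line, t_event, pfs, event, status),
    function(id, a, rx, ln, tev, pobs, ev, st) {
      n_les <- sample(seq(cfg$n_target_lesions_range[1],
                          cfg$n_target_lesions_range[2]), 1)
      d0 <- runif(n_les, cfg$baseline_diameter_mm_range[1],
                  cfg$baseline_diameter_mm_range[2])
      s0 <- sum(d0)
      g_pre <- cfg$growth_rates$pre
      g_on <- switch(st,
        responder = cfg$growth_rates$responder,
        stable = cfg$growth_rates$stable,
        hyperprogressor = cfg$growth_rates$hyperprogressor,
        progressor = 3 * log(max(1.2, (s0 + 5) / s0)) / tev)
      # scan schedule: one pre-baseline scan, baseline at therapy start,
      # then every `delta` months; progressors stop at the failure scan,
      # censored patients at the last scan before censoring
      k_max <- if (ev) max(1, ceiling(pobs / delta)) else floor(pobs / delta)
      times <- c(-delta, delta * seq(0, k_max))
      organs <- rep(c("liver", "liver", "lung", "lung", "peritoneum"),
                    length.out = n_les)
      les <- purrr::imap_dfr(d0, function(d, j) {
        ser <- simulate_lesion_series(d, g_on, times[times >= 0],
                                      cfg$measurement_rounding_mm)
        pre <- simulate_lesion_series(d, g_pre, times[times < 0],
                                      cfg$measurement_rounding_mm)
        dplyr::bind_rows(pre, ser) |>
          dplyr::mutate(patient_id = id,
                        lesion_id = sprintf("L%02d", j),
                        organ = organs[j],
                        is_new = FALSE)
      })
      if (ev && runif(1) < 1 - exp(-cfg$new_lesion_hazard * pobs)) {
        les <- dplyr::bind_rows(les, tibble::tibble(
          time_months = max(times), diameter_mm = round(runif(1, 8, 20)),
          patient_id = id, lesion_id = "NEW1", organ = "liver",
          is_new = TRUE))
      }
      alt <- tibble::tibble(patient_id = character(), gene = character(),
                            alteration = character())
      if (a) {
        pick <- runif(4) < c(0.9, 0.8, 0.6, 0.6)
        if (!any(pick)) pick[1] <- TRUE
        alt <- tibble::tibble(
          patient_id = id,
          gene = c("CCND1", "FGF19", "FGF3", "FGF4")[pick],
          alteration = "amplification")
      }
      if (runif(1) < 0.55)
        alt <- dplyr::bind_rows(alt, tibble::tibble(
          patient_id = id, gene = "TP53", alteration = "missense"))
      if (runif(1) < 0.40)
        alt <- dplyr::bind_rows(alt, tibble::tibble(
          patient_id = id, gene = "TERT", alteration = "promoter_mutation"))
      list(lesions = les, alterations = alt,
           truth = tibble::tibble(patient_id = id, responder_status = st,
                                  g_pre = g_pre, g_on = g_on,
                                  true_pfs_months = tev,
                                  censor_months = pobs,
                                  intended_hpd = ev && st == "hyperprogressor"))
    })

  lesions <- purrr::map_dfr(per_patient, "lesions") |>
    dplyr::select("patient_id", "lesion_id", "organ", "is_new",
                  "time_months", "diameter_mm") |>
    dplyr::rename(longest_diameter_mm = "diameter_mm")
  patients <- tibble::tibble(
    patient_id = ids, amp11q13 = amp, arm = arm, line = line,
    pfs_months = pfs, pfs_event = event,
    death_months = NA_real_, last_followup_months = pfs,
    sex = sex, age_group = age_group, pvtt = pvtt, dcp_group = dcp_group)
  structure(list(patients = patients,
                 lesions = lesions,
                 alterations = purrr::map_dfr(per_patient, "alterations"),
                 truth = purrr::map_dfr(per_patient, "truth"),
                 config = cfg),
            class = "synthetic_cohort")
}

empty_patients <- function() {
  tibble::tibble(patient_id = character(), amp11q13 = logical(),
                 arm = character(), line = character(),
                 pfs_months = numeric(), pfs_event = logical(),
                 death_months = numeric(), last_followup_months = numeric(),
                 sex = character(), age_group = character(),
                 pvtt = character(), dcp_group = character())
}
empty_lesions <- function() {
  tibble::tibble(patient_id = character(), lesion_id = character(),
                 organ = character(), is_new = logical(),
                 time_months = numeric(), longest_diameter_mm = numeric())
}
empty_alterations <- function() {
  tibble::tibble(patient_id = character(), gene = character(),
                 alteration = character())
}
empty_truth <- function() {
  tibble::tibble(patient_id = character(), responder_status = character(),
                 g_pre = numeric(), g_on = numeric(),
                 true_pfs_months = numeric(), censor_months = numeric(),
                 intended_hpd = logical())
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d lesion measurements, %d alterations\n",
    nrow(x$patients), nrow(x$lesions), nrow(x$alterations)))
  cat(sprintf("  Amp11q13: %d (%.1f%%); arms: %s\n",
              sum(x$patients$amp11q13),
              100 * mean(x$patients$amp11q13),
              paste(names(table(x$patients$arm)),
                    table(x$patients$arm), sep = "=", collapse = ", ")))
  invisible(x)
}
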