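#' Months per day conversion constant
#'
#' All times in this package are expressed in months. Day-denominated
#' intervals are converted with the mean Gregorian month length,
#' 30.4375 days.
#'
#' @return Number of days in one month (30.4375).
#' @export
days_per_month <- function() 30.4375

#' Simulation configuration for a synthetic immunotherapy cohort
#'
#' Builds the parameter set consumed by [simulate_cohort()]. Defaults emulate
#' a hepatocellular-carcinoma immunotherapy cohort: ~24.2% prevalence of
#' chromosome 11q13 amplification, a PD-1 antibody arm of 20 patients
#' (15 first line, 5 second line) versus 13 patients on other systemic
#' therapy, exponential progression-free survival with stratum medians of
#' 1.5 / 16.2 / 7.0 / 16.0 months, radiological assessment every 6 weeks,
#' and whole-millimetre diameter reads.
#'
#' @param n_patients Number of patients to simulate.
#' @param amp_prevalence Probability that a patient carries the 11q13
#'   amplification (CCND1/FGF3/FGF4/FGF19).
#' @param arm_fractions Named probabilities over `PD1Ab_line1`, `PD1Ab_line2`
#'   and `nonPD1Ab`; must sum to 1.
#' @param median_pfs_months Tibble with columns `arm`, `amp11q13`,
#'   `median_months`: the exponential PFS median for each (arm, genotype)
#'   stratum, in months.
#' @param growth_rates Named list of on-treatment log-volume growth rates per
#'   month by responder status (`responder`, `stable`, `hyperprogressor`),
#'   plus `pre`, the pre-treatment rate shared by all patients. Ordinary
#'   progressors get a rate calibrated to their drawn progression time (see
#'   [simulate_cohort()]).
#' @param hpd_probability Probability that an 11q13-amplified patient on the
#'   PD-1 antibody arm is assigned hyperprogressive on-treatment growth.
#' @param n_target_lesions_range Integer range (within 1..5) for the number
#'   of measurable lesions per patient.
#' @param baseline_diameter_mm_range Range of baseline longest diameters, mm.
#' @param assessment_interval_months Scan cadence in months; the default is
#'   6 weeks (42 / 30.4375 months).
#' @param max_followup_months Administrative end of follow-up, months.
#' @param measurement_rounding_mm Diameters are rounded to this grid
#'   (0 disables rounding).
#' @param censoring_rate Target fraction of patients censored before
#'   progression (independent exponential censoring).
#' @param new_lesion_hazard Per-month hazard of a new lesion appearing at the
#'   progression scan of a progressing patient.
#' @param seed Integer seed giving byte-identical cohorts.
#'
#' @return A `cohort_config` list, validated.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 10, seed = 1)
#' cfg$amp_prevalence
cohort_config <- function(n_patients = 33,
                          amp_prevalence = 0.242,
                          arm_fractions = c(PD1Ab_line1 = 15 / 33,
                                            PD1Ab_line2 = 5 / 33,
                                            nonPD1Ab = 13 / 33),
                          median_pfs_months = default_median_pfs(),
                          growth_rates = list(pre = 0.25,
                                              responder = -0.5,
                                              stable = 0.01,
                                              hyperprogressor = 1.5),
                          hpd_probability = 0.6,
                          n_target_lesions_range = c(1L, 3L),
                          baseline_diameter_mm_range = c(15, 70),
                          assessment_interval_months = 42 / days_per_month(),
                          max_followup_months = 30,
                          measurement_rounding_mm = 1,
                          censoring_rate = 0.2,
                          new_lesion_hazard = 0.15,
                          seed = 1L) {
  cfg <- structure(
    list(n_patients = n_patients,
         amp_prevalence = amp_prevalence,
         arm_fractions = arm_fractions,
         median_pfs_months = median_pfs_months,
         growth_rates = growth_rates,
         hpd_probability = hpd_probability,
         n_target_lesions_range = as.integer(n_target_lesions_range),
         baseline_diameter_mm_range = baseline_diameter_mm_range,
         assessment_interval_months = assessment_interval_months,
         max_followup_months = max_followup_months,
         measurement_rounding_mm = measurement_rounding_mm,
         censoring_rate = censoring_rate,
         new_lesion_hazard = new_lesion_hazard,
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @export
default_median_pfs <- function() {
  tibble::tibble(
    arm = c("PD1Ab", "PD1Ab", "nonPD1Ab", "nonPD1Ab"),
    amp11q13 = c(TRUE, FALSE, TRUE, FALSE),
    median_months = c(1.5, 16.2, 7.0, 16.0))
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("invalid `%s`: %s", field, why), class = "config_error")
  }
  prob_fields <- c("amp_prevalence", "hpd_probability", "censoring_rate")
  for (f in prob_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      bad(f, "must be a probability in [0, 1]")
  }
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 0)
    bad("n_patients", "must be a nonnegative count")
  af <- cfg$arm_fractions
  if (!setequal(names(af), c("PD1Ab_line1", "PD1Ab_line2", "nonPD1Ab")))
    bad("arm_fractions", "must be named PD1Ab_line1, PD1Ab_line2, nonPD1Ab")
  if (any(af < 0) || abs(sum(af) - 1) > 1e-8)
    bad("arm_fractions", "must be nonnegative and sum to 1")
  r <- cfg$n_target_lesions_range
  if (length(r) != 2 || r[1] < 1L || r[2] > 5L || r[1] > r[2])
    bad("n_target_lesions_range", "must be an integer interval within [1, 5]")
  if (cfg$assessment_interval_months <= 0)
    bad("assessment_interval_months", "must be > 0")
  mp <- cfg$median_pfs_months
  if (!all(c("arm", "amp11q13", "median_months") %in% names(mp)))
    bad("median_pfs_months", "needs columns arm, amp11q13, median_months")
  if (any(mp$median_months <= 0))
    bad("median_pfs_months", "medians must be > 0")
  if (cfg$measurement_rounding_mm < 0)
    bad("measurement_rounding_mm", "must be >= 0")
  if (diff(cfg$baseline_diameter_mm_range) < 0 ||
      cfg$baseline_diameter_mm_range[1] <= 0)
    bad("baseline_diameter_mm_range", "must be a positive interval")
  if (cfg$new_lesion_hazard < 0)
    bad("new_lesion_hazard", "must be >= 0")
  cfg
}

#' HPD decision thresholds
#'
#' The two-criterion hyperprogression rule: time to treatment failure
#' strictly under `ttf_cutoff` months, plus a tumor-burden increase of at
#' least `tbi_cutoff` percent (first-line patients) or at least
#' `ratio_cutoff`-fold increases in both TGK and TGR (second-line patients).
#' TBI and fold thresholds are inclusive; the TTF cutoff is strict.
#'
#' @param ttf_cutoff Months; treatment failure must occur strictly earlier.
#' @param tbi_cutoff Percent increase in the target-lesion diameter sum.
#' @param ratio_cutoff Fold change required of both TGK and TGR ratios.
#' @return A named list of thresholds.
#' @export
hpd_thresholds <- function(ttf_cutoff = 2, tbi_cutoff = 50, ratio_cutoff = 2) {
  stopifnot(ttf_cutoff > 0, tbi_cutoff > 0, ratio_cutoff > 0)
  list(ttf_cutoff = ttf_cutoff, tbi_cutoff = tbi_cutoff,
       ratio_cutoff = ratio_cutoff)
}
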