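#' Tumor growth kinetics (TGK)
#'
#' TGK is the change in the sum of the longest diameters of the target
#' lesions per month: `(s_end - s_start) / (t_end - t_start)`. Shrinkage is
#' negative.
#'
#' @param s_start,s_end Diameter sums (mm) at the window bounds.
#' @param t_start,t_end Window bounds in months; `t_end` must exceed
#'   `t_start`.
#' @return mm per month; vectorized.
#' @export
#' @examples
#' tgk(50, 60, 0, 2)  # 5 mm/month
tgk <- function(s_start, s_end, t_start, t_end) {
  if (any(t_end <= t_start))
    abort("`t_end` must be strictly after `t_start`", class = "domain_error")
  (s_end - s_start) / (t_end - t_start)
}

#' Tumor growth rate (TGR)
#'
#' TGR is the volume-calibrated exponential growth rate of the target-lesion
#' burden, expressed as percent volume increase per month. With tumor volume
#' proportional to the cubed diameter, the log-volume rate over a window is
#' `TG = 3 * log(s_end / s_start) / (t_end - t_start)` and
#' `TGR = 100 * (exp(TG) - 1)`. TGR is 0 exactly when the burden is
#' unchanged, negative for shrinkage.
#'
#' Nonpositive diameter sums leave TGR undefined (log scale); these return
#' `NA` with a warning rather than erroring, so batch processing can carry
#' explicit not-evaluable results.
#'
#' @inheritParams tgk
#' @return Percent per month; vectorized, `NA` where undefined.
#' @export
#' @examples
#' tgr(50, 60, 0, 2)   # 31.45 %/month
#' tgr(50, 100, 0, 3)  # volume doubling per month: 100 %/month
tgr <- function(s_start, s_end, t_start, t_end) {
  if (any(t_end <= t_start))
    abort("`t_end` must be strictly after `t_start`", class = "domain_error")
  undefined <- s_start <= 0 | s_end <= 0
  if (any(undefined))
    warn("TGR undefined for nonpositive diameter sums; returning NA")
  tg <- ifelse(undefined, NA_real_,
               3 * log(s_end / s_start) / (t_end - t_start))
  100 * (exp(tg) - 1)
}

#' Pre/on-treatment fold changes of TGK and TGR
#'
#' Fold change = on-treatment value / pre-treatment value, computed by
#' [tgk()] and [tgr()] on the two windows. Folds are defined only when the
#' pre-treatment quantity is positive: a shrinking or stable tumor before
#' therapy yields `NA` with a reason code, never a silent number.
#'
#' @param pre,on Lists/rows with fields `s_start`, `s_end`, `t_start`,
#'   `t_end` describing the pre-treatment and on-treatment windows.
#' @return A tibble with `tgk_pre`, `tgk_on`, `tgr_pre`, `tgr_on`,
#'   `tgk_ratio`, `tgr_ratio`, and `reason` (NA when both folds defined).
#' @export
growth_ratios <- function(pre, on) {
  k_pre <- tgk(pre$s_start, pre$s_end, pre$t_start, pre$t_end)
  k_on <- tgk(on$s_start, on$s_end, on$t_start, on$t_end)
  r_pre <- suppressWarnings(tgr(pre$s_start, pre$s_end, pre$t_start,
                                pre$t_end))
  r_on <- suppressWarnings(tgr(on$s_start, on$s_end, on$t_start, on$t_end))
  ok_k <- !is.na(k_pre) & k_pre > 0
  ok_r <- !is.na(r_pre) & r_pre > 0
  tibble::tibble(
    tgk_pre = k_pre, tgk_on = k_on, tgr_pre = r_pre, tgr_on = r_on,
    tgk_ratio = ifelse(ok_k, k_on / k_pre, NA_real_),
    tgr_ratio = ifelse(ok_r, r_on / r_pre, NA_real_),
    reason = dplyr::case_when(
      !ok_k & !ok_r ~ "nonpositive pre-treatment TGK and TGR",
      !ok_k ~ "nonpositive pre-treatment TGK",
      !ok_r ~ "nonpositive pre-treatment TGR",
      TRUE ~ NA_character_))
}

#' Tumor-burden increase (TBI)
#'
#' Percent increase of the target-lesion diameter sum over the treatment
#' baseline: `100 * (s_post - s_baseline) / s_baseline`.
#'
#' @param s_baseline Baseline diameter sum, mm; must be positive.
#' @param s_post Post-treatment diameter sum, mm.
#' @return Percent; vectorized.
#' @export
#' @examples
#' tumor_burden_increase(50, 76.75)  # 53.5%
tumor_burden_increase <- function(s_baseline, s_post) {
  if (any(s_baseline <= 0))
    abort("`s_baseline` must be positive", class = "domain_error")
  100 * (s_post - s_baseline) / s_baseline
}

#' Time to treatment failure
#'
#' @param therapy_start_months,failure_months Times in months; failure must
#'   follow the therapy start.
#' @return Months from therapy start to treatment failure.
#' @export
ttf <- function(therapy_start_months, failure_months) {
  out <- failure_months - therapy_start_months
  if (any(out <= 0, na.rm = TRUE))
    abort("treatment failure must occur after therapy start",
          class = "domain_error")
  out
}

#' Two-criterion hyperprogressive-disease classification
#'
#' A patient is hyperprogressive iff (1) time to treatment failure is
#' strictly under `thresholds$ttf_cutoff` months, and (2) for first-line
#' treatment the tumor-burden increase is at least `thresholds$tbi_cutoff`
#' percent, or for second-line treatment both the TGK and TGR fold changes
#' are at least `thresholds$ratio_cutoff`. TBI and fold thresholds are
#' inclusive; the TTF cutoff is strict. When TTF is under the cutoff but the
#' quantity the line-specific criterion needs is missing, the result is
#' not-evaluable (`NA`), never silently negative. A patient whose treatment
#' never failed (`ttf_months` `NA`) is not hyperprogressive.
#'
#' @param line `"first"` or `"second"` (vectorized).
#' @param ttf_months Time to treatment failure, months (`NA` = no failure).
#' @param tbi_pct Tumor-burden increase, percent (used for first line).
#' @param tgk_ratio,tgr_ratio Fold changes (used for second line).
#' @param thresholds A [hpd_thresholds()] list.
#' @return Tibble with the inputs plus `hpd` (factor yes/no, `NA` =
#'   not-evaluable) and `criterion_used`.
#' @export
#' @examples
#' classify_hpd(line = "second", ttf_months = 1.8, tbi_pct = 593.667,
#'              tgk_ratio = 7.91, tgr_ratio = 6.2)$hpd  # yes
classify_hpd <- function(line, ttf_months, tbi_pct = NA_real_,
                         tgk_ratio = NA_real_, tgr_ratio = NA_real_,
                         thresholds = hpd_thresholds()) {
  n <- max(lengths(list(line, ttf_months, tbi_pct, tgk_ratio, tgr_ratio)))
  line <- rep_len(as.character(line), n)
  if (!all(line %in% c("first", "second")))
    abort('`line` must be "first" or "second"', class = "domain_error")
  ttf_months <- rep_len(as.numeric(ttf_months), n)
  if (any(ttf_months <= 0, na.rm = TRUE))
    abort("`ttf_months` must be positive", class = "domain_error")
  tbi_pct <- rep_len(as.numeric(tbi_pct), n)
  tgk_ratio <- rep_len(as.numeric(tgk_ratio), n)
  tgr_ratio <- rep_len(as.numeric(tgr_ratio), n)

  fast_failure <- !is.na(ttf_months) & ttf_months < thresholds$ttf_cutoff
  first_ok <- tbi_pct >= thresholds$tbi_cutoff
  second_ok <- tgk_ratio >= thresholds$ratio_cutoff &
    tgr_ratio >= thresholds$ratio_cutoff
  growth_ok <- ifelse(line == "first", first_ok, second_ok)
  hpd <- dplyr::case_when(
    !fast_failure ~ "no",                 # includes never-failed (NA ttf)
    is.na(growth_ok) ~ NA_character_,     # criterion inputs missing -> NE
    growth_ok ~ "yes",
    TRUE ~ "no")
  tibble::tibble(
    line = line, ttf_months = ttf_months, tbi_pct = tbi_pct,
    tgk_ratio = tgk_ratio, tgr_ratio = tgr_ratio,
    hpd = factor(hpd, levels = c("no", "yes")),
    criterion_used = ifelse(line == "first",
                            "TTF<cutoff & TBI>=cutoff",
                            "TTF<cutoff & TGK,TGR folds>=cutoff"))
}

#' Cohort-level HPD assessment from RECIST assessments
#'
#' For each patient: time to treatment failure = time of the first
#' progression assessment; tumor-burden increase from the treatment baseline
#' to the failure scan; for second-line patients, TGK/TGR fold changes
#' between the pre-treatment window (the two most recent assessments at or
#' before therapy start, i.e. the pre-baseline scan and baseline) and the
#' on-treatment window (baseline to the failure scan). The two-criterion
#' rule of [classify_hpd()] is then applied.
#'
#' @param assessments Per-timepoint tibble from [recist_assessments()] /
#'   [recist_outcomes()].
#' @param patients Patient table with `patient_id` and `line`.
#' @param thresholds A [hpd_thresholds()] list.
#' @return Tibble with one row per patient: `patient_id`, `line`,
#'   `ttf_months`, `tbi_pct`, `tgk_ratio`, `tgr_ratio`, `hpd`,
#'   `criterion_used`.
#' @export
assess_hpd <- function(assessments, patients,
                       thresholds = hpd_thresholds()) {
  if (!all(c("patient_id", "line") %in% names(patients)))
    abort("`patients` must have columns patient_id and line",
          class = "schema_error")
  per <- assessments |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ hpd_inputs_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::left_join(dplyr::select(patients, "patient_id", "line"),
                     by = "patient_id")
  cls <- classify_hpd(per$line, per$ttf_months, per$tbi_pct,
                      per$tgk_ratio, per$tgr_ratio, thresholds)
  dplyr::bind_cols(dplyr::select(per, "patient_id"), cls)
}

hpd_inputs_one <- function(a) {
  a <- dplyr::arrange(a, .data$time_months)
  pre_rows <- a[a$time_months <= 0 & !is.na(a$s_mm), , drop = FALSE]
  base <- pre_rows[nrow(pre_rows), , drop = FALSE]
  pd_times <- a$time_months[!is.na(a$response) & a$response == "PD"]
  if (length(pd_times) == 0 || nrow(base) == 0) {
    return(tibble::tibble(ttf_months = NA_real_, tbi_pct = NA_real_,
                          tgk_ratio = NA_real_, tgr_ratio = NA_real_))
  }
  t_fail <- min(pd_times)
  fail <- a[a$time_months == t_fail, , drop = FALSE]
  tbi <- if (!is.na(fail$s_mm[1]) && base$s_mm[1] > 0) {
    tumor_burden_increase(base$s_mm[1], fail$s_mm[1])
  } else NA_real_
  ratios <- tibble::tibble(tgk_ratio = NA_real_, tgr_ratio = NA_real_)
  if (nrow(pre_rows) >= 2 && !is.na(fail$s_mm[1])) {
    p <- pre_rows[nrow(pre_rows) - 1:0, , drop = FALSE]
    gr <- growth_ratios(
      pre = list(s_start = p$s_mm[1], s_end = p$s_mm[2],
                 t_start = p$time_months[1], t_end = p$time_months[2]),
      on = list(s_start = base$s_mm[1], s_end = fail$s_mm[1],
                t_start = base$time_months[1], t_end = t_fail))
    ratios <- dplyr::select(gr, "tgk_ratio", "tgr_ratio")
  }
  tibble::tibble(ttf_months = t_fail, tbi_pct = tbi,
                 tgk_ratio = ratios$tgk_ratio[1],
                 tgr_ratio = ratios$tgr_ratio[1])
}
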