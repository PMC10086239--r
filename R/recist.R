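#' Select target lesions at baseline
#'
#' RECIST 1.1 target-lesion selection: per patient, up to five lesions and at
#' most two per organ, taken in decreasing order of baseline longest
#' diameter; ties are broken by lexicographic `lesion_id`. The baseline
#' measurement of a lesion is the one at or before therapy start (time 0)
#' closest to 0. Lesions flagged new are never targets.
#'
#' @param lesions Tibble of lesion measurements with columns `patient_id`,
#'   `lesion_id`, `organ`, `is_new`, `time_months`, `longest_diameter_mm`.
#' @param max_lesions,max_per_organ Selection caps (RECIST 1.1: 5 and 2).
#' @return Tibble with columns `patient_id`, `lesion_id`, `organ`,
#'   `baseline_mm`, one row per selected target lesion.
#' @export
select_target_lesions <- function(lesions, max_lesions = 5L,
                                  max_per_organ = 2L) {
  check_lesion_cols(lesions)
  baseline <- lesions |>
    dplyr::filter(!.data$is_new, .data$time_months <= 0) |>
    dplyr::group_by(.data$patient_id, .data$lesion_id) |>
    dplyr::slice_max(.data$time_months, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (nrow(baseline) == 0)
    abort("no baseline (time <= 0) measurement for any lesion",
          class = "evaluability_error")
  baseline |>
    dplyr::arrange(.data$patient_id,
                   dplyr::desc(.data$longest_diameter_mm), .data$lesion_id) |>
    dplyr::group_by(.data$patient_id, .data$organ) |>
    dplyr::mutate(.organ_rank = dplyr::row_number()) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(.data$.organ_rank <= max_per_organ) |>
    dplyr::filter(dplyr::row_number() <= max_lesions) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "lesion_id", "organ",
                  baseline_mm = "longest_diameter_mm")
}

#' Per-timepoint sums of target-lesion longest diameters
#'
#' Computes the tumor burden S (sum of the longest diameters of the target
#' lesions) at every assessment time, per patient. If any target lesion lacks
#' a measurement at a time where others were measured, the sum at that time
#' is not evaluable (`NA`), and `n_measured` records how many targets were
#' read.
#'
#' @inheritParams select_target_lesions
#' @param targets Optional tibble of target lesions (from
#'   [select_target_lesions()]); computed from `lesions` when `NULL`.
#' @return Tibble with `patient_id`, `time_months`, `s_mm` (NA when not
#'   evaluable), `n_measured`, `n_targets`, `new_lesion` (a new lesion has
#'   appeared at or before this time).
#' @export
tumor_burden_series <- function(lesions, targets = NULL) {
  check_lesion_cols(lesions)
  if (is.null(targets)) targets <- select_target_lesions(lesions)
  target_meas <- lesions |>
    dplyr::semi_join(targets, by = c("patient_id", "lesion_id"))
  sums <- target_meas |>
    dplyr::group_by(.data$patient_id, .data$time_months) |>
    dplyr::summarise(s_mm = sum(.data$longest_diameter_mm),
                     n_measured = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(dplyr::count(targets, .data$patient_id,
                                  name = "n_targets"),
                     by = "patient_id") |>
    dplyr::mutate(s_mm = ifelse(.data$n_measured < .data$n_targets,
                                NA_real_, .data$s_mm))
  new_rows <- dplyr::filter(lesions, .data$is_new %in% TRUE)
  first_new <- if (nrow(new_rows) == 0) {
    tibble::tibble(patient_id = character(), first_new = numeric())
  } else {
    new_rows |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_new = min(.data$time_months), .groups = "drop")
  }
  sums |>
    dplyr::left_join(first_new, by = "patient_id") |>
    dplyr::mutate(new_lesion = !is.na(.data$first_new) &
                    .data$time_months >= .data$first_new) |>
    dplyr::select(-"first_new") |>
    dplyr::arrange(.data$patient_id, .data$time_months)
}

#' Classify per-timepoint RECIST 1.1 responses
#'
#' Applies the RECIST 1.1 category rules to each post-baseline assessment:
#' PD if a new lesion is present, or the burden is at least 120% of the nadir
#' with an absolute increase of at least 5 mm; CR if the burden is 0 with no
#' new lesion; PR if the burden is at most 70% of baseline (and not PD);
#' otherwise SD. The nadir is the smallest evaluable burden at or before the
#' assessment, baseline included. Assessments with a non-evaluable burden are
#' classified NE and are skipped when tracking the nadir. The baseline is the
#' assessment at time <= 0 closest to 0; its burden must be positive.
#'
#' @param burden A tibble from [tumor_burden_series()] (or with the same
#'   columns).
#' @param pr_threshold_pct Shrinkage from baseline required for PR
#'   (default -30).
#' @param pd_threshold_pct,pd_threshold_mm Growth over nadir required for PD
#'   (default +20% and +5 mm, both required).
#' @return Tibble with one row per assessment: `patient_id`, `time_months`,
#'   `s_mm`, `pct_change_baseline`, `pct_change_nadir`,
#'   `abs_change_nadir_mm`, `new_lesion`, and `response` (factor with levels
#'   CR, PR, SD, PD, NE; NA for the baseline and pre-baseline rows).
#' @export
recist_assessments <- function(burden, pr_threshold_pct = -30,
                               pd_threshold_pct = 20, pd_threshold_mm = 5) {
  needed <- c("patient_id", "time_months", "s_mm", "new_lesion")
  if (!all(needed %in% names(burden)))
    abort(paste("`burden` must have columns",
                paste(needed, collapse = ", ")), class = "schema_error")
  burden |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ classify_patient_series(
      .x, pr_threshold_pct, pd_threshold_pct, pd_threshold_mm)) |>
    dplyr::ungroup()
}

classify_patient_series <- function(series, pr_pct, pd_pct, pd_mm) {
  series <- dplyr::arrange(series, .data$time_months)
  pre <- which(series$time_months <= 0)
  if (length(pre) == 0)
    abort("patient has no baseline assessment at time <= 0",
          class = "evaluability_error")
  b_idx <- pre[length(pre)]
  s0 <- series$s_mm[b_idx]
  if (is.na(s0) || s0 <= 0)
    abort("baseline tumor burden must be evaluable and positive",
          class = "evaluability_error")
  n <- nrow(series)
  out <- series |>
    dplyr::mutate(pct_change_baseline = NA_real_,
                  pct_change_nadir = NA_real_,
                  abs_change_nadir_mm = NA_real_,
                  response = factor(NA, levels = recist_levels()))
  nadir <- s0
  for (i in seq_len(n)) {
    t <- series$time_months[i]
    if (t <= 0) next           # pre-baseline and baseline rows: no category
    s <- series$s_mm[i]
    new <- isTRUE(series$new_lesion[i])
    if (is.na(s)) {
      out$response[i] <- if (new) "PD" else "NE"
      next
    }
    nadir <- min(nadir, s)
    d_base <- 100 * (s - s0) / s0
    d_nadir <- if (nadir > 0) 100 * (s - nadir) / nadir else Inf
    d_abs <- s - nadir
    pd <- new || (d_nadir >= pd_pct && d_abs >= pd_mm)
    cat_i <- if (pd) "PD"
      else if (s == 0) "CR"
      else if (d_base <= pr_pct) "PR"
      else "SD"
    out$pct_change_baseline[i] <- d_base
    out$pct_change_nadir[i] <- if (is.finite(d_nadir)) d_nadir else NA_real_
    out$abs_change_nadir_mm[i] <- d_abs
    out$response[i] <- cat_i
  }
  out
}

recist_levels <- function() c("CR", "PR", "SD", "PD", "NE")

#' Best overall response across serial assessments
#'
#' Best category in the order CR > PR > SD > PD; assessments classified NE
#' are ignored unless every assessment is NE (then the best overall response
#' is NE). No confirmation scan is required. An empty input is NE.
#'
#' @param responses Character or factor vector of per-timepoint categories.
#' @return A single factor level among CR, PR, SD, PD, NE.
#' @export
#' @examples
#' best_overall_response(c("SD", "PR", "PD"))  # PR
best_overall_response <- function(responses) {
  responses <- as.character(responses)
  responses <- responses[!is.na(responses)]
  informative <- responses[responses != "NE"]
  lv <- factor(recist_levels(), levels = recist_levels())
  if (length(informative) == 0) return(lv[match("NE", recist_levels())])
  lv[min(match(informative, recist_levels()))]
}

#' Derive progression-free survival from assessments
#'
#' PFS is the time from therapy start to the earlier of first radiological
#' progression and death; patients with neither are censored at last
#' follow-up.
#'
#' @param assessments Tibble for one patient from [recist_assessments()]
#'   (columns `time_months`, `response`).
#' @param death_months Death time in months, or `NA`/`NULL` if alive.
#' @param last_followup_months Last follow-up time, months; must be > 0.
#' @return A list with `pfs_months` and `pfs_event`.
#' @export
derive_pfs <- function(assessments, death_months = NA,
                       last_followup_months) {
  if (is.null(death_months)) death_months <- NA_real_
  if (length(last_followup_months) != 1 || is.na(last_followup_months) ||
      last_followup_months <= 0)
    abort("`last_followup_months` must be a single positive time",
          class = "domain_error")
  pd_times <- assessments$time_months[!is.na(assessments$response) &
                                        assessments$response == "PD"]
  candidates <- c(if (length(pd_times)) min(pd_times), death_months)
  candidates <- candidates[!is.na(candidates)]
  if (length(candidates) == 0)
    return(list(pfs_months = last_followup_months, pfs_event = FALSE))
  list(pfs_months = min(candidates), pfs_event = TRUE)
}

#' Primary-resistance label
#'
#' Primary resistance is initial on-treatment progression, or progression
#' after a best response of stable disease lasting less than 6 months:
#' `TRUE` iff the first informative post-baseline assessment is PD, or
#' progression occurred at under `sd_cutoff_months` months with no prior
#' response better than SD.
#'
#' @inheritParams derive_pfs
#' @param sd_cutoff_months Progression after SD before this time counts as
#'   primary resistance (default 6 months).
#' @return Logical flag.
#' @export
classify_primary_resistance <- function(assessments, sd_cutoff_months = 6) {
  a <- assessments |>
    dplyr::filter(.data$time_months > 0, !is.na(.data$response),
                  .data$response != "NE") |>
    dplyr::arrange(.data$time_months)
  if (nrow(a) == 0) return(FALSE)
  if (a$response[1] == "PD") return(TRUE)
  pd_idx <- which(a$response == "PD")
  if (length(pd_idx) == 0) return(FALSE)
  first_pd <- pd_idx[1]
  prior_best <- best_overall_response(a$response[seq_len(first_pd - 1)])
  prior_best == "SD" && a$time_months[first_pd] < sd_cutoff_months
}

#' Per-patient RECIST outcomes
#'
#' Runs the full response evaluation for a cohort: target-lesion selection,
#' burden series, per-timepoint categories, then per patient the best
#' overall response, PFS (progression or death, else censored at last
#' follow-up), time to treatment failure (first progression), and the
#' primary-resistance label.
#'
#' @inheritParams select_target_lesions
#' @param patients Optional patient table supplying `death_months` and
#'   `last_followup_months` per `patient_id`; when absent, death is unknown
#'   and last follow-up defaults to the last assessment time.
#' @return A list with `assessments` (per-timepoint tibble) and `outcomes`
#'   (per-patient tibble with `bor`, `pfs_months`, `pfs_event`,
#'   `ttf_months`, `primary_resistance`).
#' @export
recist_outcomes <- function(lesions, patients = NULL) {
  assessments <- recist_assessments(tumor_burden_series(lesions))
  outcomes <- assessments |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(a, key) {
      info <- patient_followup(patients, key$patient_id[1], a)
      pfs <- derive_pfs(a, info$death, info$followup)
      pd_times <- a$time_months[!is.na(a$response) & a$response == "PD"]
      tibble::tibble(
        bor = best_overall_response(a$response),
        pfs_months = pfs$pfs_months,
        pfs_event = pfs$pfs_event,
        ttf_months = if (length(pd_times)) min(pd_times) else NA_real_,
        primary_resistance = classify_primary_resistance(a))
    }) |>
    dplyr::ungroup()
  list(assessments = assessments, outcomes = outcomes)
}

patient_followup <- function(patients, id, assessments) {
  death <- NA_real_
  followup <- max(assessments$time_months)
  if (!is.null(patients)) {
    row <- patients[patients$patient_id == id, , drop = FALSE]
    if (nrow(row) == 1) {
      if ("death_months" %in% names(row)) death <- row$death_months[1]
      if ("last_followup_months" %in% names(row)) {
        fu <- row$last_followup_months[1]
        if (!is.na(fu)) followup <- fu
      }
    }
  }
  if (followup <= 0) followup <- max(assessments$time_months, 1e-6)
  list(death = death, followup = followup)
}

check_lesion_cols <- function(lesions) {
  needed <- c("patient_id", "lesion_id", "organ", "is_new", "time_months",
              "longest_diameter_mm")
  missing <- setdiff(needed, names(lesions))
  if (length(missing))
    abort(paste("lesion table is missing column(s):",
                paste(missing, collapse = ", ")), class = "schema_error")
  invisible(lesions)
}
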