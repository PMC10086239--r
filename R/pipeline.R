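#' End-to-end pipeline: simulate/read -> RECIST -> HPD -> cohort statistics
#'
#' Runs the full analysis chain on either a simulated cohort (pass a
#' [cohort_config()]) or on-disk tables (pass a named list of paths with
#' elements `patients`, `lesions`, and optionally `alterations`). Every
#' intermediate table is written tab-separated under `out_dir` together with
#' a JSON summary report; rerunning with the same configuration and seed is
#' byte-identical.
#'
#' The summary covers group sizes, the best-overall-response distribution,
#' HPD counts by arm and genotype, the per-arm Fisher tests of progressive
#' disease against Amp11q13 status, Kaplan-Meier medians per
#' (arm, genotype) stratum, and the log-rank test across strata.
#'
#' @param input A `cohort_config`, a `synthetic_cohort`, or a named list of
#'   file paths.
#' @param out_dir Output directory; `NULL` computes everything in memory
#'   without writing.
#' @param thresholds [hpd_thresholds()] used for the HPD stage.
#' @return A `pipeline_report` list: `patients`, `assessments`, `outcomes`,
#'   `hpd`, and `summary`.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         thresholds = hpd_thresholds()) {
  stage <- "input"
  res <- tryCatch({
    if (inherits(input, "cohort_config")) input <- simulate_cohort(input)
    if (inherits(input, "synthetic_cohort")) {
      patients <- input$patients
      lesions <- input$lesions
      alterations <- input$alterations
    } else if (is.list(input) &&
               all(c("patients", "lesions") %in% names(input))) {
      patients <- read_patient_table(input$patients)
      lesions <- read_lesion_table(input$lesions)
      alterations <- if (!is.null(input$alterations))
        read_alteration_table(input$alterations) else empty_alterations()
    } else {
      abort(paste("`input` must be a cohort_config, a synthetic_cohort,",
                  "or a list of paths"), class = "config_error")
    }

    if (nrow(patients) == 0) {
      warn("empty cohort: writing an empty report")
      return(empty_report(out_dir))
    }

    stage <- "genotype"
    if (!"amp11q13" %in% names(patients)) {
      patients <- patients |>
        dplyr::left_join(classify_amp11q13(alterations,
                                           patients$patient_id),
                         by = "patient_id")
    }

    stage <- "recist"
    rec <- recist_outcomes(lesions, patients)
    outcomes <- rec$outcomes |>
      dplyr::left_join(dplyr::select(patients, "patient_id", "amp11q13",
                                     "arm", "line"),
                       by = "patient_id")

    stage <- "hpd"
    hpd <- assess_hpd(rec$assessments, patients, thresholds)

    stage <- "stats"
    summary <- summarise_cohort(patients, outcomes, hpd)

    report <- structure(list(patients = patients,
                             assessments = rec$assessments,
                             outcomes = outcomes, hpd = hpd,
                             summary = summary, thresholds = thresholds),
                        class = "pipeline_report")
    if (!is.null(out_dir)) write_report(report, out_dir)
    report
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage `%s`: %s", stage,
                  conditionMessage(e)),
          class = "pipeline_error", parent = e)
  })
  res
}

summarise_cohort <- function(patients, outcomes, hpd) {
  merged <- outcomes |>
    dplyr::left_join(dplyr::select(hpd, "patient_id", "hpd"),
                     by = "patient_id") |>
    dplyr::mutate(stratum = paste0(.data$arm, "_",
                                   ifelse(.data$amp11q13, "Amp", "nonAmp")))
  fisher_by_arm <- merged |>
    dplyr::group_by(.data$arm) |>
    dplyr::group_modify(function(d, key) {
      tab <- matrix(c(sum(d$amp11q13 & d$bor == "PD"),
                      sum(d$amp11q13 & d$bor != "PD"),
                      sum(!d$amp11q13 & d$bor == "PD"),
                      sum(!d$amp11q13 & d$bor != "PD")), nrow = 2,
                    byrow = TRUE)
      fisher_exact(tab)
    }) |>
    dplyr::ungroup()
  km <- if (sum(outcomes$pfs_event) > 0) {
    glance(km_fit(merged, "pfs_months", "pfs_event", "stratum"))
  } else tibble::tibble()
  lr <- if (length(unique(merged$stratum)) > 1 &&
            sum(merged$pfs_event) > 0) {
    logrank_test(merged, "pfs_months", "pfs_event", "stratum")
  } else tibble::tibble()
  list(
    n_patients = nrow(patients),
    group_sizes = as.list(table(merged$arm)),
    amp11q13_n = sum(patients$amp11q13),
    bor_distribution = as.list(table(merged$bor)),
    hpd_counts = as.list(table(arm = merged$arm,
                               hpd = as.character(merged$hpd))),
    hpd_by_genotype = merged |>
      dplyr::filter(.data$arm == "PD1Ab") |>
      dplyr::count(.data$amp11q13, .data$hpd),
    fisher_pd_vs_amp = fisher_by_arm,
    km_medians = km,
    logrank = lr)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$patients, file.path(out_dir, "patients.tsv"))
  readr::write_tsv(report$assessments,
                   file.path(out_dir, "assessments.tsv"))
  readr::write_tsv(report$outcomes, file.path(out_dir, "outcomes.tsv"))
  readr::write_tsv(report$hpd, file.path(out_dir, "hpd.tsv"))
  summary <- report$summary
  summary$thresholds <- report$thresholds
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

empty_report <- function(out_dir) {
  report <- structure(list(patients = empty_patients(),
                           assessments = tibble::tibble(),
                           outcomes = tibble::tibble(),
                           hpd = tibble::tibble(),
                           summary = list(n_patients = 0),
                           thresholds = hpd_thresholds()),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(n_patients = 0),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_report> %d patients", s$n_patients))
  if (s$n_patients > 0) {
    cat(sprintf(" (%d Amp11q13)\n", s$amp11q13_n))
    cat("BOR:", paste(names(s$bor_distribution),
                      unlist(s$bor_distribution), sep = "=",
                      collapse = " "), "\n")
  } else cat("\n")
  invisible(x)
}
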