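#' Read the tab-separated cohort tables
#'
#' All interchange files are tab-separated text with a header row; times are
#' in months. Required columns are validated by name (a missing one raises a
#' schema error naming it); unknown columns are preserved (patient-table
#' extras become covariates). Rows with a non-numeric diameter are dropped
#' with a warning listing their line numbers; duplicated
#' (patient, lesion, time) measurements raise an error listing the
#' duplicates.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A typed tibble.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_lesion_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  require_cols(raw, c("patient_id", "lesion_id", "time_months",
                      "longest_diameter_mm"), path)
  if (!"organ" %in% names(raw)) raw$organ <- "unspecified"
  if (!"is_new" %in% names(raw)) raw$is_new <- "FALSE"
  diam <- suppressWarnings(as.numeric(raw$longest_diameter_mm))
  bad <- which(is.na(diam) & !is.na(raw$longest_diameter_mm))
  if (length(bad)) {
    warn(sprintf("dropping %d row(s) with non-numeric diameter (lines %s)",
                 length(bad), paste(bad + 1, collapse = ", ")))
    raw <- raw[-bad, , drop = FALSE]
    diam <- diam[-bad]
  }
  out <- raw |>
    dplyr::mutate(time_months = as.numeric(.data$time_months),
                  longest_diameter_mm = diam,
                  is_new = as.logical(.data$is_new)) |>
    dplyr::select("patient_id", "lesion_id", "organ", "is_new",
                  "time_months", "longest_diameter_mm",
                  dplyr::everything())
  dup <- out |>
    dplyr::count(.data$patient_id, .data$lesion_id, .data$time_months) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort(paste0("duplicated (patient, lesion, time) measurement(s): ",
                 paste(sprintf("%s/%s@%g", dup$patient_id, dup$lesion_id,
                               dup$time_months), collapse = "; ")),
          class = "dedup_error")
  out
}

#' @rdname read_tables
#' @export
read_patient_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  require_cols(raw, c("patient_id", "arm", "line"), path)
  numify <- intersect(c("pfs_months", "death_months",
                        "last_followup_months"), names(raw))
  boolify <- intersect(c("amp11q13", "pfs_event"), names(raw))
  raw |>
    dplyr::mutate(dplyr::across(dplyr::all_of(numify), as.numeric),
                  dplyr::across(dplyr::all_of(boolify), as.logical))
}

#' @rdname read_tables
#' @export
read_alteration_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  require_cols(raw, c("patient_id", "gene", "alteration"), path)
  raw
}

require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")), class = "schema_error")
  invisible(df)
}

#' Write a synthetic cohort to tab-separated files
#'
#' Writes `patients.tsv`, `lesions.tsv`, `alterations.tsv` and the
#' ground-truth sidecar `truth.tsv` into `dir`.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("patients.tsv", "lesions.tsv",
                            "alterations.tsv", "truth.tsv"))
  readr::write_tsv(cohort$patients, paths[1])
  readr::write_tsv(cohort$lesions, paths[2])
  readr::write_tsv(cohort$alterations, paths[3])
  readr::write_tsv(cohort$truth, paths[4])
  invisible(paths)
}
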