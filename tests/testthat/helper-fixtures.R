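# Small builders for lesion-measurement fixtures used across tests.

lesion_rows <- function(patient_id, lesion_id, time_months, diameter_mm,
                        organ = "liver", is_new = FALSE) {
  tibble::tibble(patient_id = patient_id, lesion_id = lesion_id,
                 organ = organ, is_new = is_new,
                 time_months = time_months,
                 longest_diameter_mm = diameter_mm)
}

# one patient with a single target lesion measured at the given times
one_lesion_series <- function(times, diameters, patient_id = "P1",
                              lesion_id = "L1", new_lesion_at = NULL) {
  out <- lesion_rows(patient_id, lesion_id, times, diameters)
  if (!is.null(new_lesion_at)) {
    out <- dplyr::bind_rows(out, lesion_rows(patient_id, "NEW1",
                                             new_lesion_at, 10,
                                             is_new = TRUE))
  }
  out
}

# the worked-example HPD case series shipped with the package
read_case_series <- function() {
  readr::read_tsv(system.file("extdata", "hpd_case_series.tsv",
                              package = "hpdkinetics"),
                  show_col_types = FALSE)
}
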