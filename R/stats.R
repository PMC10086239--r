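#' Chromosome 11q13 amplification status from gene-level calls
#'
#' A patient is Amp11q13 iff at least one of CCND1, FGF3, FGF4, FGF19
#' carries a copy-number amplification call. Point mutations in those genes
#' do not count; gene symbols are matched case-insensitively.
#'
#' @param alterations Tibble with columns `patient_id`, `gene`,
#'   `alteration` (the call kind, e.g. "amplification", "missense").
#' @param patient_ids Optional vector of all patient ids; patients with no
#'   alteration rows are then reported as `FALSE`.
#' @param genes Gene set defining the amplicon.
#' @return Tibble with `patient_id` and logical `amp11q13`.
#' @export
#' @examples
#' classify_amp11q13(tibble::tibble(patient_id = "P1", gene = "CCND1",
#'                                  alteration = "amplification"))
classify_amp11q13 <- function(alterations, patient_ids = NULL,
                              genes = c("CCND1", "FGF3", "FGF4", "FGF19")) {
  needed <- c("patient_id", "gene", "alteration")
  if (!all(needed %in% names(alterations)))
    abort("`alterations` needs columns patient_id, gene, alteration",
          class = "schema_error")
  hits <- alterations |>
    dplyr::filter(toupper(.data$gene) %in% toupper(genes),
                  tolower(.data$alteration) == "amplification") |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::mutate(amp11q13 = TRUE)
  universe <- unique(c(patient_ids, alterations$patient_id))
  tibble::tibble(patient_id = universe) |>
    dplyr::left_join(hits, by = "patient_id") |>
    dplyr::mutate(amp11q13 = !is.na(.data$amp11q13))
}

#' Contingency table of two categorical variables
#'
#' Cross-tabulates two variables of a patient-level tibble. Missing values
#' either form their own explicit category (`na_policy = "category"`, the
#' default — the convention needed to reproduce baseline-characteristics
#' chi-square tests computed over an NA row) or are dropped.
#'
#' @param data A tibble of records.
#' @param row_var,col_var Column names (strings) to tabulate.
#' @param na_policy `"category"` or `"drop"`.
#' @return An integer matrix with dimnames; rows = `row_var` levels,
#'   columns = `col_var` levels (plus `"NA"` under the category policy when
#'   missing values exist).
#' @export
contingency_table <- function(data, row_var, col_var,
                              na_policy = c("category", "drop")) {
  na_policy <- match.arg(na_policy)
  for (v in c(row_var, col_var)) {
    if (!v %in% names(data))
      abort(sprintf("variable `%s` not found in data", v),
            class = "config_error")
  }
  r <- as.character(data[[row_var]])
  cc <- as.character(data[[col_var]])
  if (na_policy == "category") {
    r[is.na(r)] <- "NA"
    cc[is.na(cc)] <- "NA"
  } else {
    keep <- !is.na(r) & !is.na(cc)
    r <- r[keep]; cc <- cc[keep]
  }
  tab <- table(r, cc)
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  names(dimnames(out)) <- c(row_var, col_var)
  out
}

#' Two-sided Fisher exact test
#'
#' Exact two-sided P for a 2x2 table under the hypergeometric null: the sum
#' of the probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (up to a 1e-7
#' relative tolerance for floating-point ties). A table with a zero row or
#' column margin is degenerate and returns P = 1.
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return Tibble with `p_value` and `odds_ratio` (conditional MLE).
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 5, 0, 10), 2))  # P = 0.0325
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table)))
    abort("`table` must be a 2x2 matrix of nonnegative integers",
          class = "domain_error")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(tibble::tibble(p_value = 1, odds_ratio = NA_real_))
  ft <- fisher.test(table)
  tibble::tibble(p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate))
}

#' Pearson chi-square test without continuity correction
#'
#' `statistic = sum((O - E)^2 / E)` with expectations from the margins,
#' `df = (r - 1)(c - 1)`, upper-tail P. No Yates correction is applied (the
#' convention under which printed baseline-table P-values reproduce from
#' printed counts). A zero margin leaves the expectations undefined.
#'
#' @param table An r x c matrix of nonnegative counts (r, c >= 2), e.g. from
#'   [contingency_table()].
#' @return Tibble with `statistic`, `df`, `p_value` (all `NA` if a margin is
#'   zero).
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    abort("`table` must be at least 2x2", class = "domain_error")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(tibble::tibble(statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_))
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples (e.g. immune-cell densities
#' by genotype). Small untied samples (both sizes at most `exact_max`) are
#' tested by exact enumeration; larger or tied samples use the normal
#' approximation with tie correction and continuity correction. Identical
#' samples give P = 1.
#'
#' @param x,y Numeric vectors, both nonempty.
#' @param exact_max Largest per-group size for the exact test.
#' @return Tibble with `u_statistic` and `p_value`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact P = 0.1
mann_whitney <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0)
    abort("both samples must be nonempty", class = "domain_error")
  if (length(unique(c(x, y))) == 1)
    return(tibble::tibble(u_statistic = length(x) * length(y) / 2,
                          p_value = 1))
  ties <- any(duplicated(c(x, y)))
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact,
                                     correct = !use_exact))
  tibble::tibble(u_statistic = unname(wt$statistic),
                 p_value = min(wt$p.value, 1))
}
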