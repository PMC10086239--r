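#' Kaplan-Meier fit by group
#'
#' Product-limit survival estimates of progression-free survival (or any
#' right-censored time) per group, with log-log confidence intervals. The
#' median is extracted from the curve as the earliest event time at which
#' the survival estimate drops to 0.5 or below; if the curve never does, the
#' median is not reached (`NA`).
#'
#' @param data Tibble of records.
#' @param time,event,group Column names (strings): follow-up time in months,
#'   logical/0-1 event indicator, grouping variable. `group = NULL` fits a
#'   single curve.
#' @return A `km_fit` object wrapping the [survival::survfit] fit; see
#'   [tidy.km_fit()] and [glance.km_fit()].
#' @export
km_fit <- function(data, time = "pfs_months", event = "pfs_event",
                   group = NULL) {
  check_surv_cols(data, time, event, group)
  if (any(data[[time]] <= 0, na.rm = TRUE))
    abort("survival times must be positive", class = "domain_error")
  groups <- if (is.null(group)) factor(rep("all", nrow(data)))
            else factor(data[[group]])
  empty <- setdiff(levels(groups), levels(droplevels(groups)))
  if (length(empty))
    warn(paste("dropping empty group(s):", paste(empty, collapse = ", ")))
  df <- data.frame(.time = data[[time]],
                   .event = as.integer(data[[event]]),
                   .group = droplevels(groups))
  fit <- survival::survfit(survival::Surv(.time, .event) ~ .group,
                           data = df, conf.type = "log-log")
  structure(list(fit = fit, data = df, group_var = group %||% "all"),
            class = "km_fit")
}

#' @describeIn km_fit Per-timepoint curve: group, time, numbers at risk,
#'   events, survival estimate and confidence bounds.
#' @param x A `km_fit` object.
#' @param ... Unused.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep("all", length(s$time))
         else sub("^\\.group=", "", as.character(s$strata))
  tibble::tibble(group = grp, time = s$time, n_risk = s$n.risk,
                 n_event = s$n.event, survival = s$surv,
                 conf_low = s$lower, conf_high = s$upper)
}

#' @describeIn km_fit One row per group: size, events, and the median
#'   survival time (earliest time with survival <= 0.5; `NA` = not reached).
#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  curve <- tidy(x)
  curve |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = max(.data$n_risk),
      events = sum(.data$n_event),
      median_months = km_median(.data$time, .data$survival, .data$n_event),
      .groups = "drop")
}

km_median <- function(time, survival, n_event) {
  at <- which(survival <= 0.5 + 1e-12 & n_event > 0)
  if (length(at) == 0) NA_real_ else time[min(at)]
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank chi-square comparing survival across
#' groups, with `df = groups - 1`.
#'
#' @inheritParams km_fit
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, time = "pfs_months", event = "pfs_event",
                         group = "amp11q13") {
  check_surv_cols(data, time, event, group)
  groups <- droplevels(factor(data[[group]]))
  if (nlevels(groups) < 2)
    abort("log-rank test needs at least two nonempty groups",
          class = "domain_error")
  df <- data.frame(.time = data[[time]],
                   .event = as.integer(data[[event]]), .group = groups)
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group,
                           data = df)
  k <- length(sd$n) - 1
  tibble::tibble(statistic = sd$chisq, df = k,
                 p_value = pchisq(sd$chisq, k, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; per term the hazard
#' ratio, 95% Wald confidence interval and Wald P-value. An optional
#' two-variable interaction adds main effects plus their product term; the
#' interaction P is the Wald P of the product term. Monotone-likelihood
#' situations (perfect separation in small strata) are caught and reported
#' on the fit object rather than crashing.
#'
#' @inheritParams km_fit
#' @param terms Character vector of covariate column names.
#' @param interaction Optional length-2 character vector of column names
#'   whose interaction is tested.
#' @return A `cox_fit` object; see [tidy.cox_fit()] and
#'   [glance.cox_fit()].
#' @export
cox_fit <- function(data, time = "pfs_months", event = "pfs_event",
                    terms, interaction = NULL) {
  check_surv_cols(data, time, event, NULL)
  if (sum(as.integer(data[[event]])) == 0)
    abort("Cox regression needs at least one event", class = "fit_error")
  rhs <- terms
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2)
    rhs <- union(rhs, interaction)
    rhs <- c(rhs, paste(interaction, collapse = ":"))
  }
  missing_terms <- setdiff(unique(unlist(strsplit(rhs, ":"))), names(data))
  if (length(missing_terms))
    abort(paste("term(s) not in data:",
                paste(missing_terms, collapse = ", ")),
          class = "config_error")
  fml <- stats::as.formula(paste(
    sprintf("survival::Surv(%s, as.integer(%s))", time, event), "~",
    paste(rhs, collapse = " + ")))
  warnings <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, interaction = interaction,
                 warnings = warnings),
            class = "cox_fit")
}

#' @describeIn cox_fit Per-term tibble: `term`, `hr`, `conf_low`,
#'   `conf_high`, `p_value`. Coefficients that did not converge (monotone
#'   likelihood) are flagged by the fit's `warnings`.
#' @param x A `cox_fit` object.
#' @param ... Unused.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(term = rownames(s$coefficients),
                 hr = s$coefficients[, "exp(coef)"],
                 conf_low = s$conf.int[, "lower .95"],
                 conf_high = s$conf.int[, "upper .95"],
                 p_value = s$coefficients[, "Pr(>|z|)"])
}

#' @describeIn cox_fit One-row model summary: `n`, `n_events`,
#'   `concordance`, `likelihood_ratio_p`, and `interaction_p` (Wald P of the
#'   product term, `NA` if no interaction was requested).
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  inter_p <- NA_real_
  if (!is.null(x$interaction)) {
    co <- tidy(x)
    hit <- grepl(":", co$term, fixed = TRUE)
    if (any(hit)) inter_p <- co$p_value[which(hit)[1]]
  }
  tibble::tibble(n = s$n, n_events = s$nevent,
                 concordance = unname(s$concordance["C"]),
                 likelihood_ratio_p = unname(s$logtest["pvalue"]),
                 interaction_p = inter_p,
                 converged = length(x$warnings) == 0)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit>\n")
  print(tidy(x))
  if (length(x$warnings))
    cat("fit warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> medians (months):\n")
  print(glance(x))
  invisible(x)
}

check_surv_cols <- function(data, time, event, group) {
  for (v in c(time, event, group)) {
    if (!is.null(v) && !v %in% names(data))
      abort(sprintf("column `%s` not found in data", v),
            class = "config_error")
  }
  invisible(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
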