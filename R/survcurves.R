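#' Kaplan-Meier estimate by group
#'
#' Product-limit estimator of the survival function, per level of a grouping
#' column, via [survival::survfit()]. The returned object carries the step
#' function (times, survival probabilities, numbers at risk) and the usual
#' `summary`/`plot` methods of the survival package.
#'
#' @param data Data frame of survival records.
#' @param time,event Column names of the follow-up time (positive, months)
#'   and event indicator (0/1 or logical).
#' @param group Optional grouping column name; `NULL` fits a single curve.
#' @return A `survfit` object.
#' @export
km_estimate <- function(data, time = "os_time", event = "os_event",
                        group = NULL) {
  check_survival_columns(data, time, event)
  if (sum(data[[event]]) < 1L) {
    # All-censored input is legal: the curve is flat at 1.
    message("no events observed; the curve stays at 1")
  }
  rhs <- if (is.null(group)) "1" else paste0("factor(", group, ")")
  fml <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                  ") ~ ", rhs))
  fit <- survival::survfit(fml, data = data)
  fit$call <- NULL
  fit
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank statistic over event times,
#' via [survival::survdiff()]. Two groups by default; k groups give the
#' (k-1)-df extension.
#'
#' @inheritParams km_estimate
#' @param group Grouping column name (required).
#' @return List `chisq`, `df`, `p_value`, `n` (per-group sizes).
#' @export
logrank_test <- function(data, time = "os_time", event = "os_event",
                         group = "group") {
  check_survival_columns(data, time, event)
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups")
  sd <- survival::survdiff(
    survival::Surv(data[[time]], data[[event]]) ~ g)
  df <- nlevels(g) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = as.vector(sd$n))
}

#' Cox proportional-hazards association
#'
#' Fits [survival::coxph()] with the Efron tie approximation and reports,
#' per covariate term, the hazard ratio with 95% Wald confidence interval
#' and p-value. `univariate = TRUE` loops the covariates singly instead of
#' fitting them jointly. Terms whose coefficient is not estimable
#' (collinear/duplicated covariates) or that show signs of separation
#' (monotone likelihood) are flagged in the `flagged` column.
#'
#' @inheritParams km_estimate
#' @param covariates Character vector of covariate column names.
#' @param univariate Fit each covariate alone (`TRUE`) or jointly
#'   (default `FALSE`).
#' @return Data frame `term`, `hr`, `ci_low`, `ci_high`, `p_value`,
#'   `flagged`, plus attribute `n_events`.
#' @export
cox_fit <- function(data, time = "os_time", event = "os_event",
                    covariates, univariate = FALSE) {
  check_survival_columns(data, time, event)
  if (length(covariates) < 1L) stop("no covariates given")
  n_events <- sum(data[[event]])
  if (n_events < length(covariates) + 1L) {
    stop("too few events (", n_events, ") for ", length(covariates),
         " covariate(s)")
  }

  fit_one <- function(covs) {
    fml <- stats::as.formula(paste0(
      "survival::Surv(", time, ", ", event, ") ~ ",
      paste(covs, collapse = " + ")))
    warned <- character()
    fit <- withCallingHandlers(
      survival::coxph(fml, data = data, ties = "efron"),
      warning = function(w) {
        warned <<- c(warned, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (any(grepl("did not converge|Ran out of iterations", warned))) {
      stop("Cox fit did not converge for: ", paste(covs, collapse = ", "))
    }
    separated <- any(grepl("converged before|infinite", warned))
    co <- summary(fit)$coefficients
    data.frame(term = rownames(co), hr = co[, "exp(coef)"],
               ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
               ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
               p_value = co[, "Pr(>|z|)"],
               flagged = separated | is.na(co[, "coef"]) |
                 abs(co[, "coef"]) > 10,
               row.names = NULL, stringsAsFactors = FALSE)
  }

  res <- if (univariate) {
    do.call(rbind, lapply(covariates, fit_one))
  } else {
    fit_one(covariates)
  }
  attr(res, "n_events") <- n_events
  res
}

check_survival_columns <- function(data, time, event) {
  if (!all(c(time, event) %in% names(data))) {
    stop("missing survival column(s): ",
         paste(setdiff(c(time, event), names(data)), collapse = ", "))
  }
  t <- data[[time]]
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop("'", time, "' must be finite and positive")
  }
  e <- data[[event]]
  if (!all(e %in% c(0, 1, TRUE, FALSE))) {
    stop("'", event, "' must be 0/1 or logical")
  }
  invisible(data)
}
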