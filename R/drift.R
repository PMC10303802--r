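#' Classify DNAm-age drift against chronological age
#'
#' For every sample and clock, the deviation is `dnam_age - chron_age`
#' (years). Samples are classed as `matched` when `|deviation| < band`,
#' `DNAmaa` (acceleration) when `deviation >= band`, and `DNAmad`
#' (deceleration) when `deviation <= -band`; the band boundary itself
#' therefore belongs to the drifted classes. Samples without a chronological
#' age are dropped with a message reporting the count, mirroring how cohort
#' analyses discard age-less records.
#'
#' @param chron_ages Named numeric vector of chronological ages in years
#'   (names are sample ids). `NA` entries are dropped with a message.
#' @param dnam_ages Data frame with columns `sample_id`, `clock`,
#'   `dnam_age` — the (row-bound) output of [predict.clock_model()] for one
#'   or more clocks.
#' @param band Half-width of the matched band in years; default 3.
#' @param deviation Either `"difference"` (default; `dnam - chron`) or
#'   `"residual"` (residual of the per-clock least-squares fit of DNAm age on
#'   chronological age).
#' @return A `drift_table`: data frame with columns `sample_id`, `chron_age`,
#'   `clock`, `dnam_age`, `deviation`, `class`, with the band stored as an
#'   attribute.
#' @seealso [cohort_summary()], [select_hdnamad()]
#' @export
compute_drift <- function(chron_ages, dnam_ages, band = 3,
                          deviation = c("difference", "residual")) {
  deviation <- match.arg(deviation)
  if (!is.numeric(band) || length(band) != 1L || !is.finite(band) ||
      band <= 0) {
    stop("'band' must be a single positive number of years")
  }
  if (is.null(names(chron_ages))) stop("'chron_ages' must be named by sample")
  req <- c("sample_id", "clock", "dnam_age")
  if (!all(req %in% names(dnam_ages))) {
    stop("'dnam_ages' needs columns ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(dnam_ages$dnam_age))) {
    stop("non-finite DNAm age in 'dnam_ages'")
  }

  dropped <- names(chron_ages)[is.na(chron_ages)]
  if (length(dropped) > 0L) {
    message("dropping ", length(dropped), " of ", length(chron_ages),
            " sample(s) without chronological age")
    chron_ages <- chron_ages[!is.na(chron_ages)]
  }
  if (any(!is.finite(chron_ages))) stop("non-finite chronological age")

  keep <- dnam_ages$sample_id %in% names(chron_ages)
  d <- dnam_ages[keep, req, drop = FALSE]
  d$chron_age <- unname(chron_ages[d$sample_id])

  if (deviation == "difference") {
    d$deviation <- d$dnam_age - d$chron_age
  } else {
    d$deviation <- NA_real_
    for (cl in unique(d$clock)) {
      i <- d$clock == cl
      d$deviation[i] <- stats::resid(stats::lm(dnam_age ~ chron_age,
                                               data = d[i, ]))
    }
  }
  d$class <- ifelse(abs(d$deviation) < band, "matched",
                    ifelse(d$deviation >= band, "DNAmaa", "DNAmad"))
  d <- d[, c("sample_id", "chron_age", "clock", "dnam_age", "deviation",
             "class")]
  rownames(d) <- NULL
  structure(d, band = band, deviation_mode = deviation,
            class = c("drift_table", "data.frame"))
}

#' Cohort-level summary of one clock's drift
#'
#' Reports the Pearson correlation between DNAm and chronological age (with
#' its p-value), the mean absolute difference (MAD, years) and the deviation
#' range. With a constant age vector the correlation is undefined and
#' reported as `NA` — distinct from zero — while the MAD is still computed.
#'
#' @param records A `drift_table` from [compute_drift()].
#' @param clock Clock name to summarize.
#' @return List with `clock`, `n`, `pearson_r`, `pearson_p`, `mad`,
#'   `deviation_range` (min, max), class `"cohort_summary"`.
#' @export
cohort_summary <- function(records, clock) {
  stopifnot(inherits(records, "drift_table"))
  d <- records[records$clock == clock, ]
  if (nrow(d) == 0L) stop("clock '", clock, "' not present in the records")
  if (nrow(d) < 3L) stop("need at least 3 samples for a cohort summary")
  r <- p <- NA_real_
  if (stats::sd(d$dnam_age) > 0 && stats::sd(d$chron_age) > 0) {
    ct <- stats::cor.test(d$chron_age, d$dnam_age, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(clock = clock, n = nrow(d), pearson_r = r, pearson_p = p,
                 mad = mean(abs(d$deviation)),
                 deviation_range = range(d$deviation)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Clock '%s' on %d samples\n", x$clock, x$n))
  if (is.na(x$pearson_r)) {
    cat("  Pearson r: undefined (constant ages)\n")
  } else {
    cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  }
  cat(sprintf("  MAD = %.2f yr; deviation range [%.1f, %.1f] yr\n",
              x$mad, x$deviation_range[1L], x$deviation_range[2L]))
  invisible(x)
}

#' @export
summary.drift_table <- function(object, ...) {
  lapply(unique(object$clock), function(cl) cohort_summary(object, cl))
}

#' Select high-DNAm-age-deceleration (hDNAmad) samples
#'
#' The dual-clock tercile rule: samples classed `DNAmad` by the primary
#' clock are the candidates; they are ranked by primary-clock deviation
#' ascending (most decelerated first, ties broken by sample id) and the top
#' `floor(fraction * n_candidates)` retained; of those, a sample is labelled
#' hDNAmad-positive iff the confirmation clock also classes it `DNAmad`.
#' All other samples are negative.
#'
#' `fraction = 1/3` reproduces the cohort-stratification tercile (403
#' candidates give 134 retained). `fraction = 1` reduces the rule to plain
#' dual-clock confirmation, appropriate when the decelerated subgroup itself
#' is the estimand (as in simulation recovery).
#'
#' @param records A `drift_table` containing both clocks for every sample.
#' @param primary_clock Clock whose DNAmad calls define and rank candidates.
#' @param confirm_clock Clock whose DNAmad call confirms membership.
#' @param fraction Fraction of candidates retained, in (0, 1\]; default 1/3.
#' @return Named logical vector over all samples in `records`, `TRUE` for
#'   hDNAmad-positive, with attributes `n_candidates` and `tercile_size`.
#' @export
select_hdnamad <- function(records, primary_clock, confirm_clock,
                           fraction = 1 / 3) {
  stopifnot(inherits(records, "drift_table"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]")
  }
  prim <- records[records$clock == primary_clock, ]
  conf <- records[records$clock == confirm_clock, ]
  if (nrow(prim) == 0L) stop("primary clock '", primary_clock, "' absent")
  if (nrow(conf) == 0L) stop("confirmation clock '", confirm_clock,
                             "' absent")
  if (!setequal(prim$sample_id, conf$sample_id)) {
    stop("both clocks must cover the same samples")
  }

  samples <- sort(unique(prim$sample_id))
  labels <- stats::setNames(logical(length(samples)), samples)

  cand <- prim[prim$class == "DNAmad", ]
  k <- floor(fraction * nrow(cand))
  if (nrow(cand) == 0L) {
    warning("no DNAmad candidate under the primary clock; ",
            "all samples labelled negative")
  } else if (k > 0L) {
    ord <- order(cand$deviation, cand$sample_id)
    top <- cand$sample_id[ord][seq_len(k)]
    confirmed <- conf$sample_id[conf$class == "DNAmad"]
    labels[top[top %in% confirmed]] <- TRUE
  }
  attr(labels, "n_candidates") <- nrow(cand)
  attr(labels, "tercile_size") <- as.integer(k)
  labels
}
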