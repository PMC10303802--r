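#' The 39 autosomal chromosome arms
#'
#' 1p..22q minus the five acrocentric short arms (13p, 14p, 15p, 21p, 22p),
#' which carry no unique sequence and are conventionally dropped from
#' arm-level calls.
#'
#' @param drop_acrocentric_p Drop the acrocentric p-arms (default `TRUE`,
#'   giving 39 arms); `FALSE` gives all 44.
#' @return Character vector of arm ids.
#' @export
autosome_arms <- function(drop_acrocentric_p = TRUE) {
  arms <- as.vector(t(outer(1:22, c("p", "q"), paste0)))
  if (drop_acrocentric_p) {
    arms <- setdiff(arms, paste0(c(13, 14, 15, 21, 22), "p"))
  }
  arms
}

#' Aneuploidy score
#'
#' The sum total of altered chromosome arms: per sample, the count of arms
#' whose call is non-zero (+1 gained or -1 lost). Range 0..number of arms.
#'
#' @param calls Integer/numeric matrix samples x arms with values in
#'   \{-1, 0, +1\}; colnames must be valid arm ids.
#' @param arms Allowed arm universe; default [autosome_arms()].
#' @return Named integer vector of per-sample scores.
#' @export
aneuploidy_score <- function(calls, arms = autosome_arms()) {
  if (!is.matrix(calls)) stop("'calls' must be a samples x arms matrix")
  if (is.null(colnames(calls))) stop("'calls' must have arm colnames")
  unknown <- setdiff(colnames(calls), arms)
  if (length(unknown) > 0L) {
    stop("unknown arm id(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(calls %in% c(-1, 0, 1))) {
    stop("arm calls must be -1, 0 or +1")
  }
  scores <- as.integer(rowSums(calls != 0))
  stats::setNames(scores, rownames(calls))
}

#' Threshold mean arm values into calls
#'
#' Convenience for simulated data: mean copy-number values beyond
#' `threshold` in absolute value become +1/-1, the rest 0. Arm-level calls
#' from real pipelines should be supplied directly.
#'
#' @param values Numeric samples x arms matrix of mean segment values.
#' @param threshold Absolute call threshold; default 0.2.
#' @return Matrix of calls in \{-1, 0, +1\}.
#' @export
call_arms <- function(values, threshold = 0.2) {
  stopifnot(is.matrix(values), threshold > 0)
  calls <- matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
  calls[values > threshold] <- 1L
  calls[values < -threshold] <- -1L
  calls
}

# Default silent variant classes (everything else counts as non-silent).
.silent_classes <- c("Silent", "Synonymous", "3'UTR", "5'UTR", "Intron",
                     "IGR", "RNA")

#' Silent variant classes
#'
#' @return Character vector of variant classes counted as silent by [tmb()].
#' @export
silent_variant_classes <- function() .silent_classes

#' Tumor mutation burden
#'
#' Non-silent mutations per megabase of callable sequence. The default
#' denominator (38 Mb) is the conventional whole-exome callable size;
#' adjust for other assays.
#'
#' @param muts Mutation table: data frame with columns `sample_id`, `gene`,
#'   `variant_class` (see [read_maf()]).
#' @param callable_mb Callable megabases; default 38.
#' @param samples Optional sample-id vector: samples without mutation rows
#'   get TMB 0 and the result follows this order.
#' @param silent_classes Variant classes not counted; default
#'   [silent_variant_classes()].
#' @return Named numeric vector of per-sample TMB.
#' @export
tmb <- function(muts, callable_mb = 38, samples = NULL,
                silent_classes = silent_variant_classes()) {
  if (!is.numeric(callable_mb) || callable_mb <= 0) {
    stop("'callable_mb' must be positive")
  }
  req <- c("sample_id", "variant_class")
  if (!all(req %in% names(muts))) {
    stop("'muts' needs columns ", paste(req, collapse = ", "))
  }
  nonsilent <- muts[!(muts$variant_class %in% silent_classes), ]
  counts <- table(factor(nonsilent$sample_id,
                         levels = if (is.null(samples))
                           sort(unique(muts$sample_id)) else samples))
  stats::setNames(as.numeric(counts) / callable_mb, names(counts))
}

#' Read a MAF-like mutation table
#'
#' Recognizes the columns `Tumor_Sample_Barcode`, `Hugo_Symbol` and
#' `Variant_Classification` of a tab-separated MAF export.
#'
#' @param path TSV path.
#' @return Data frame `sample_id`, `gene`, `variant_class`.
#' @export
read_maf <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  if (!all(req %in% names(tab))) {
    stop("MAF must have columns ", paste(req, collapse = ", "))
  }
  data.frame(sample_id = tab$Tumor_Sample_Barcode, gene = tab$Hugo_Symbol,
             variant_class = tab$Variant_Classification,
             stringsAsFactors = FALSE)
}

# Closed status vocabulary of gene alteration tables.
.alteration_statuses <- c("none", "gain", "amplification", "deletion",
                          "mutation", "multiple")

#' Per-gene alteration frequency by group
#'
#' From a long gene-alteration table (`sample_id`, `gene`, `status`),
#' computes the fraction of altered samples per group for one gene and the
#' 2x2 counts table (altered/unaltered x group), ready for
#' [two_group_table_test()]. Samples without a row for the gene count as
#' unaltered.
#'
#' @param alts Data frame `sample_id`, `gene`, `status` with statuses in
#'   `none`, `gain`, `amplification`, `deletion`, `mutation`, `multiple`.
#' @param gene Gene to tabulate.
#' @param labels Two-group labels named by sample id (or aligned with the
#'   sorted sample universe of `alts`).
#' @param which Statuses counted as altered; default all non-`none`.
#' @return List with `fractions` (per group), `table` (2x2 counts,
#'   altered/unaltered x group).
#' @export
alteration_frequency <- function(alts, gene, labels,
                                 which = setdiff(.alteration_statuses,
                                                 "none")) {
  req <- c("sample_id", "gene", "status")
  if (!all(req %in% names(alts))) {
    stop("'alts' needs columns ", paste(req, collapse = ", "))
  }
  bad <- setdiff(unique(alts$status), .alteration_statuses)
  if (length(bad) > 0L) {
    stop("unknown status value(s): ", paste(bad, collapse = ", "))
  }
  if (!gene %in% alts$gene) stop("gene '", gene, "' not in the table")

  samples <- if (!is.null(names(labels))) names(labels) else
    sort(unique(alts$sample_id))
  if (length(labels) != length(samples)) {
    stop("'labels' must cover every sample (use a named vector)")
  }
  lab <- droplevels(as.factor(labels))
  if (nlevels(lab) != 2L) stop("exactly two groups required")

  g <- alts[alts$gene == gene & alts$status %in% which, ]
  altered <- samples %in% g$sample_id
  tab <- table(altered = factor(altered, levels = c(TRUE, FALSE),
                                labels = c("altered", "unaltered")),
               group = lab)
  fr <- tab["altered", ] / colSums(tab)
  list(fractions = fr, table = unclass(tab))
}

#' Two-group 2x2 contingency test
#'
#' `method = "auto"` (default) runs Fisher's exact test when any expected
#' cell count is below 5 and the chi-square test otherwise; both are
#' available explicitly. A table with a zero margin is reported as p = 1
#' with an undefined (NA) odds ratio. The odds ratio reported is the sample
#' cross-product ratio.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param method `"auto"`, `"fisher"` or `"chisq"`.
#' @return List `p_value`, `odds_ratio`, `method`, `table`.
#' @export
two_group_table_test <- function(table, method = c("auto", "fisher",
                                                   "chisq")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("'table' must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("'table' must hold non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(p_value = 1, odds_ratio = NA_real_, method = "degenerate",
                table = table))
  }
  orr <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  if (method == "auto") {
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    method <- if (any(expected < 5)) "fisher" else "chisq"
  }
  p <- if (method == "fisher") {
    stats::fisher.test(table)$p.value
  } else {
    suppressWarnings(stats::chisq.test(table, correct = FALSE)$p.value)
  }
  list(p_value = p, odds_ratio = orr, method = method, table = table)
}
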