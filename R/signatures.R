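#' Built-in expression signature panels
#'
#' The four fixed panels used for cohort characterization: the myeloid and
#' T-effector immune signatures, the cell-cycle proliferation panel
#' (Ki-67 under its gene symbol MKI67), and the ten telomerase holoenzyme
#' components (TCAB1 under its symbol WRAP53).
#'
#' @return Named list of character vectors of gene symbols.
#' @export
builtin_panels <- function() {
  list(
    myeloid = c("IL6", "CXCL1", "CXCL2", "CXCL3", "CXCL8", "PTGS2"),
    Teffector = c("CD8A", "EOMES", "PRF1", "IFNG", "CD274"),
    cell_cycle = c("CDK2", "CDK4", "CDK6", "BUB1B", "CCNE1", "POLQ",
                   "AURKA", "MKI67", "CCNB2"),
    telomerase = c("TERT", "TERC", "DKC1", "WRAP53", "NHP2", "GAR1",
                   "NOP10", "RUVBL1", "RUVBL2", "NVL")
  )
}

#' Gene symbol aliases
#'
#' Maps legacy/report names to the HGNC symbols used in expression matrices
#' (e.g. KI-67 to MKI67, TCAB1 to WRAP53, PD-L1 to CD274). The shipped table
#' at `system.file("extdata", "gene_aliases.csv", package = "dnamdrift")` can
#' be replaced by the user.
#'
#' @param path Alias CSV (columns `alias`, `symbol`); default the shipped
#'   table.
#' @return Named character vector, alias -> symbol.
#' @export
gene_aliases <- function(path = system.file("extdata", "gene_aliases.csv",
                                            package = "dnamdrift")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$symbol, tab$alias)
}

#' Single-sample GSEA enrichment score
#'
#' Ranks the measured genes of one sample by descending expression (ties
#' broken by gene id) and accumulates, step by step down the list, the
#' difference between the weighted in-set cumulative fraction and the
#' unweighted out-of-set cumulative fraction. In-set weights are
#' `rank^tau`, where `rank` is the position counted from the bottom of the
#' list (the top gene has rank N); `tau = 0` gives the unweighted kernel.
#' The score is the sum of the stepwise differences; positive scores mean
#' the set is concentrated at the top of the sample's expression profile.
#'
#' @param expr Named numeric vector: one sample's expression over the
#'   measured gene universe.
#' @param gene_set Character vector of gene ids (or a single element of
#'   [read_gmt()]'s result).
#' @param tau Rank-weight exponent, >= 0. Default 0.25.
#' @return Single numeric enrichment score.
#' @export
ssgsea_score <- function(expr, gene_set, tau = 0.25) {
  if (!is.numeric(expr) || is.null(names(expr))) {
    stop("'expr' must be a named numeric vector")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop("'tau' must be a single number >= 0")
  }
  gene_set <- unique(as.character(gene_set))
  n <- length(expr)
  in_set <- names(expr) %in% gene_set
  m <- sum(in_set)
  if (m == 0L) stop("no gene of the set is measured in this sample")
  if (m == n) stop("gene set covers the whole measured universe")

  ord <- order(-expr, names(expr))
  in_set <- in_set[ord]
  # rank counted from the bottom: top gene gets n
  w <- (n:1)^tau
  w[!in_set] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (n - m)
  sum(p_in - p_out)
}

#' Score signature panels across a cohort
#'
#' Applies [ssgsea_score()] per sample and panel. Panel genes absent from
#' the matrix are reported via a message; a panel with no measured gene at
#' all is skipped with a warning.
#'
#' @param expr Numeric matrix, genes x samples (log2-scale abundances), with
#'   gene rownames and sample colnames.
#' @param panels Named list of gene-id vectors; default [builtin_panels()].
#' @param tau Rank-weight exponent; default 0.25.
#' @param normalize If `TRUE`, divide all scores by the overall score range
#'   across the table (the across-sample renormalization some ssGSEA
#'   implementations apply). Off by default: group comparisons are
#'   rank-based and unaffected.
#' @return Numeric matrix samples x panels with attribute `tau`, class
#'   `"score_table"`.
#' @export
score_panels <- function(expr, panels = builtin_panels(), tau = 0.25,
                         normalize = FALSE) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("'expr' must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("'expr' must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in 'expr'")
  if (is.null(names(panels)) || any(!nzchar(names(panels)))) {
    stop("'panels' must be a named list")
  }

  keep <- vapply(panels, function(g) sum(g %in% rownames(expr)) > 0L,
                 logical(1L))
  if (any(!keep)) {
    warning("panel(s) with no measured gene skipped: ",
            paste(names(panels)[!keep], collapse = ", "))
    panels <- panels[keep]
  }
  if (length(panels) == 0L) stop("no scorable panel")
  for (nm in names(panels)) {
    absent <- setdiff(panels[[nm]], rownames(expr))
    if (length(absent) > 0L) {
      message("panel '", nm, "': ", length(absent),
              " gene(s) not measured: ", paste(absent, collapse = ", "))
    }
  }

  scores <- vapply(names(panels), function(nm) {
    apply(expr, 2L, ssgsea_score, gene_set = panels[[nm]], tau = tau)
  }, numeric(ncol(expr)))
  scores <- matrix(scores, nrow = ncol(expr),
                   dimnames = list(colnames(expr), names(panels)))
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, tau = tau, class = c("score_table", class(scores)))
}

#' Differential expression by rank test
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two groups on
#' log2-scale values, Benjamini-Hochberg adjustment across genes, and the
#' retention rule `|log2 fold change| > fc_threshold` (strict) and adjusted
#' p below `alpha`. The fold change is the difference of group means on the
#' log2 scale (first factor level minus second).
#'
#' @param expr Numeric genes x samples matrix (log2 scale).
#' @param labels Per-sample two-group factor (or coercible), aligned with
#'   `colnames(expr)` order, or named by sample id.
#' @param fc_threshold Retention threshold on |log2 fold change|; default 1.5.
#' @param alpha Adjusted-p cutoff; default 0.05.
#' @param all If `TRUE` return every gene with a `significant` flag instead
#'   of only the retained records.
#' @return Data frame `gene`, `log2_fc`, `p_raw`, `p_adj`, `direction`
#'   (up/down in the first group), ordered by `p_adj`.
#' @export
differential_expression <- function(expr, labels, fc_threshold = 1.5,
                                    alpha = 0.05, all = FALSE) {
  lab <- align_two_group_labels(labels, colnames(expr))
  g1 <- lab == levels(lab)[1L]
  if (sum(g1) < 3L || sum(!g1) < 3L) {
    stop("each group needs at least 3 samples")
  }
  lfc <- rowMeans(expr[, g1, drop = FALSE]) -
    rowMeans(expr[, !g1, drop = FALSE])
  p <- apply(expr, 1L, function(v) rank_sum_p(v[g1], v[!g1]))
  res <- data.frame(gene = rownames(expr), log2_fc = unname(lfc),
                    p_raw = unname(p),
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  res$direction <- ifelse(res$log2_fc > 0, "up", "down")
  res$significant <- abs(res$log2_fc) > fc_threshold & res$p_adj < alpha &
    !is.na(res$p_adj)
  res <- res[order(res$p_adj, res$gene), ]
  rownames(res) <- NULL
  if (all) res else res[res$significant,
                        setdiff(names(res), "significant"), drop = FALSE]
}

#' Compare a per-sample score between groups
#'
#' Two groups: two-sided Wilcoxon rank-sum test. More than two groups:
#' Kruskal-Wallis. Used for panel scores, single-gene expression, TMB,
#' aneuploidy scores — any per-sample real value.
#'
#' @param values Named or positional numeric vector of per-sample values.
#' @param labels Group labels aligned with `values` (or named by sample id).
#' @return List with `statistic`, `p_value`, `method`, `n_groups`.
#' @export
compare_group_scores <- function(values, labels) {
  if (!is.null(names(values)) && !is.null(names(labels))) {
    labels <- labels[names(values)]
  }
  if (length(values) != length(labels)) {
    stop("'values' and 'labels' lengths differ")
  }
  lab <- droplevels(as.factor(labels))
  if (nlevels(lab) < 2L) stop("need at least 2 non-empty groups")
  if (any(table(lab) == 0L)) stop("empty group")
  if (nlevels(lab) == 2L) {
    ht <- suppressWarnings(
      stats::wilcox.test(values[lab == levels(lab)[1L]],
                         values[lab == levels(lab)[2L]]))
  } else {
    ht <- stats::kruskal.test(values, lab)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method, n_groups = nlevels(lab))
}

# Two-sided rank-sum p. Without ties wilcox.test is exact for small n; with
# ties and a small enumerable design the permutation null of the midrank-sum
# statistic is enumerated exactly, else the normal approximation is used.
rank_sum_p <- function(x, y, max_enum = 1e5) {
  if (!anyDuplicated(c(x, y))) {
    return(suppressWarnings(stats::wilcox.test(x, y)$p.value))
  }
  n1 <- length(x)
  n <- n1 + length(y)
  if (choose(n, n1) <= max_enum) {
    r <- rank(c(x, y))
    obs <- abs(sum(r[seq_len(n1)]) - n1 * (n + 1) / 2)
    combs <- utils::combn(n, n1)
    w <- colSums(matrix(r[combs], nrow = n1))
    return(mean(abs(w - n1 * (n + 1) / 2) >= obs - 1e-9))
  }
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

# Align a two-group label vector to a sample-id order and check group count.
align_two_group_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    if (!all(sample_ids %in% names(labels))) {
      stop("labels missing for some samples")
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("'labels' length must match the number of samples")
  }
  lab <- droplevels(as.factor(labels))
  if (nlevels(lab) != 2L) stop("exactly two groups required")
  lab
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1L)), path)
  invisible(path)
}

#' Shipped editable gene lists
#'
#' `checkpoint_genes()` returns the default immune-checkpoint gene list
#' (21 genes; the named differential set plus canonical checkpoint members,
#' user-replaceable). `stemness_panel()` reads the stemness GMT — the
#' shipped file is a synthetic 109-entry placeholder, since the real panel
#' is defined in external work; supply your own GMT for real analyses.
#'
#' @param path File to read; defaults to the shipped copies.
#' @return Character vector of genes (`checkpoint_genes`) or a one-element
#'   named list (`stemness_panel`).
#' @export
checkpoint_genes <- function(path = system.file("extdata",
                                                "checkpoint_genes.txt",
                                                package = "dnamdrift")) {
  readLines(path)
}

#' @rdname checkpoint_genes
#' @export
stemness_panel <- function(path = system.file("extdata",
                                              "stemness_panel_synthetic.gmt",
                                              package = "dnamdrift")) {
  read_gmt(path)
}
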