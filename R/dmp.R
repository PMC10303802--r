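#' Call differentially methylated probes between two groups
#'
#' Per probe: delta beta = group-1 mean minus group-2 mean of beta values,
#' two-sided Wilcoxon rank-sum p, Benjamini-Hochberg adjustment over all
#' tested probes. A probe is retained iff `|delta_beta| > delta_threshold`
#' (strict) and adjusted p < `alpha`. Probes in `exclude_probes` — typically
#' the union of the clock CpG sets, whose age-related drift would otherwise
#' dominate the comparison — are never tested. Probes with all values
#' missing in either group are skipped, with the count reported.
#'
#' @param beta Numeric probes x samples matrix of beta values (rownames,
#'   colnames required; values in \[0,1\] or `NA`).
#' @param labels Two-group per-sample labels (aligned with columns, or named
#'   by sample id). Delta beta is first level minus second.
#' @param exclude_probes Character vector of probe ids to exclude from
#'   testing (e.g. `unlist(lapply(clocks, function(cl) names(coef(cl))))`).
#' @param delta_threshold Strict retention threshold on |delta beta|;
#'   default 0.20.
#' @param alpha Adjusted-p cutoff; default 0.05.
#' @param adjust Multiple-testing method, `"BH"` (default) or `"bonferroni"`.
#' @param all If `TRUE`, return every tested probe with a `significant`
#'   flag instead of only retained records.
#' @return Data frame `probe_id`, `delta_beta`, `p_raw`, `p_adj`,
#'   `direction` (`hyper`/`hypo` in the first group), with attribute
#'   `n_tested`.
#' @export
call_dmps <- function(beta, labels, exclude_probes = character(),
                      delta_threshold = 0.20, alpha = 0.05,
                      adjust = c("BH", "bonferroni"), all = FALSE) {
  adjust <- match.arg(adjust)
  beta <- validate_beta_matrix(beta)
  lab <- align_two_group_labels(labels, colnames(beta))
  g1 <- lab == levels(lab)[1L]
  if (sum(g1) < 3L || sum(!g1) < 3L) {
    stop("each group needs at least 3 samples")
  }

  beta <- beta[!(rownames(beta) %in% exclude_probes), , drop = FALSE]
  ok1 <- rowSums(!is.na(beta[, g1, drop = FALSE])) > 0L
  ok2 <- rowSums(!is.na(beta[, !g1, drop = FALSE])) > 0L
  skipped <- sum(!(ok1 & ok2))
  if (skipped > 0L) {
    message(skipped, " probe(s) skipped: all values missing in one group")
    beta <- beta[ok1 & ok2, , drop = FALSE]
  }
  if (nrow(beta) == 0L) {
    out <- data.frame(probe_id = character(), delta_beta = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
    attr(out, "n_tested") <- 0L
    return(out)
  }

  delta <- rowMeans(beta[, g1, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, !g1, drop = FALSE], na.rm = TRUE)
  p <- apply(beta, 1L, function(v) {
    rank_sum_p(v[g1][!is.na(v[g1])], v[!g1][!is.na(v[!g1])])
  })
  res <- data.frame(probe_id = rownames(beta), delta_beta = unname(delta),
                    p_raw = unname(p),
                    p_adj = stats::p.adjust(p, method = adjust),
                    stringsAsFactors = FALSE)
  res$direction <- ifelse(res$delta_beta > 0, "hyper", "hypo")
  res$significant <- abs(res$delta_beta) > delta_threshold &
    res$p_adj < alpha & !is.na(res$p_adj)
  res <- res[order(res$p_adj, res$probe_id), ]
  rownames(res) <- NULL
  n_tested <- nrow(res)
  if (!all) res <- res[res$significant,
                       setdiff(names(res), "significant"), drop = FALSE]
  attr(res, "n_tested") <- n_tested
  res
}

#' Genomic-region composition of DMPs
#'
#' Tabulates retained DMPs by CpG-island relation and by gene region,
#' split by direction (hypo/hyper). Island-relation fractions sum to 1 per
#' direction (each probe has exactly one relation); gene-region counting is
#' multi-membership — a probe annotated `TSS200;Body` contributes one
#' assignment to each region, and fractions are over probe-region
#' assignments. A per-chromosome count table is also returned. Probes
#' missing from the annotation fall into an `unknown` bucket with a warning.
#'
#' @param dmps Output of [call_dmps()] (retained records).
#' @param annotation Probe annotation data frame from
#'   [read_probe_manifest()] (columns `probe_id`, `chromosome`,
#'   `island_relation`, `gene_region`).
#' @return List of data frames `island`, `gene_region`, `chromosome`, each
#'   with columns `direction`, `region` (or `chromosome`), `count`,
#'   `fraction`.
#' @export
region_composition <- function(dmps, annotation) {
  empty <- function(col) data.frame(direction = character(),
                                    region = character(),
                                    count = integer(), fraction = numeric(),
                                    stringsAsFactors = FALSE)
  if (nrow(dmps) == 0L) {
    return(list(island = empty(), gene_region = empty(),
                chromosome = empty()))
  }
  idx <- match(dmps$probe_id, annotation$probe_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " DMP probe(s) without annotation ",
            "counted as 'unknown'")
  }

  frac_table <- function(direction, region) {
    tab <- as.data.frame(table(direction = direction, region = region),
                         stringsAsFactors = FALSE)
    names(tab)[3L] <- "count"
    tab <- tab[tab$count > 0L, ]
    tot <- stats::ave(tab$count, tab$direction, FUN = sum)
    tab$fraction <- tab$count / tot
    rownames(tab) <- NULL
    tab
  }

  island <- ifelse(is.na(idx), "unknown", annotation$island_relation[idx])
  chrom <- ifelse(is.na(idx), "unknown", annotation$chromosome[idx])

  # gene regions: expand multi-membership assignments
  gr_str <- ifelse(is.na(idx), "unknown", annotation$gene_region[idx])
  gr_str[!nzchar(gr_str)] <- "intergenic"
  gr_list <- strsplit(gr_str, ";", fixed = TRUE)
  gr_dir <- rep(dmps$direction, lengths(gr_list))

  chrom_tab <- frac_table(dmps$direction, chrom)
  names(chrom_tab)[2L] <- "chromosome"
  list(island = frac_table(dmps$direction, island),
       gene_region = frac_table(gr_dir, unlist(gr_list)),
       chromosome = chrom_tab)
}

#' Read a 450K-style probe annotation manifest
#'
#' Expects a CSV with columns `IlmnID`, `CHR`, `MAPINFO`,
#' `Relation_to_UCSC_CpG_Island`, `UCSC_RefGene_Group` (the manifest
#' column layout). Island relations `N_Shore`/`S_Shore` collapse to
#' `Shore`, `N_Shelf`/`S_Shelf` to `Shelf`, and empty values to `GenePoor`
#' (open-sea probes). Gene regions stay as a semicolon-separated string of
#' unique region memberships.
#'
#' @param path Manifest CSV path.
#' @return Data frame `probe_id`, `chromosome`, `position`,
#'   `island_relation`, `gene_region`.
#' @export
read_probe_manifest <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = character())
  req <- c("IlmnID", "CHR", "MAPINFO", "Relation_to_UCSC_CpG_Island",
           "UCSC_RefGene_Group")
  if (!all(req %in% names(tab))) {
    stop("manifest must have columns ", paste(req, collapse = ", "))
  }
  rel <- tab$Relation_to_UCSC_CpG_Island
  rel[rel %in% c("N_Shore", "S_Shore")] <- "Shore"
  rel[rel %in% c("N_Shelf", "S_Shelf")] <- "Shelf"
  rel[!nzchar(rel)] <- "GenePoor"
  bad <- !rel %in% c("Island", "Shore", "Shelf", "GenePoor")
  if (any(bad)) {
    stop("unrecognized island relation(s): ",
         paste(unique(tab$Relation_to_UCSC_CpG_Island[bad]), collapse = ", "))
  }
  gr <- vapply(strsplit(tab$UCSC_RefGene_Group, ";", fixed = TRUE),
               function(x) paste(unique(x[nzchar(x)]), collapse = ";"),
               character(1L))
  data.frame(probe_id = tab$IlmnID, chromosome = as.character(tab$CHR),
             position = as.integer(tab$MAPINFO), island_relation = rel,
             gene_region = gr, stringsAsFactors = FALSE)
}
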