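#' Pipeline configuration
#'
#' Collects the file paths and thresholds the end-to-end run needs. Clocks
#' are given as named coefficient-CSV paths with matching transform kinds;
#' the first clock name is the primary (candidate-defining) clock and the
#' second the confirmation clock for the hDNAmad rule. All inputs are the
#' formats [write_bundle()] emits.
#'
#' @param beta,expression,clinical,mutations,arm_calls,manifest Input file
#'   paths (beta/expression TSV matrices, clinical TSV, MAF-like TSV,
#'   sample x arm TSV, manifest CSV).
#' @param clocks Named character vector of clock coefficient CSV paths
#'   (exactly two: primary first).
#' @param clock_transforms Character vector of transform kinds aligned with
#'   `clocks`; default piecewise for the first, identity for the second.
#' @param out_dir Output directory for stage TSVs and the summary table.
#' @param band Matched-band half-width in years; default 3.
#' @param fraction Tercile fraction of the hDNAmad rule; default 1/3.
#' @param tau ssGSEA rank-weight exponent; default 0.25.
#' @param dmp_delta,dmp_alpha DMP retention thresholds; defaults 0.20, 0.05.
#' @param deg_fc,deg_alpha DEG retention thresholds; defaults 1.5, 0.05.
#' @param endpoint `"os"` or `"pfs"`; default `"os"`.
#' @param callable_mb TMB denominator in Mb; default 38.
#' @param missing_policy Clock missing-probe policy; default
#'   `"impute_cohort_mean"`.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(beta, expression, clinical, mutations,
                            arm_calls, manifest, clocks,
                            clock_transforms = c("piecewise_log_linear",
                                                 "identity"),
                            out_dir, band = 3, fraction = 1 / 3,
                            tau = 0.25, dmp_delta = 0.20, dmp_alpha = 0.05,
                            deg_fc = 1.5, deg_alpha = 0.05,
                            endpoint = c("os", "pfs"), callable_mb = 38,
                            missing_policy = "impute_cohort_mean") {
  endpoint <- match.arg(endpoint)
  if (length(clocks) != 2L || is.null(names(clocks))) {
    stop("'clocks' must be two named coefficient-file paths")
  }
  if (length(clock_transforms) != 2L) {
    stop("'clock_transforms' must have two entries")
  }
  cfg <- list(beta = beta, expression = expression, clinical = clinical,
              mutations = mutations, arm_calls = arm_calls,
              manifest = manifest, clocks = clocks,
              clock_transforms = clock_transforms, out_dir = out_dir,
              band = band, fraction = fraction, tau = tau,
              dmp_delta = dmp_delta, dmp_alpha = dmp_alpha,
              deg_fc = deg_fc, deg_alpha = deg_alpha, endpoint = endpoint,
              callable_mb = callable_mb, missing_policy = missing_policy)
  structure(cfg, class = "pipeline_config")
}

#' Convenience: pipeline config over a written bundle directory
#'
#' @param dir Directory produced by [write_bundle()].
#' @param out_dir Output directory; default `file.path(dir, "results")`.
#' @param ... Passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
bundle_pipeline_config <- function(dir, out_dir = file.path(dir, "results"),
                                   ...) {
  clock_files <- list.files(dir, pattern = "^clock_.*\\.csv$")
  nm <- sub("^clock_(.*)\\.csv$", "\\1", clock_files)
  # primary = the piecewise (horvath-like) clock when present
  ord <- order(!grepl("horvath", nm))
  clocks <- stats::setNames(file.path(dir, clock_files[ord]), nm[ord])
  tfk <- ifelse(grepl("horvath", names(clocks)),
                "piecewise_log_linear", "identity")
  pipeline_config(beta = file.path(dir, "beta.tsv"),
                  expression = file.path(dir, "expression.tsv"),
                  clinical = file.path(dir, "clinical.tsv"),
                  mutations = file.path(dir, "mutations.tsv"),
                  arm_calls = file.path(dir, "arm_calls.tsv"),
                  manifest = file.path(dir, "manifest.csv"),
                  clocks = clocks, clock_transforms = tfk,
                  out_dir = out_dir, ...)
}

#' Run the full stratification pipeline
#'
#' Stages: clock prediction -> drift classification and hDNAmad selection ->
#' signature scoring and expression comparison -> DMP calling with clock-CpG
#' exclusion and region composition -> aneuploidy/TMB comparison ->
#' survival association (KM + log-rank + uni/multivariate Cox). Each stage
#' writes its TSV into `out_dir`; a `summary.tsv` collects the headline
#' numbers. Any stage failure aborts with the stage name. The run is a pure
#' function of inputs and config: rerunning on identical inputs reproduces
#' every output byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Path of the output directory, invisibly; the summary data frame
#'   as attribute `"summary"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  tsv <- function(d, f) utils::write.table(d, out(f), sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  summ <- list()
  note <- function(stage, metric, value) {
    summ[[length(summ) + 1L]] <<- data.frame(
      stage = stage, metric = metric,
      value = as.character(value), stringsAsFactors = FALSE)
  }

  ## clocks -----------------------------------------------------------------
  preds <- stage("clocks", {
    beta <- read_beta_matrix(cfg$beta)
    clocks <- lapply(seq_along(cfg$clocks), function(i) {
      read_clock(cfg$clocks[[i]], name = names(cfg$clocks)[i],
                 transform = transform_spec(cfg$clock_transforms[i]))
    })
    do.call(rbind, lapply(clocks, predict, beta = beta,
                          missing_policy = cfg$missing_policy))
  })
  tsv(preds, "dnam_age.tsv")

  ## acceleration ------------------------------------------------------------
  labels <- stage("acceleration", {
    clinical <- utils::read.delim(cfg$clinical, stringsAsFactors = FALSE)
    chron <- stats::setNames(clinical$age, clinical$sample_id)
    drift <- compute_drift(chron, preds, band = cfg$band)
    tsv(drift, "drift.tsv")
    for (cl in names(cfg$clocks)) {
      cs <- cohort_summary(drift, cl)
      note("acceleration", paste0(cl, "_mad_yr"), sprintf("%.4f", cs$mad))
      note("acceleration", paste0(cl, "_pearson_r"),
           sprintf("%.4f", cs$pearson_r))
    }
    lab <- select_hdnamad(drift, names(cfg$clocks)[1L],
                          names(cfg$clocks)[2L], fraction = cfg$fraction)
    tsv(data.frame(sample_id = names(lab), hdnamad = as.integer(lab)),
        "hdnamad_labels.tsv")
    note("acceleration", "n_candidates", attr(lab, "n_candidates"))
    note("acceleration", "tercile_size", attr(lab, "tercile_size"))
    note("acceleration", "n_positive", sum(lab))
    note("acceleration", "n_negative", sum(!lab))
    lab
  })
  group <- factor(ifelse(labels, "hDNAmad_pos", "hDNAmad_neg"),
                  levels = c("hDNAmad_pos", "hDNAmad_neg"))
  names(group) <- names(labels)

  ## signatures ---------------------------------------------------------------
  stage("signatures", {
    expr <- read_id_matrix(cfg$expression)
    expr <- expr[, names(group), drop = FALSE]
    scores <- suppressMessages(score_panels(expr, tau = cfg$tau))
    tsv(data.frame(sample_id = rownames(scores), unclass(scores),
                   check.names = FALSE), "panel_scores.tsv")
    tests <- do.call(rbind, lapply(colnames(scores), function(p) {
      ct <- compare_group_scores(scores[, p], group)
      data.frame(panel = p,
                 mean_pos = mean(scores[group == "hDNAmad_pos", p]),
                 mean_neg = mean(scores[group == "hDNAmad_neg", p]),
                 statistic = ct$statistic, p_value = ct$p_value,
                 stringsAsFactors = FALSE)
    }))
    tsv(tests, "panel_score_tests.tsv")
    for (i in seq_len(nrow(tests))) {
      note("signatures", paste0(tests$panel[i], "_p"),
           sprintf("%.3g", tests$p_value[i]))
    }
    if (all(table(group) >= 3L)) {
      degs <- differential_expression(expr, group, cfg$deg_fc,
                                      cfg$deg_alpha)
      tsv(degs, "degs.tsv")
      note("signatures", "n_degs", nrow(degs))
    }
  })

  ## dmp ----------------------------------------------------------------------
  stage("dmp", {
    beta <- read_beta_matrix(cfg$beta)
    manifest <- read_probe_manifest(cfg$manifest)
    clock_probes <- unlist(lapply(seq_along(cfg$clocks), function(i) {
      names(coef(read_clock(cfg$clocks[[i]]))) }))
    if (all(table(group) >= 3L)) {
      dmps <- suppressMessages(
        call_dmps(beta[, names(group), drop = FALSE], group,
                  exclude_probes = clock_probes,
                  delta_threshold = cfg$dmp_delta, alpha = cfg$dmp_alpha))
      tsv(dmps, "dmps.tsv")
      comp <- region_composition(dmps, manifest)
      tsv(comp$island, "dmp_island_composition.tsv")
      tsv(comp$gene_region, "dmp_gene_region_composition.tsv")
      tsv(comp$chromosome, "dmp_chromosome_counts.tsv")
      note("dmp", "n_dmps", nrow(dmps))
      note("dmp", "n_hypo", sum(dmps$direction == "hypo"))
      note("dmp", "n_hyper", sum(dmps$direction == "hyper"))
    }
  })

  ## genomics -------------------------------------------------------------------
  stage("genomics", {
    arm_tab <- utils::read.delim(cfg$arm_calls, check.names = FALSE,
                                 stringsAsFactors = FALSE)
    calls <- as.matrix(arm_tab[, -1L, drop = FALSE])
    rownames(calls) <- arm_tab[[1L]]
    aneu <- aneuploidy_score(calls)[names(group)]
    muts <- read_maf(cfg$mutations)
    burden <- tmb(muts, callable_mb = cfg$callable_mb,
                  samples = names(group))
    tsv(data.frame(sample_id = names(group), aneuploidy = aneu,
                   tmb = sprintf("%.6g", burden)), "genomic_scores.tsv")
    at <- compare_group_scores(aneu, group)
    tt <- compare_group_scores(burden, group)
    note("genomics", "aneuploidy_p", sprintf("%.3g", at$p_value))
    note("genomics", "tmb_p", sprintf("%.3g", tt$p_value))
  })

  ## survival ---------------------------------------------------------------------
  stage("survival", {
    clinical <- utils::read.delim(cfg$clinical, stringsAsFactors = FALSE)
    clinical <- clinical[match(names(group), clinical$sample_id), ]
    clinical$hdnamad <- as.integer(labels[clinical$sample_id])
    time_col <- paste0(cfg$endpoint, "_time")
    event_col <- paste0(cfg$endpoint, "_event")
    lr <- logrank_test(clinical, time_col, event_col, "hdnamad")
    note("survival", "logrank_chisq", sprintf("%.4f", lr$chisq))
    note("survival", "logrank_p", sprintf("%.3g", lr$p_value))
    covs <- "hdnamad"
    # dichotomized clinical covariates, where present
    if ("age" %in% names(clinical)) {
      clinical$age_ge60 <- as.integer(clinical$age >= 60)
      covs <- c(covs, "age_ge60")
    }
    if ("stage" %in% names(clinical)) {
      clinical$stage_advanced <- as.integer(clinical$stage %in%
                                              c("III", "IV"))
      covs <- c(covs, "stage_advanced")
    }
    if ("grade" %in% names(clinical)) {
      clinical$grade_high <- as.integer(clinical$grade == "G3")
      covs <- c(covs, "grade_high")
    }
    if ("histology" %in% names(clinical)) {
      clinical$nonendometrioid <- as.integer(clinical$histology !=
                                               "endometrioid")
      covs <- c(covs, "nonendometrioid")
    }
    uni <- cox_fit(clinical, time_col, event_col, covs, univariate = TRUE)
    multi <- cox_fit(clinical, time_col, event_col, covs)
    uni$analysis <- "univariate"
    multi$analysis <- "multivariate"
    cox_tab <- rbind(uni, multi)
    for (col in c("hr", "ci_low", "ci_high", "p_value")) {
      cox_tab[[col]] <- sprintf("%.5g", cox_tab[[col]])
    }
    tsv(cox_tab, "cox.tsv")
    hr_row <- uni[uni$term == "hdnamad", ]
    note("survival", "hdnamad_univariate_hr", sprintf("%.4f", hr_row$hr))
    note("survival", "hdnamad_univariate_p",
         sprintf("%.3g", hr_row$p_value))
  })

  summary_tab <- do.call(rbind, summ)
  tsv(summary_tab, "summary.tsv")
  res <- cfg$out_dir
  attr(res, "summary") <- summary_tab
  invisible(res)
}
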