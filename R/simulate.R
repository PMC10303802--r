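#' Synthetic cohort configuration
#'
#' Defines the statistical structure of a simulated tumor cohort: two
#' synthetic clocks whose noise-free beta values encode each sample's target
#' DNAm age; a truth-positive subgroup whose target age is rejuvenated by
#' `rejuvenation_offset_years` on both clocks; background probes with a
#' marked differentially methylated effect subset; signature-panel
#' expression shifts; exponential survival with a group hazard ratio; and
#' group-dependent mutation counts and arm-call rates. Defaults follow the
#' cohort structure the analysis targets: a 429-tumor cohort with ~19%
#' dual-clock high-deceleration prevalence and a 15-year rejuvenation
#' offset.
#'
#' @param n_samples Cohort size; default 429.
#' @param age_range Chronological age range in years; default c(40, 90).
#' @param clock_sizes Named integer vector: probes per synthetic clock. The
#'   first clock uses the piecewise log/linear transform, the second the
#'   identity transform. Default `c(horvath_like = 100, phenoage_like = 100)`.
#' @param hdnamad_prevalence Truth-positive fraction; default 0.19.
#' @param rejuvenation_offset_years Deceleration delta in years injected
#'   into truth-positives on both clocks; default 15.
#' @param beta_noise_sd Gaussian noise SD added to clock betas (clipped to
#'   \[0,1\]); default 0.01.
#' @param n_background_probes Non-clock probes; default 300.
#' @param n_effect_probes Background probes carrying a group beta shift;
#'   default 40.
#' @param effect_delta_beta Mean beta shift of effect probes; default 0.30.
#' @param effect_hypo_fraction Fraction of effect probes hypomethylated in
#'   truth-positives; default 0.9.
#' @param n_background_genes Non-panel expression genes; default 200.
#' @param panel_effect_log2 Log2 expression shift in truth-positives: +shift
#'   on cell-cycle/telomerase panel genes, -shift on myeloid/T-effector
#'   genes; default 2.
#' @param hazard_ratio Hazard multiplier of truth-positives; default 2.
#' @param censoring_rate Target fraction of censored records under uniform
#'   censoring; default 0.6.
#' @param mutation_rate_by_group Poisson mean mutation counts
#'   `c(neg = , pos = )`; default c(neg = 120, pos = 40) (lower burden in
#'   the decelerated group).
#' @param arm_alteration_prob_by_group Per-arm alteration probability
#'   `c(neg = , pos = )`; default c(neg = 0.10, pos = 0.35) (higher
#'   aneuploidy in the decelerated group).
#' @param seed Integer master seed; independent substreams are derived from
#'   it per table, so regenerating one table never perturbs the others.
#' @return Validated config list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 429,
                          age_range = c(40, 90),
                          clock_sizes = c(horvath_like = 100,
                                          phenoage_like = 100),
                          hdnamad_prevalence = 0.19,
                          rejuvenation_offset_years = 15,
                          beta_noise_sd = 0.01,
                          n_background_probes = 300,
                          n_effect_probes = 40,
                          effect_delta_beta = 0.30,
                          effect_hypo_fraction = 0.9,
                          n_background_genes = 200,
                          panel_effect_log2 = 2,
                          hazard_ratio = 2,
                          censoring_rate = 0.6,
                          mutation_rate_by_group = c(neg = 120, pos = 40),
                          arm_alteration_prob_by_group = c(neg = 0.10,
                                                           pos = 0.35),
                          seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples), age_range = age_range,
              clock_sizes = clock_sizes,
              hdnamad_prevalence = hdnamad_prevalence,
              rejuvenation_offset_years = rejuvenation_offset_years,
              beta_noise_sd = beta_noise_sd,
              n_background_probes = as.integer(n_background_probes),
              n_effect_probes = as.integer(n_effect_probes),
              effect_delta_beta = effect_delta_beta,
              effect_hypo_fraction = effect_hypo_fraction,
              n_background_genes = as.integer(n_background_genes),
              panel_effect_log2 = panel_effect_log2,
              hazard_ratio = hazard_ratio,
              censoring_rate = censoring_rate,
              mutation_rate_by_group = mutation_rate_by_group,
              arm_alteration_prob_by_group = arm_alteration_prob_by_group,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 1L) stop("'n_samples' must be at least 1")
    if (length(age_range) != 2L || age_range[1L] <= 0 ||
        age_range[2L] <= age_range[1L]) {
      stop("'age_range' must be an increasing positive pair")
    }
    if (length(clock_sizes) != 2L || is.null(names(clock_sizes)) ||
        any(clock_sizes < 2L)) {
      stop("'clock_sizes' must name two clocks of at least 2 probes each")
    }
    if (hdnamad_prevalence < 0 || hdnamad_prevalence > 1) {
      stop("'hdnamad_prevalence' must be in [0,1]")
    }
    if (rejuvenation_offset_years < 0) {
      stop("'rejuvenation_offset_years' must be >= 0")
    }
    if (beta_noise_sd < 0) stop("'beta_noise_sd' must be >= 0")
    if (n_effect_probes > n_background_probes) {
      stop("more effect probes than background probes")
    }
    if (effect_delta_beta < 0 || effect_delta_beta > 1 ||
        effect_hypo_fraction < 0 || effect_hypo_fraction > 1) {
      stop("effect parameters out of range")
    }
    if (hazard_ratio <= 0) stop("'hazard_ratio' must be positive")
    if (censoring_rate < 0 || censoring_rate >= 1) {
      stop("'censoring_rate' must be in [0,1)")
    }
    if (length(mutation_rate_by_group) != 2L ||
        any(mutation_rate_by_group < 0)) {
      stop("'mutation_rate_by_group' must be two non-negative means")
    }
    if (length(arm_alteration_prob_by_group) != 2L ||
        any(arm_alteration_prob_by_group < 0) ||
        any(arm_alteration_prob_by_group > 1)) {
      stop("'arm_alteration_prob_by_group' must be two probabilities")
    }
  })
  invisible(cfg)
}

# Seed a substream deterministically from the master seed. Offsets are
# small so derived seeds stay far below .Machine$integer.max.
substream <- function(seed, k) set.seed(seed * 101L + k)

# Build one synthetic clock whose noise-free betas encode a target
# transformed age exactly: beta = b0 + w * (t - t_ref) / sum(w^2), the
# minimum-norm solution of intercept + w.beta = t.
make_synthetic_clock <- function(name, n_probes, transform, prefix,
                                 age_range) {
  w_scale <- if (transform$kind == "identity") {
    # identity clocks predict in years: larger weights keep the per-probe
    # beta adjustment small over a decades-wide target range
    6 * diff(age_range) / n_probes
  } else {
    1
  }
  w <- stats::runif(n_probes, 0.2, 1) *
    sample(c(-1, 1), n_probes, replace = TRUE) * w_scale
  names(w) <- sprintf("%s%04d", prefix, seq_len(n_probes))
  b0 <- stats::runif(n_probes, 0.25, 0.75)
  t_ref <- age_transform(mean(age_range), transform)
  intercept <- t_ref - sum(w * b0)
  list(clock = clock_model(name, intercept, w, transform),
       b0 = b0, t_ref = t_ref)
}

# Noise-free beta block encoding per-sample target transformed ages.
clock_beta_block <- function(ck, targets_t) {
  w <- ck$clock$coefficients
  shift <- (targets_t - ck$t_ref) / sum(w^2)
  ck$b0 + outer(w, shift) # probes x samples
}

#' Simulate a cohort bundle
#'
#' Generates, from one master seed, all tables the pipeline consumes:
#' a beta matrix (two clock blocks plus background probes with a marked
#' effect subset), a log2-scale expression matrix with panel shifts, a
#' clinical table with exponential survival under a group hazard ratio and
#' uniform censoring, a MAF-like mutation table, arm-level copy-number
#' calls, a probe annotation manifest, the two synthetic clock models and
#' the ground-truth subgroup labels. Noise-free clock betas reproduce each
#' sample's target DNAm age exactly; truth-positives target
#' `chron - rejuvenation_offset_years` on both clocks.
#'
#' @param config A [cohort_config()].
#' @return List of class `"cohort_bundle"`: `beta`, `expression`,
#'   `clinical`, `mutations`, `arm_calls`, `manifest`, `clocks`, `truth`
#'   (named logical), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  ## -- ages and truth labels ---------------------------------------------
  substream(cfg$seed, 1L)
  age <- round(stats::runif(n, cfg$age_range[1L], cfg$age_range[2L]), 1)
  names(age) <- samples
  truth <- stats::setNames(
    stats::runif(n) < cfg$hdnamad_prevalence, samples)
  target_age <- ifelse(truth, pmax(age - cfg$rejuvenation_offset_years, 1),
                       age)

  ## -- clocks and clock betas --------------------------------------------
  substream(cfg$seed, 2L)
  transforms <- list(transform_spec("piecewise_log_linear"),
                     transform_spec("identity"))
  prefixes <- c("cgA", "cgB")
  clocks <- vector("list", 2L)
  blocks <- vector("list", 2L)
  for (i in 1:2) {
    ck <- make_synthetic_clock(names(cfg$clock_sizes)[i],
                               cfg$clock_sizes[[i]], transforms[[i]],
                               prefixes[i], cfg$age_range)
    clocks[[i]] <- ck$clock
    blocks[[i]] <- clock_beta_block(
      ck, age_transform(target_age, transforms[[i]]))
  }
  names(clocks) <- names(cfg$clock_sizes)

  ## -- background probes with effect subset ------------------------------
  substream(cfg$seed, 3L)
  nb <- cfg$n_background_probes
  bg_ids <- sprintf("bg%04d", seq_len(nb))
  conc <- 6 # beta-distribution concentration: realistic [0,1] dispersion
  mu <- stats::runif(nb, 0.15, 0.85)
  mu_pos <- mu_neg <- mu
  effect_ids <- character()
  effect_dir <- character()
  if (cfg$n_effect_probes > 0L) {
    eff <- seq_len(cfg$n_effect_probes)
    effect_ids <- bg_ids[eff]
    n_hypo <- round(cfg$effect_hypo_fraction * length(eff))
    is_hypo <- seq_along(eff) <= n_hypo
    effect_dir <- ifelse(is_hypo, "hypo", "hyper")
    d <- cfg$effect_delta_beta
    # keep both group means inside [0.05, 0.95] after the +/- d shift
    mu_neg[eff] <- ifelse(is_hypo,
                          stats::runif(length(eff), 0.05 + d, 0.95),
                          stats::runif(length(eff), 0.05, 0.95 - d))
    mu_pos[eff] <- mu_neg[eff] + ifelse(is_hypo, -d, d)
  }
  bg <- matrix(NA_real_, nb, n, dimnames = list(bg_ids, samples))
  for (j in seq_len(n)) {
    m <- if (truth[j]) mu_pos else mu_neg
    bg[, j] <- stats::rbeta(nb, m * conc, (1 - m) * conc)
  }

  ## -- assemble beta matrix, add clock noise, clip -----------------------
  substream(cfg$seed, 4L)
  clock_beta <- do.call(rbind, blocks)
  if (cfg$beta_noise_sd > 0) {
    clock_beta <- clock_beta +
      stats::rnorm(length(clock_beta), sd = cfg$beta_noise_sd)
  }
  colnames(clock_beta) <- samples
  beta <- pmin(pmax(rbind(clock_beta, bg), 0), 1)
  validate_beta_matrix(beta)

  ## -- probe annotation manifest -----------------------------------------
  substream(cfg$seed, 5L)
  manifest <- simulate_manifest(rownames(beta))

  ## -- expression ---------------------------------------------------------
  substream(cfg$seed, 6L)
  panels <- builtin_panels()
  up_genes <- c(panels$cell_cycle, panels$telomerase)
  down_genes <- c(panels$myeloid, panels$Teffector)
  genes <- c(up_genes, down_genes,
             sprintf("GENE%04d", seq_len(cfg$n_background_genes)))
  base <- stats::runif(length(genes), 2, 8)
  expr <- matrix(stats::rnorm(length(genes) * n, mean = base, sd = 1),
                 nrow = length(genes), dimnames = list(genes, samples))
  if (any(truth)) {
    expr[up_genes, truth] <- expr[up_genes, truth] + cfg$panel_effect_log2
    expr[down_genes, truth] <- expr[down_genes, truth] -
      cfg$panel_effect_log2
  }
  expr <- pmax(expr, 0) # log2(x+1) abundances are non-negative

  ## -- clinical and survival ----------------------------------------------
  substream(cfg$seed, 7L)
  clinical <- simulate_clinical(samples, age, truth, cfg)

  ## -- mutations -----------------------------------------------------------
  substream(cfg$seed, 8L)
  mutations <- simulate_mutations(samples, truth, cfg)

  ## -- arm calls ------------------------------------------------------------
  substream(cfg$seed, 9L)
  arms <- autosome_arms()
  p_arm <- ifelse(truth, cfg$arm_alteration_prob_by_group[["pos"]],
                  cfg$arm_alteration_prob_by_group[["neg"]])
  altered <- matrix(stats::runif(n * length(arms)) < rep(p_arm,
                                                         length(arms)),
                    nrow = n, dimnames = list(samples, arms))
  sign <- matrix(sample(c(-1L, 1L), n * length(arms), replace = TRUE),
                 nrow = n)
  arm_calls <- altered * sign
  mode(arm_calls) <- "integer"

  structure(list(beta = beta, expression = expr, clinical = clinical,
                 mutations = mutations, arm_calls = arm_calls,
                 manifest = manifest, clocks = clocks, truth = truth,
                 effect_probes = stats::setNames(effect_dir, effect_ids),
                 config = cfg),
            class = "cohort_bundle")
}

simulate_manifest <- function(probe_ids) {
  np <- length(probe_ids)
  rel <- sample(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", ""),
                np, replace = TRUE,
                prob = c(0.35, 0.12, 0.12, 0.05, 0.05, 0.31))
  regions <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
  gr <- vapply(seq_len(np), function(i) {
    k <- sample(0:2, 1L, prob = c(0.3, 0.5, 0.2))
    paste(sample(regions, k), collapse = ";")
  }, character(1L))
  raw <- data.frame(IlmnID = probe_ids,
                    CHR = sample(as.character(1:22), np, replace = TRUE),
                    MAPINFO = sample.int(2e8, np, replace = TRUE),
                    Relation_to_UCSC_CpG_Island = rel,
                    UCSC_RefGene_Group = gr, stringsAsFactors = FALSE)
  rel2 <- rel
  rel2[rel2 %in% c("N_Shore", "S_Shore")] <- "Shore"
  rel2[rel2 %in% c("N_Shelf", "S_Shelf")] <- "Shelf"
  rel2[!nzchar(rel2)] <- "GenePoor"
  data.frame(probe_id = probe_ids, chromosome = raw$CHR,
             position = raw$MAPINFO, island_relation = rel2,
             gene_region = gr, stringsAsFactors = FALSE)
}

simulate_clinical <- function(samples, age, truth, cfg) {
  n <- length(samples)
  rexp_group <- function(base_median) {
    lambda <- log(2) / base_median *
      ifelse(truth, cfg$hazard_ratio, 1)
    stats::rexp(n, rate = lambda)
  }
  os_t <- rexp_group(60)
  pfs_t <- pmin(rexp_group(40), os_t)
  cens <- function(t) {
    if (cfg$censoring_rate == 0) {
      return(list(time = t, event = rep(1L, n)))
    }
    # uniform censoring horizon solved so the expected censored fraction
    # matches the configured rate for the cohort's hazard mixture
    lam <- log(2) / 60 * ifelse(truth, cfg$hazard_ratio, 1)
    p_cens <- function(K) mean((1 - exp(-lam * K)) / (lam * K)) -
      cfg$censoring_rate
    K <- stats::uniroot(p_cens, c(1e-3, 1e5))$root
    C <- stats::runif(n, 0, K)
    list(time = pmax(pmin(t, C), 1e-3), event = as.integer(t <= C))
  }
  os <- cens(os_t)
  pfs <- cens(pfs_t)
  stage <- ifelse(truth,
                  sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                         prob = c(0.15, 0.10, 0.45, 0.30)),
                  sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                         prob = c(0.50, 0.20, 0.20, 0.10)))
  grade <- ifelse(truth,
                  sample(c("G1", "G2", "G3"), n, replace = TRUE,
                         prob = c(0.1, 0.2, 0.7)),
                  sample(c("G1", "G2", "G3"), n, replace = TRUE,
                         prob = c(0.4, 0.35, 0.25)))
  histology <- ifelse(truth,
                      sample(c("endometrioid", "serous", "mixed"), n,
                             replace = TRUE, prob = c(0.3, 0.55, 0.15)),
                      sample(c("endometrioid", "serous", "mixed"), n,
                             replace = TRUE, prob = c(0.8, 0.12, 0.08)))
  data.frame(sample_id = samples, age = unname(age), stage = unname(stage),
             grade = unname(grade), histology = unname(histology),
             os_time = os$time, os_event = os$event,
             pfs_time = pfs$time, pfs_event = pfs$event,
             stringsAsFactors = FALSE)
}

simulate_mutations <- function(samples, truth, cfg) {
  n_mut <- stats::rpois(length(samples),
                        ifelse(truth, cfg$mutation_rate_by_group[["pos"]],
                               cfg$mutation_rate_by_group[["neg"]]))
  gene_pool <- c("TP53", "RB1", "CDKN2A", "PIK3CA", "PTEN", "ARID1A",
                 sprintf("GENE%04d", seq_len(max(cfg$n_background_genes,
                                                 1L))))
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Frame_Shift_Ins", "Splice_Site", "Silent", "3'UTR",
               "Intron")
  class_prob <- c(0.45, 0.08, 0.06, 0.05, 0.06, 0.18, 0.06, 0.06)
  total <- sum(n_mut)
  data.frame(
    sample_id = rep(samples, n_mut),
    gene = sample(gene_pool, total, replace = TRUE),
    variant_class = sample(classes, total, replace = TRUE,
                           prob = class_prob),
    stringsAsFactors = FALSE)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d samples, %d probes, %d genes, ",
                     "%d truth-positive (%.1f%%)\n"),
              ncol(x$beta), nrow(x$beta), nrow(x$expression),
              sum(x$truth), 100 * mean(x$truth)))
  cat("Clocks:", paste(names(x$clocks), collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' Emits every table in the format its consuming module reads (TSV matrices,
#' clinical/mutation TSVs, manifest CSV, clock coefficient CSVs, truth
#' labels) plus a `MANIFEST.txt` of md5 checksums. [read_bundle()] inverts
#' the operation exactly.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory '", dir, "'")
  fp <- function(f) file.path(dir, f)

  write_beta_matrix(bundle$beta, fp("beta.tsv"))
  write_numeric_matrix(bundle$expression, fp("expression.tsv"),
                       id_col = "gene_id")
  write_clinical <- bundle$clinical
  for (col in c("os_time", "pfs_time")) {
    write_clinical[[col]] <- sprintf("%.17g", write_clinical[[col]])
  }
  utils::write.table(write_clinical, fp("clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  maf <- data.frame(Tumor_Sample_Barcode = bundle$mutations$sample_id,
                    Hugo_Symbol = bundle$mutations$gene,
                    Variant_Classification = bundle$mutations$variant_class)
  utils::write.table(maf, fp("mutations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(bundle$arm_calls), bundle$arm_calls,
               check.names = FALSE),
    fp("arm_calls.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  m <- bundle$manifest
  utils::write.table(
    data.frame(IlmnID = m$probe_id, CHR = m$chromosome,
               MAPINFO = m$position,
               Relation_to_UCSC_CpG_Island = restore_relation(m),
               UCSC_RefGene_Group = m$gene_region),
    fp("manifest.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$clocks)) {
    write_clock(bundle$clocks[[nm]], fp(paste0("clock_", nm, ".csv")))
  }
  utils::write.table(
    data.frame(sample_id = names(bundle$truth),
               hdnamad_truth = as.integer(bundle$truth)),
    fp("truth_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  files <- setdiff(list.files(dir), "MANIFEST.txt")
  sums <- tools::md5sum(file.path(dir, files))
  writeLines(paste(unname(sums), files), fp("MANIFEST.txt"))
  invisible(dir)
}

# Island relations are collapsed on read; writing restores a representative
# manifest dialect value (Shore -> N_Shore etc. is not invertible, so the
# collapsed value is kept where the dialect accepts it).
restore_relation <- function(m) {
  r <- m$island_relation
  r[r == "GenePoor"] <- ""
  r
}

#' Read a written cohort bundle
#'
#' @param dir Directory produced by [write_bundle()].
#' @param check_sums Verify md5 checksums against `MANIFEST.txt`
#'   (default `TRUE`).
#' @return List with the on-disk tables: `beta`, `expression`, `clinical`,
#'   `mutations`, `arm_calls`, `manifest`, `clocks`, `truth`.
#' @export
read_bundle <- function(dir, check_sums = TRUE) {
  fp <- function(f) file.path(dir, f)
  if (check_sums) {
    man <- utils::read.table(fp("MANIFEST.txt"), stringsAsFactors = FALSE)
    now <- unname(tools::md5sum(file.path(dir, man$V2)))
    if (!identical(now, man$V1)) {
      stop("checksum mismatch in bundle: ",
           paste(man$V2[now != man$V1], collapse = ", "))
    }
  }
  clocks <- list()
  for (f in list.files(dir, pattern = "^clock_.*\\.csv$")) {
    nm <- sub("^clock_(.*)\\.csv$", "\\1", f)
    tf <- if (grepl("horvath", nm)) transform_spec("piecewise_log_linear")
          else transform_spec("identity")
    clocks[[nm]] <- read_clock(fp(f), name = nm, transform = tf)
  }
  truth_tab <- utils::read.delim(fp("truth_labels.tsv"),
                                 stringsAsFactors = FALSE)
  arm_tab <- utils::read.delim(fp("arm_calls.tsv"), check.names = FALSE,
                               stringsAsFactors = FALSE)
  arm_calls <- as.matrix(arm_tab[, -1L, drop = FALSE])
  rownames(arm_calls) <- arm_tab[[1L]]
  mode(arm_calls) <- "integer"
  list(beta = read_beta_matrix(fp("beta.tsv")),
       expression = read_id_matrix(fp("expression.tsv")),
       clinical = utils::read.delim(fp("clinical.tsv"),
                                    stringsAsFactors = FALSE),
       mutations = read_maf(fp("mutations.tsv")),
       arm_calls = arm_calls,
       manifest = read_probe_manifest(fp("manifest.csv")),
       clocks = clocks,
       truth = stats::setNames(truth_tab$hdnamad_truth == 1L,
                               truth_tab$sample_id))
}
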