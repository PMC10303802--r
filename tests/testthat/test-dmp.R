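# Deterministic two-group beta fixture with one clean differential probe.
dmp_fixture <- function() {
  beta <- rbind(
    flat = rep(0.5, 10),
    clean = c(0.78, 0.79, 0.80, 0.81, 0.82, 0.48, 0.49, 0.50, 0.51, 0.52),
    edge = c(rep(0.60, 5), rep(0.40, 5)), # delta exactly 0.20
    clockcg = c(rep(0.95, 5), rep(0.05, 5))
  )
  colnames(beta) <- paste0("s", 1:10)
  list(beta = beta, labels = rep(c("g1", "g2"), each = 5))
}

test_that("DMP calling applies the exact rank-sum p and strict delta rule", {
  fx <- dmp_fixture()
  res <- suppressWarnings(call_dmps(fx$beta, fx$labels, all = TRUE))
  clean <- res[res$probe_id == "clean", ]
  expect_equal(clean$delta_beta, 0.30, tolerance = 1e-12)
  expect_equal(clean$p_raw, 2 / 252, tolerance = 1e-12)
  expect_equal(res$delta_beta[res$probe_id == "flat"], 0)
  expect_equal(res$delta_beta[res$probe_id == "edge"], 0.20,
               tolerance = 1e-12)

  kept <- suppressWarnings(call_dmps(fx$beta, fx$labels))
  # strict |delta| > 0.20: the edge probe is excluded, flat never retained
  expect_true("clean" %in% kept$probe_id)
  expect_false("edge" %in% kept$probe_id)
  expect_false("flat" %in% kept$probe_id)
  expect_equal(kept$direction[kept$probe_id == "clean"], "hyper")

  # single-probe input: BH leaves the exact p unchanged and retains it
  one <- call_dmps(fx$beta["clean", , drop = FALSE], fx$labels)
  expect_equal(one$p_adj, 2 / 252, tolerance = 1e-12)
  expect_equal(nrow(one), 1L)
})

test_that("excluded clock probes are never tested or emitted", {
  fx <- dmp_fixture()
  res <- suppressWarnings(call_dmps(fx$beta, fx$labels,
                                    exclude_probes = c("clockcg", "clean"),
                                    all = TRUE))
  expect_false(any(c("clockcg", "clean") %in% res$probe_id))
  expect_equal(attr(res, "n_tested"), 2L)
})

test_that("tightening thresholds never adds a probe", {
  set.seed(19)
  beta <- matrix(stats::runif(40 * 12), 40, 12,
                 dimnames = list(sprintf("cg%03d", 1:40), paste0("s", 1:12)))
  beta[1:8, 1:6] <- pmin(beta[1:8, 1:6] + 0.45, 1)
  lab <- rep(c("A", "B"), each = 6)
  loose <- suppressWarnings(call_dmps(beta, lab, delta_threshold = 0.1,
                                      alpha = 0.2))
  tight_d <- suppressWarnings(call_dmps(beta, lab, delta_threshold = 0.3,
                                        alpha = 0.2))
  tight_a <- suppressWarnings(call_dmps(beta, lab, delta_threshold = 0.1,
                                        alpha = 0.01))
  expect_true(all(tight_d$probe_id %in% loose$probe_id))
  expect_true(all(tight_a$probe_id %in% loose$probe_id))
})

test_that("probes all-missing in one group are skipped with a count", {
  fx <- dmp_fixture()
  beta <- fx$beta
  beta["flat", 1:5] <- NA
  expect_message(res <- suppressWarnings(
    call_dmps(beta, fx$labels, all = TRUE)), "skipped")
  expect_false("flat" %in% res$probe_id)
})

test_that("group errors are raised", {
  fx <- dmp_fixture()
  expect_error(suppressWarnings(call_dmps(fx$beta[, 1:7],
                                          fx$labels[1:7])), "at least 3")
})

test_that("injected effect probes dominate calls with high precision", {
  cfg <- cohort_config(n_samples = 100, hdnamad_prevalence = 0.5,
                       effect_delta_beta = 0.3, seed = 29)
  b <- simulate_cohort(cfg)
  g <- factor(ifelse(b$truth, "pos", "neg"), levels = c("pos", "neg"))
  names(g) <- names(b$truth)
  clock_probes <- unlist(lapply(b$clocks, function(cl) names(coef(cl))))
  dmps <- suppressWarnings(call_dmps(b$beta, g,
                                     exclude_probes = clock_probes))
  expect_true(all(!dmps$probe_id %in% clock_probes))
  precision <- mean(dmps$probe_id %in% names(b$effect_probes))
  expect_gt(precision, 0.8)
  # injected 90% hypo split is recovered within 5 points
  hypo_frac <- mean(dmps$direction == "hypo")
  expect_gt(hypo_frac, 0.85)
  expect_lt(hypo_frac, 0.95)
})

test_that("region composition matches hand counts on a small fixture", {
  dmps <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    delta_beta = c(-0.3, -0.4, -0.5, 0.3),
    p_raw = rep(0.001, 4), p_adj = rep(0.004, 4),
    direction = c("hypo", "hypo", "hypo", "hyper"),
    stringsAsFactors = FALSE)
  ann <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    chromosome = c("1", "2", "2", "3"),
    position = 1:4,
    island_relation = c("Island", "Shore", "Shore", "Island"),
    gene_region = c("TSS200;Body", "Body", "", "TSS200"),
    stringsAsFactors = FALSE)
  comp <- region_composition(dmps, ann)

  isl <- comp$island
  expect_equal(isl$fraction[isl$direction == "hypo" &
                              isl$region == "Island"], 1 / 3)
  expect_equal(isl$fraction[isl$direction == "hypo" &
                              isl$region == "Shore"], 2 / 3)
  expect_equal(sum(isl$fraction[isl$direction == "hypo"]), 1)
  expect_equal(sum(isl$fraction[isl$direction == "hyper"]), 1)

  # p1 contributes one assignment to TSS200 and one to Body
  gr <- comp$gene_region
  hypo_gr <- gr[gr$direction == "hypo", ]
  expect_equal(hypo_gr$count[hypo_gr$region == "TSS200"], 1L)
  expect_equal(hypo_gr$count[hypo_gr$region == "Body"], 2L)
  expect_equal(hypo_gr$count[hypo_gr$region == "intergenic"], 1L)
  expect_equal(sum(hypo_gr$fraction), 1)

  # all-Island direction gives fraction 1
  comp2 <- region_composition(dmps[4, ], ann)
  expect_equal(comp2$island$fraction, 1)

  # unannotated probes fall into 'unknown' with a warning
  expect_warning(comp3 <- region_composition(
    rbind(dmps, data.frame(probe_id = "pX", delta_beta = -0.5,
                           p_raw = 0.001, p_adj = 0.004,
                           direction = "hypo")), ann), "unknown")
  expect_true("unknown" %in% comp3$island$region)

  # empty input gives empty tables
  empty <- region_composition(dmps[0, ], ann)
  expect_equal(nrow(empty$island), 0L)
})

test_that("manifest reading collapses island relations", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "IlmnID,CHR,MAPINFO,Relation_to_UCSC_CpG_Island,UCSC_RefGene_Group",
    "cg1,1,100,Island,TSS200;TSS200;Body",
    "cg2,2,200,N_Shore,",
    "cg3,X,300,S_Shelf,Body",
    "cg4,7,400,,5UTR"), f)
  m <- read_probe_manifest(f)
  expect_equal(m$island_relation, c("Island", "Shore", "Shelf", "GenePoor"))
  expect_equal(m$gene_region[1], "TSS200;Body") # duplicates collapsed
  expect_equal(m$chromosome[3], "X")
})
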