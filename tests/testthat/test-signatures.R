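test_that("unweighted enrichment matches the hand-derived 4-gene cases", {
  expr <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  expect_equal(ssgsea_score(expr, "g1", tau = 0), 2)
  expect_equal(ssgsea_score(expr, "g4", tau = 0), -2)
  # anti-symmetry of the unweighted kernel
  expect_equal(ssgsea_score(expr, c("g1", "g3"), tau = 0),
               -ssgsea_score(expr, c("g2", "g4"), tau = 0))
})

test_that("scores equal the brute-force oracle on random small universes", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    expr <- stats::setNames(round(stats::rnorm(n, 5, 2), 3),
                            sprintf("g%02d", seq_len(n)))
    m <- sample(seq_len(n - 1), 1)
    set <- sample(names(expr), m)
    tau <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgsea_score(expr, set, tau), ssgsea_oracle(expr, set, tau),
                 tolerance = 1e-12)
  }
})

test_that("degenerate gene sets are rejected", {
  expr <- c(a = 1, b = 2, c = 3)
  expect_error(ssgsea_score(expr, "zz"), "no gene")
  expect_error(ssgsea_score(expr, c("a", "b", "c")), "whole measured")
})

test_that("scores are rank-invariant under monotone transforms", {
  set.seed(7)
  expr <- stats::setNames(stats::runif(30, 1, 10), sprintf("g%02d", 1:30))
  set <- sample(names(expr), 6)
  s0 <- ssgsea_score(expr, set, tau = 0)
  expect_equal(ssgsea_score(2 * expr, set, tau = 0), s0)
  expect_equal(ssgsea_score(expr^3, set, tau = 0), s0)
  # tau > 0: the weighted score changes but keeps its sign under doubling
  s1 <- ssgsea_score(expr, set, tau = 0.25)
  expect_equal(sign(ssgsea_score(2 * expr, set, tau = 0.25)), sign(s1))
})

test_that("panel scoring is deterministic, per-sample, and skips empties", {
  set.seed(12)
  genes <- c(builtin_panels()$myeloid, sprintf("G%03d", 1:40))
  expr <- matrix(stats::rnorm(length(genes) * 4, 5), length(genes), 4,
                 dimnames = list(genes, paste0("s", 1:4)))
  expr[, 2] <- expr[, 1] # identical samples
  st <- suppressMessages(score_panels(expr, panels = list(
    myeloid = builtin_panels()$myeloid, absent = c("NOPE1", "NOPE2")))) |>
    suppressWarnings()
  expect_equal(colnames(st), "myeloid")
  expect_equal(st["s1", ], st["s2", ])
  # monotone transform of one sample leaves its tau = 0 score unchanged
  st0 <- score_panels(expr, panels = builtin_panels()["myeloid"], tau = 0)
  expr2 <- expr
  expr2[, 3] <- expr2[, 3] * 2
  st0b <- score_panels(expr2, panels = builtin_panels()["myeloid"], tau = 0)
  expect_equal(st0["s3", ], st0b["s3", ])
})

test_that("group panel effects injected in simulation are detected", {
  cfg <- cohort_config(n_samples = 100, hdnamad_prevalence = 0.5,
                       panel_effect_log2 = 2, seed = 23)
  b <- simulate_cohort(cfg)
  st <- suppressMessages(score_panels(b$expression))
  g <- factor(ifelse(b$truth[rownames(st)], "pos", "neg"),
              levels = c("pos", "neg"))
  for (p in c("cell_cycle", "telomerase")) {
    expect_gt(mean(st[g == "pos", p]), mean(st[g == "neg", p]))
    expect_lt(compare_group_scores(st[, p], g)$p_value, 0.01)
  }
  for (p in c("myeloid", "Teffector")) {
    expect_lt(mean(st[g == "pos", p]), mean(st[g == "neg", p]))
    expect_lt(compare_group_scores(st[, p], g)$p_value, 0.01)
  }
})

test_that("differential expression applies the strict retention rule", {
  expr <- rbind(
    flat = rep(5, 10),
    big = c(rep(10, 5), rep(2, 5)),
    edge = c(rep(6.5, 5), rep(5, 5)) # log2 fc exactly 1.5
  )
  colnames(expr) <- paste0("s", 1:10)
  lab <- rep(c("A", "B"), each = 5)
  full <- suppressWarnings(
    differential_expression(expr, lab, all = TRUE))
  expect_equal(full$log2_fc[full$gene == "flat"], 0)
  big <- full[full$gene == "big", ]
  expect_equal(big$log2_fc, 8)
  expect_equal(big$p_raw, 2 / 252, tolerance = 1e-12)
  expect_equal(full$log2_fc[full$gene == "edge"], 1.5)

  kept <- suppressWarnings(differential_expression(expr, lab))
  expect_equal(kept$gene, "big") # strict > 1.5 excludes the edge gene
  expect_equal(kept$direction, "up")

  # single-gene input: BH leaves the exact p unchanged
  one <- differential_expression(expr["big", , drop = FALSE], lab)
  expect_equal(one$p_adj, 2 / 252, tolerance = 1e-12)
})

test_that("relabelling groups flips fold changes and preserves p-values", {
  set.seed(5)
  expr <- matrix(stats::rnorm(200), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  lab <- factor(rep(c("A", "B"), each = 5), levels = c("A", "B"))
  a <- suppressWarnings(differential_expression(expr, lab, all = TRUE))
  b <- suppressWarnings(differential_expression(
    expr, stats::relevel(lab, "B"), all = TRUE))
  b <- b[match(a$gene, b$gene), ]
  expect_equal(a$log2_fc, -b$log2_fc)
  expect_equal(a$p_raw, b$p_raw)
})

test_that("BH adjustment is monotone in raw-p rank order and capped at 1", {
  set.seed(13)
  expr <- matrix(stats::rnorm(300), 30, 10,
                 dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:10)))
  res <- suppressWarnings(differential_expression(
    expr, rep(c("A", "B"), each = 5), all = TRUE))
  res <- res[order(res$p_raw), ]
  expect_true(all(diff(res$p_adj) >= -1e-12))
  expect_true(all(res$p_adj <= 1))
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("group comparisons use the exact rank tests", {
  expect_equal(compare_group_scores(c(1, 2, 3, 10, 11, 12),
                                    rep(c("a", "b"), each = 3))$p_value,
               0.1)
  # permuted labels of one sample set: p = 1 under the exact test
  v <- c(1, 2, 3, 4)
  expect_equal(compare_group_scores(v, c("a", "b", "b", "a"))$p_value, 1)
  # three identical groups: zero Kruskal-Wallis statistic
  kw <- compare_group_scores(rep(c(1, 2, 3), times = 3),
                             rep(c("x", "y", "z"), each = 3))
  expect_equal(kw$statistic, 0)
  expect_error(compare_group_scores(1:3, c("a", "a", "a")), "2 non-empty")
})

test_that("GMT files round-trip and shipped gene lists load", {
  f <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(one = c("A", "B"), two = c("C", "D", "E"))
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)

  expect_length(checkpoint_genes(), 21)
  stem <- stemness_panel()
  expect_length(stem[[1]], 109)
  al <- gene_aliases()
  expect_equal(unname(al["KI-67"]), "MKI67")
  expect_equal(unname(al["TCAB1"]), "WRAP53")
})
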