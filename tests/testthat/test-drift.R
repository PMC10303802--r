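test_that("drift classes follow the +/-3 yr band with boundary in drift", {
  d <- drift_from_deviations(list(horvath = c(-10, 2.9, 3, -3, 0)))
  expect_equal(d$deviation, c(-10, 2.9, 3, -3, 0))
  expect_equal(d$class, c("DNAmad", "matched", "DNAmaa", "DNAmad",
                          "matched"))
})

test_that("classes partition the cohort for any positive band", {
  set.seed(21)
  dev <- stats::rnorm(200, 0, 10)
  for (band in c(0.5, 3, 7)) {
    ids <- sprintf("S%03d", seq_along(dev))
    preds <- data.frame(sample_id = ids, clock = "c",
                        dnam_age = 60 + dev)
    d <- compute_drift(stats::setNames(rep(60, length(dev)), ids), preds,
                       band = band)
    expect_equal(sum(d$class == "matched") + sum(d$class == "DNAmaa") +
                   sum(d$class == "DNAmad"), length(dev))
    expect_true(all((abs(d$deviation) < band) == (d$class == "matched")))
  }
})

test_that("samples without chronological age are dropped with a count", {
  ids <- c("a", "b", "c")
  preds <- data.frame(sample_id = ids, clock = "c", dnam_age = c(50, 60, 70))
  chron <- stats::setNames(c(55, NA, 65), ids)
  expect_message(d <- compute_drift(chron, preds), "1 of 3")
  expect_equal(d$sample_id, c("a", "c"))
  expect_error(compute_drift(stats::setNames(c(Inf, 1, 2), ids), preds),
               "non-finite")
})

test_that("residual deviation mode uses least-squares residuals", {
  ids <- sprintf("S%d", 1:4)
  chron <- stats::setNames(c(50, 60, 70, 80), ids)
  dnam <- c(40, 55, 72, 85)
  preds <- data.frame(sample_id = ids, clock = "c", dnam_age = dnam)
  d <- compute_drift(chron, preds, deviation = "residual")
  expect_equal(d$deviation, unname(resid(lm(dnam ~ c(50, 60, 70, 80)))),
               tolerance = 1e-8)
})

test_that("cohort summary reports r, MAD and range; degenerate r is NA", {
  d <- drift_from_deviations(list(c1 = c(0, 0, 0)))
  s <- cohort_summary(d, "c1")
  expect_true(is.na(s$pearson_r)) # constant chron ages
  expect_equal(s$mad, 0)

  ids <- c("a", "b", "c")
  preds <- data.frame(sample_id = ids, clock = "c",
                      dnam_age = c(40, 60, 80))
  d2 <- compute_drift(stats::setNames(c(50, 60, 70), ids), preds)
  s2 <- cohort_summary(d2, "c")
  expect_equal(s2$pearson_r, 1)
  expect_equal(s2$mad, 20 / 3)
  expect_equal(s2$deviation_range, c(-10, 10))

  # constant dnam vector: r undefined, MAD still finite
  preds3 <- data.frame(sample_id = ids, clock = "c", dnam_age = rep(60, 3))
  s3 <- cohort_summary(compute_drift(stats::setNames(c(50, 60, 70), ids),
                                     preds3), "c")
  expect_true(is.na(s3$pearson_r))
  expect_equal(s3$mad, 20 / 3)

  # identical vectors: perfect correlation, zero MAD
  preds4 <- data.frame(sample_id = ids, clock = "c",
                       dnam_age = c(50, 60, 70))
  s4 <- cohort_summary(compute_drift(stats::setNames(c(50, 60, 70), ids),
                                     preds4), "c")
  expect_equal(s4$pearson_r, 1)
  expect_equal(s4$mad, 0)
})

test_that("the tercile rule reproduces its worked examples", {
  # 403 candidates -> floor(403/3) = 134 retained
  set.seed(31)
  dev <- c(stats::runif(403, -79, -3), stats::runif(26, -2.9, 2.9))
  d <- drift_from_deviations(list(primary = dev, confirm = dev))
  lab <- select_hdnamad(d, "primary", "confirm")
  expect_equal(attr(lab, "n_candidates"), 403L)
  expect_equal(attr(lab, "tercile_size"), 134L)
  expect_lte(sum(lab), 134L)

  # hand-enumerated 3-candidate case
  d3 <- drift_from_deviations(list(p = c(-10, -5, -4),
                                   c = c(-10, -10, 10)))
  lab3 <- select_hdnamad(d3, "p", "c")
  expect_equal(attr(lab3, "tercile_size"), 1L)
  expect_equal(unname(lab3), c(TRUE, FALSE, FALSE), ignore_attr = TRUE)

  # tercile members all DNAmaa on the confirmation clock -> empty set
  d0 <- drift_from_deviations(list(p = c(-10, -5, -4), c = c(10, 10, 10)))
  expect_equal(sum(select_hdnamad(d0, "p", "c")), 0L)

  # zero candidates -> warning, all negative
  dn <- drift_from_deviations(list(p = c(0, 1, -1), c = c(0, 0, 0)))
  expect_warning(labn <- select_hdnamad(dn, "p", "c"), "no DNAmad")
  expect_equal(sum(labn), 0L)
})

test_that("hDNAmad labels are monotone in primary deviation", {
  dev_p <- c(-20, -15, -10, -8, -6, -4)
  dev_c <- rep(-10, 6)
  d <- drift_from_deviations(list(p = dev_p, c = dev_c))
  lab <- select_hdnamad(d, "p", "c")
  stopifnot(lab[["S001"]])
  # making a positive sample still more decelerated keeps it positive
  dev_p2 <- dev_p
  dev_p2[1] <- -40
  lab2 <- select_hdnamad(drift_from_deviations(list(p = dev_p2,
                                                    c = dev_c)), "p", "c")
  expect_true(lab2[["S001"]])
  expect_lte(sum(lab), floor(sum(dev_p <= -3) / 3))
})

test_that("injected rejuvenation subgroups are recovered with fraction 1", {
  cfg <- cohort_config(n_samples = 250, hdnamad_prevalence = 0.2,
                       rejuvenation_offset_years = 15,
                       beta_noise_sd = 0.01, seed = 17)
  b <- simulate_cohort(cfg)
  preds <- do.call(rbind, lapply(b$clocks, predict, beta = b$beta))
  chron <- stats::setNames(b$clinical$age, b$clinical$sample_id)
  d <- compute_drift(chron, preds)
  lab <- select_hdnamad(d, "horvath_like", "phenoage_like", fraction = 1)
  truth <- b$truth[names(lab)]
  sens <- sum(lab & truth) / sum(truth)
  spec <- sum(!lab & !truth) / sum(!truth)
  expect_gt(sens, 0.9)
  expect_gt(spec, 0.9)
})
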