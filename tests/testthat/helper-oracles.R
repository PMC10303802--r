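# Independent oracles used by the suite. Deliberately written as plain
# step-by-step computations, not calls into the package.

# Brute-force single-sample enrichment: walk the descending-expression list
# and materialize both cumulative distributions explicitly.
ssgsea_oracle <- function(expr, set, tau) {
  ord <- order(-expr, names(expr))
  ids <- names(expr)[ord]
  n <- length(ids)
  in_set <- ids %in% set
  m <- sum(in_set)
  bottom_rank <- seq(n, 1)
  w <- ifelse(in_set, bottom_rank^tau, 0)
  p_in <- 0
  p_out <- 0
  score <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      p_in <- p_in + w[i] / sum(w)
    } else {
      p_out <- p_out + 1 / (n - m)
    }
    score <- score + (p_in - p_out)
  }
  score
}

# Two-sided Fisher exact p by hypergeometric enumeration over the support
# of the (1,1) cell at fixed margins, summing all outcomes no more likely
# than the observed one (with the same relative tolerance fisher.test
# applies when comparing point probabilities).
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Build a drift_table directly from deviation vectors (one clock), for
# rule-level tests that do not involve the clock engine.
drift_from_deviations <- function(dev_by_clock, chron = 60) {
  stopifnot(is.list(dev_by_clock), !is.null(names(dev_by_clock)))
  n <- length(dev_by_clock[[1]])
  ids <- sprintf("S%03d", seq_len(n))
  preds <- do.call(rbind, lapply(names(dev_by_clock), function(cl) {
    data.frame(sample_id = ids, clock = cl,
               dnam_age = chron + dev_by_clock[[cl]],
               stringsAsFactors = FALSE)
  }))
  compute_drift(stats::setNames(rep(chron, n), ids), preds)
}

# Small deterministic beta fixture: probes x samples in [0,1].
toy_beta <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(n_probes * n_samples), n_probes, n_samples,
         dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                         sprintf("S%02d", seq_len(n_samples))))
}
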