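# Shared small-scale fixtures and independent oracles used across the suite.

small_config <- function(seed = 42, n_probes = 2000, n_cimp_extra = 60,
                         healthy = FALSE, ...) {
  sim_config(
    seed = seed, n_probes = n_probes, n_cimp_extra = n_cimp_extra,
    cohorts = data.frame(
      cohort = c("BRCA", "BLCA", "COAD"),
      n_tumor = c(40L, 30L, 30L),
      n_normal = c(40L, 15L, 15L),
      stringsAsFactors = FALSE),
    healthy_cohort = if (healthy) "HB" else NULL,
    n_healthy = 20L, ...)
}

small_sim <- function(seed = 42, ...) {
  cfg <- small_config(seed = seed, ...)
  ann <- simulate_annotation(cfg$n_probes, seed = cfg$seed,
                             snp_frac = cfg$snp_frac,
                             sex_frac = cfg$sex_frac, n_genes = cfg$n_genes)
  c(simulate_cohorts(cfg, ann), list(annotation = ann, config = cfg))
}

# Oracle: two-sided Fisher exact p by full hypergeometric enumeration over
# all tables with the observed margins (probability-mass ordering).
fisher_p_enum <- function(a, b, c_, d) {
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Oracle: AUC by brute-force concordant-pair counting with 0.5 tie credit.
auc_pairs <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Oracle: information gain from an explicit binned contingency table.
ig_direct <- function(values, labels, n_bins) {
  breaks <- unique(stats::quantile(values,
                                   probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(values, breaks = breaks, include.lowest = TRUE)
  ent <- function(x) {
    p <- table(x) / length(x)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h <- ent(labels)
  hc <- 0
  for (b in levels(bins)) {
    idx <- bins == b
    if (any(idx)) hc <- hc + mean(idx) * ent(labels[idx])
  }
  h - hc
}
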