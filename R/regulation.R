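#' Log2 counts-per-million transform
#'
#' Library-size normalisation to counts per million followed by
#' `log2(cpm + 1)`; the expression scale used for differential expression
#' and methylation-expression correlation.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return genes x samples numeric matrix.
#' @export
log_cpm <- function(counts) {
  .assert(all(counts >= 0, na.rm = TRUE), "counts must be non-negative")
  libsize <- colSums(counts, na.rm = TRUE)
  libsize[libsize == 0] <- 1
  log2(sweep(counts, 2, libsize, "/") * 1e6 + 1)
}

#' Call differentially expressed genes
#'
#' A deliberately simple DE caller: Welch t-test per gene on log2 CPM with
#' BH FDR, applying the thresholds |log2 FC| > `log2fc_min` and
#' FDR < `fdr_max`. Externally computed DE tables (e.g. from a
#' negative-binomial GLM) with columns `gene`, `log2_fc`, `p_value`, `fdr`
#' can be substituted downstream via [as_deg_table()].
#'
#' @param counts genes x samples count matrix.
#' @param sheet sample sheet identifying tumor and normal columns.
#' @param log2fc_min,fdr_max DEG thresholds (defaults 1 and 0.01).
#' @param cohort optional cohort restriction.
#' @param tumor_tissue,normal_tissue tissue labels.
#' @return data.frame `gene`, `log2_fc`, `p_value`, `fdr`, `direction`
#'   (`up`/`down`/`ns`), `reason`.
#' @export
call_degs <- function(counts, sheet, log2fc_min = 1, fdr_max = 0.01,
                      cohort = NULL, tumor_tissue = "tumor",
                      normal_tissue = "adjacent_normal") {
  sh <- sheet[sheet$sample_id %in% colnames(counts), ]
  if (!is.null(cohort)) sh <- sh[sh$cohort == cohort, ]
  tcols <- sh$sample_id[sh$tissue == tumor_tissue]
  ncols <- sh$sample_id[sh$tissue == normal_tissue]
  .assert(length(tcols) >= 3 && length(ncols) >= 3,
          "need >= 3 samples per group")
  l <- log_cpm(counts[, c(tcols, ncols), drop = FALSE])
  res <- .welch_t_rows(l[, tcols, drop = FALSE], l[, ncols, drop = FALSE])
  lfc <- res$estimate
  p <- res$p
  allzero <- rowSums(counts[, c(tcols, ncols), drop = FALSE]) == 0
  reason <- rep(NA_character_, nrow(counts))
  p[allzero] <- NA_real_
  reason[allzero] <- "all_zero_counts"
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  direction <- rep("ns", length(p))
  direction[ok & lfc > log2fc_min & fdr < fdr_max] <- "up"
  direction[ok & lfc < -log2fc_min & fdr < fdr_max] <- "down"
  data.frame(gene = rownames(counts), log2_fc = lfc, p_value = p, fdr = fdr,
             direction = direction, reason = reason, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Validate an externally computed DE table
#'
#' Accepts a drop-in replacement for [call_degs()] output (e.g. from a
#' dedicated count-model package) and normalises it to the expected columns,
#' assigning directions from the thresholds.
#'
#' @param df data.frame with columns `gene`, `log2_fc`, `p_value`, `fdr`
#'   (direction recomputed if absent).
#' @param log2fc_min,fdr_max DEG thresholds.
#' @return standardised DEG data.frame.
#' @export
as_deg_table <- function(df, log2fc_min = 1, fdr_max = 0.01) {
  need <- c("gene", "log2_fc", "p_value", "fdr")
  .assert(all(need %in% names(df)),
          paste("DE table needs columns:", paste(need, collapse = ", ")))
  if (!"direction" %in% names(df)) {
    df$direction <- "ns"
    ok <- !is.na(df$fdr)
    df$direction[ok & df$log2_fc > log2fc_min & df$fdr < fdr_max] <- "up"
    df$direction[ok & df$log2_fc < -log2fc_min & df$fdr < fdr_max] <- "down"
  }
  df
}

# Pearson correlation between one beta row and one expression row, pairwise
# complete; returns r, p (t-distribution, n-2 df) and a degenerate flag.
.cor_one <- function(b, e, alpha) {
  ok <- !is.na(b) & !is.na(e)
  n <- sum(ok)
  if (n < 10 || stats::sd(b[ok]) == 0 || stats::sd(e[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  r <- stats::cor(b[ok], e[ok])
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tt), n - 2)
  list(r = r, p = p, n = n, degenerate = FALSE)
}

.corr_call <- function(r, p, alpha) {
  call <- rep("NS", length(r))
  sig <- !is.na(p) & p < alpha
  call[sig & r < 0] <- "Neg"
  call[sig & r > 0] <- "Pos"
  call
}

#' Cis correlation between DMCs and their annotated genes
#'
#' One record per (differentially methylated CpG, its own annotated gene):
#' Pearson correlation of the CpG's beta with the gene's log2 CPM across
#' matched samples; two-sided p from the t-distribution with n - 2 df.
#' `Neg` when r < 0 and p < `alpha`, `Pos` when r > 0 and p < `alpha`,
#' otherwise `NS` (constant inputs are flagged degenerate `NS`).
#'
#' @param beta probes x samples beta matrix.
#' @param expr genes x samples log2-CPM matrix (see [log_cpm()]).
#' @param annotation probe annotation supplying the CpG -> gene map.
#' @param dmcs DMC table from [call_dmcs()] (rows with direction `ns` are
#'   skipped).
#' @param alpha significance threshold on p (default 0.05).
#' @return data.frame `probe_id`, `gene`, `mode`, `r`, `p_value`, `n`,
#'   `call`, `degenerate`.
#' @export
cis_correlation <- function(beta, expr, annotation, dmcs, alpha = 0.05) {
  dm <- dmcs[dmcs$direction != "ns", ]
  ann <- annotation[match(dm$probe_id, annotation$probe_id), ]
  use <- !is.na(ann$gene) & ann$gene %in% rownames(expr) &
    dm$probe_id %in% rownames(beta)
  dm <- dm[use, ]; gene <- ann$gene[use]
  shared <- intersect(colnames(beta), colnames(expr))
  .assert(length(shared) >= 10, "need >= 10 shared samples")
  out <- vector("list", nrow(dm))
  for (i in seq_len(nrow(dm))) {
    cc <- .cor_one(beta[dm$probe_id[i], shared], expr[gene[i], shared], alpha)
    out[[i]] <- data.frame(probe_id = dm$probe_id[i], gene = gene[i],
                           mode = "cis", r = cc$r, p_value = cc$p, n = cc$n,
                           degenerate = cc$degenerate,
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(probe_id = character(), gene = character(), mode = character(),
               r = numeric(), p_value = numeric(), n = integer(),
               degenerate = logical(), stringsAsFactors = FALSE)
  res$call <- .corr_call(res$r, res$p_value, alpha)
  res
}

#' Trans correlation between DMCs and DEGs
#'
#' Correlates every differentially methylated CpG with every differentially
#' expressed gene, excluding each CpG's own annotated gene (those pairs are
#' the cis screen). Computed by matrix cross-products of standardised rows;
#' optionally capped by seeded subsampling of pairs.
#'
#' @param beta probes x samples beta matrix.
#' @param expr genes x samples log2-CPM matrix.
#' @param dmcs DMC table ([call_dmcs()]); `ns` rows skipped.
#' @param degs DEG table ([call_degs()]); `ns` rows skipped.
#' @param annotation probe annotation (for the cis exclusion).
#' @param alpha significance threshold.
#' @param max_pairs optional cap on the number of reported pairs.
#' @param seed seed used when subsampling to `max_pairs`.
#' @return data.frame as in [cis_correlation()] with `mode = "trans"`.
#' @export
trans_correlation <- function(beta, expr, dmcs, degs, annotation,
                              alpha = 0.05, max_pairs = Inf, seed = 1L) {
  dm <- dmcs[dmcs$direction != "ns" & dmcs$probe_id %in% rownames(beta), ]
  dg <- degs[degs$direction != "ns" & degs$gene %in% rownames(expr), ]
  empty <- data.frame(probe_id = character(), gene = character(),
                      mode = character(), r = numeric(), p_value = numeric(),
                      n = integer(), degenerate = logical(),
                      call = character(), stringsAsFactors = FALSE)
  if (nrow(dm) == 0 || nrow(dg) == 0) return(empty)
  shared <- intersect(colnames(beta), colnames(expr))
  .assert(length(shared) >= 10, "need >= 10 shared samples")
  b <- beta[dm$probe_id, shared, drop = FALSE]
  e <- expr[dg$gene, shared, drop = FALSE]
  n <- length(shared)
  zb <- (b - .row_mean(b)) / .row_sd(b)
  ze <- (e - .row_mean(e)) / .row_sd(e)
  r <- tcrossprod(zb, ze) / (n - 1)  # probes x genes
  own <- annotation$gene[match(dm$probe_id, annotation$probe_id)]
  pairs <- expand.grid(pi_ = seq_len(nrow(dm)), gi_ = seq_len(nrow(dg)))
  keep <- is.na(own[pairs$pi_]) | own[pairs$pi_] != dg$gene[pairs$gi_]
  pairs <- pairs[keep, ]
  if (nrow(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), ]
  }
  rv <- r[cbind(pairs$pi_, pairs$gi_)]
  rv <- pmin(pmax(rv, -1), 1)
  tt <- rv * sqrt((n - 2) / (1 - rv^2))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[abs(rv) >= 1] <- 0
  degen <- is.na(rv)
  p[degen] <- NA_real_
  res <- data.frame(probe_id = dm$probe_id[pairs$pi_],
                    gene = dg$gene[pairs$gi_], mode = "trans", r = rv,
                    p_value = p, n = n, degenerate = degen,
                    stringsAsFactors = FALSE)
  res$call <- .corr_call(res$r, res$p_value, alpha)
  rownames(res) <- NULL
  res
}

#' Stratified sign-bias summary of correlation calls
#'
#' For each stratum — DMC direction (hyper/hypo) crossed with either DEG
#' direction (trans screen) or the CpG's gene feature (cis screen) — the
#' fractions of negative, positive and non-significant correlation calls.
#' Empty strata are absent from the output.
#'
#' @param records correlation table from [cis_correlation()] or
#'   [trans_correlation()].
#' @param dmcs DMC table supplying probe directions.
#' @param degs optional DEG table supplying gene directions (trans).
#' @param annotation optional annotation supplying gene features (cis).
#' @return data.frame `dmc_direction`, `stratum`, `n`, `frac_neg`,
#'   `frac_pos`, `frac_ns`.
#' @export
bias_summary <- function(records, dmcs, degs = NULL, annotation = NULL) {
  .assert(nrow(records) > 0, "records must be non-empty")
  dmc_dir <- dmcs$direction[match(records$probe_id, dmcs$probe_id)]
  strat <- if (!is.null(degs)) {
    degs$direction[match(records$gene, degs$gene)]
  } else if (!is.null(annotation)) {
    annotation$feature[match(records$probe_id, annotation$probe_id)]
  } else rep("all", nrow(records))
  key <- paste(dmc_dir, strat, sep = "|")
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    calls <- records$call[idx]
    data.frame(dmc_direction = dmc_dir[idx[1]], stratum = strat[idx[1]],
               n = length(idx),
               frac_neg = mean(calls == "Neg"),
               frac_pos = mean(calls == "Pos"),
               frac_ns = mean(calls == "NS"), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
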