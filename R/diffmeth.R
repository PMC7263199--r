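#' Kolmogorov-Smirnov normality check for beta values
#'
#' Standardises the values and applies a one-sample K-S test against the
#' standard normal. Used to choose between the t-test family and the
#' Wilcoxon family in differential methylation.
#'
#' @param values numeric vector (>= 8 non-missing values, nonzero variance).
#' @param alpha significance level; `TRUE` (consistent with normal) is
#'   returned when the K-S p-value is >= `alpha`.
#' @return logical scalar.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  .assert(length(x) >= 8, "need at least 8 non-missing values")
  s <- stats::sd(x)
  if (s == 0) stop("values are constant (zero variance)", call. = FALSE)
  z <- (x - mean(x)) / s
  p <- suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  p >= alpha
}

#' Differential methylation test at a single CpG
#'
#' Computes delta-beta (mean tumor minus mean normal) and a two-sided
#' p-value from the test selected by the design: paired or Welch t-test when
#' the betas look normal, Wilcoxon signed-rank / rank-sum otherwise. Missing
#' values are dropped pairwise (a pair with either member missing is dropped
#' in the paired mode).
#'
#' @param tumor,normal beta vectors; equal length and shared patient order
#'   when `paired`.
#' @param paired logical; paired design.
#' @param normal_dist logical; treat betas as normally distributed.
#' @return list with `delta_beta`, `p_value`, `test`.
#' @export
test_site <- function(tumor, normal, paired = FALSE, normal_dist = TRUE) {
  if (paired)
    .assert(length(tumor) == length(normal),
            "paired test requires equal-length vectors with shared ordering")
  x <- matrix(tumor, nrow = 1)
  y <- matrix(normal, nrow = 1)
  if (paired) {
    ok <- !is.na(tumor) & !is.na(normal)
    .assert(sum(ok) >= 3, "need >= 3 complete pairs")
  } else {
    .assert(sum(!is.na(tumor)) >= 3 && sum(!is.na(normal)) >= 3,
            "need >= 3 observations per group")
  }
  if (normal_dist) {
    res <- if (paired) .paired_t_rows(x - y) else .welch_t_rows(x, y)
    test <- if (paired) "paired_t" else "unpaired_t"
  } else {
    res <- .wilcox_rows(x, y, paired)
    test <- if (paired) "wilcoxon_paired" else "wilcoxon_unpaired"
  }
  delta <- mean(tumor, na.rm = TRUE) - mean(normal, na.rm = TRUE)
  list(delta_beta = delta, p_value = res$p[1], test = test)
}

# Internal engine: two-group differential methylation over matrix rows.
# cols1/cols2 are column names of beta; paired uses positional pairing.
.dm_two_group <- function(beta, cols1, cols2, paired, normal_dist,
                          delta_min, fdr_max, test_label) {
  x <- beta[, cols1, drop = FALSE]
  y <- beta[, cols2, drop = FALSE]
  if (normal_dist) {
    res <- if (paired) .paired_t_rows(x - y) else .welch_t_rows(x, y)
  } else {
    res <- .wilcox_rows(x, y, paired)
  }
  delta <- if (paired) .row_mean(x - y) else .row_mean(x) - .row_mean(y)
  p <- res$p
  reason <- rep(NA_character_, nrow(beta))
  low_n <- res$n < 3
  p[low_n] <- NA_real_
  reason[low_n] <- "insufficient_obs"
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  direction <- rep("ns", length(p))
  direction[ok & delta > delta_min & fdr < fdr_max] <- "hyper"
  direction[ok & delta < -delta_min & fdr < fdr_max] <- "hypo"
  data.frame(probe_id = rownames(beta), delta_beta = delta, p_value = p,
             fdr = fdr, direction = direction, test = test_label,
             reason = reason, row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially methylated CpGs (DMCs)
#'
#' Tumor-vs-normal differential methylation over a whole beta matrix with
#' Benjamini-Hochberg FDR across all tested probes. A probe is `hyper` when
#' delta-beta > `delta_min` and FDR < `fdr_max`, `hypo` symmetrically, `ns`
#' otherwise. In paired mode tumor and adjacent-normal columns are matched
#' by `patient_id`.
#'
#' @param beta probes x samples beta matrix.
#' @param sheet sample sheet with `sample_id`, `cohort`, `tissue`,
#'   `patient_id`.
#' @param mode `"paired"` or `"unpaired"`.
#' @param cohort optional cohort id to restrict to.
#' @param delta_min,fdr_max DMC thresholds (defaults 0.2 and 0.01).
#' @param normal_dist logical; `TRUE` uses the t-test family (global
#'   normality decision), `FALSE` the Wilcoxon family.
#' @param tumor_tissue,normal_tissue tissue labels of the two groups.
#' @return data.frame with `probe_id`, `delta_beta`, `p_value`, `fdr`,
#'   `direction`, `test`, `reason`.
#' @export
call_dmcs <- function(beta, sheet, mode = c("paired", "unpaired"),
                      cohort = NULL, delta_min = 0.2, fdr_max = 0.01,
                      normal_dist = TRUE, tumor_tissue = "tumor",
                      normal_tissue = "adjacent_normal") {
  mode <- match.arg(mode)
  sh <- sheet[sheet$sample_id %in% colnames(beta), ]
  if (!is.null(cohort)) sh <- sh[sh$cohort == cohort, ]
  tums <- sh[sh$tissue == tumor_tissue, ]
  norms <- sh[sh$tissue == normal_tissue, ]
  .assert(nrow(norms) > 0, "no normal samples in cohort")
  .assert(nrow(tums) > 0, "no tumor samples in cohort")
  if (mode == "paired") {
    pid <- intersect(tums$patient_id[!is.na(tums$patient_id)],
                     norms$patient_id[!is.na(norms$patient_id)])
    .assert(length(pid) >= 3, "need >= 3 tumor/normal pairs")
    cols1 <- tums$sample_id[match(pid, tums$patient_id)]
    cols2 <- norms$sample_id[match(pid, norms$patient_id)]
    label <- if (normal_dist) "paired_t" else "wilcoxon_paired"
  } else {
    .assert(nrow(tums) >= 3 && nrow(norms) >= 3,
            "need >= 3 samples per group")
    cols1 <- tums$sample_id
    cols2 <- norms$sample_id
    label <- if (normal_dist) "unpaired_t" else "wilcoxon_unpaired"
  }
  .dm_two_group(beta, cols1, cols2, paired = (mode == "paired"),
                normal_dist = normal_dist, delta_min = delta_min,
                fdr_max = fdr_max, test_label = label)
}

#' Summarise methylation at the region level
#'
#' Groups probes into gene regions — CGI-relative (Island, shores, shelves)
#' or TSS-relative (TSS200, TSS1500, 5'UTR, first exon, body, 3'UTR) — and
#' summarises each (gene, region) as the arithmetic mean of its non-missing
#' member CpG betas, per sample. Regions with no probes are omitted.
#'
#' @param beta probes x samples beta matrix.
#' @param annotation probe annotation covering the probes of `beta`.
#' @param scheme `"cgi"` or `"tss"`.
#' @return list with `values` (regions x samples matrix, rownames
#'   `"gene|region"`) and `regions` (data.frame `gene`, `region`,
#'   `n_probes`).
#' @export
summarize_regions <- function(beta, annotation, scheme = c("cgi", "tss")) {
  scheme <- match.arg(scheme)
  ann <- annotation[match(rownames(beta), annotation$probe_id), ]
  reg <- if (scheme == "cgi") ann$cgi_relation else ann$feature
  valid <- if (scheme == "cgi")
    c("Island", "NShore", "NShelf", "SShore", "SShelf")
  else c("TSS200", "TSS1500", "5'UTR", "FirstExon", "Body", "3'UTR")
  use <- !is.na(ann$gene) & reg %in% valid
  .assert(any(use), "no probe maps to a (gene, region)")
  key <- paste(ann$gene[use], reg[use], sep = "|")
  b <- beta[use, , drop = FALSE]
  num <- rowsum(ifelse(is.na(b), 0, b), key)
  den <- rowsum((!is.na(b)) * 1, key)
  values <- num / den
  values[den == 0] <- NA_real_
  parts <- do.call(rbind, strsplit(rownames(values), "|", fixed = TRUE))
  list(values = values,
       regions = data.frame(gene = parts[, 1], region = parts[, 2],
                            n_probes = as.integer(table(key)[rownames(values)]),
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Region-level differential methylation counts
#'
#' Paired t-test per (gene, region) on region-summarised betas, then counts
#' of hyper- / hypo-methylated / unchanged genes per region class at the
#' site-level thresholds (the delta threshold can be disabled by setting
#' `delta_min = 0`).
#'
#' @param regions output of [summarize_regions()].
#' @param sheet sample sheet (a paired design must be available).
#' @param delta_min,fdr_max thresholds.
#' @param cohort optional cohort restriction.
#' @return list with `counts` (data.frame `region`, `hyper`, `hypo`, `ns`)
#'   and `table` (per-region differential results).
#' @export
region_differential <- function(regions, sheet, delta_min = 0.2,
                                fdr_max = 0.01, cohort = NULL) {
  sh <- sheet[sheet$sample_id %in% colnames(regions$values), ]
  if (!is.null(cohort)) sh <- sh[sh$cohort == cohort, ]
  tums <- sh[sh$tissue == "tumor" & !is.na(sh$patient_id), ]
  norms <- sh[sh$tissue == "adjacent_normal" & !is.na(sh$patient_id), ]
  pid <- intersect(tums$patient_id, norms$patient_id)
  if (length(pid) < 3)
    stop("no paired design available; use unpaired site-level analysis",
         call. = FALSE)
  tab <- .dm_two_group(regions$values,
                       tums$sample_id[match(pid, tums$patient_id)],
                       norms$sample_id[match(pid, norms$patient_id)],
                       paired = TRUE, normal_dist = TRUE,
                       delta_min = delta_min, fdr_max = fdr_max,
                       test_label = "paired_t")
  names(tab)[names(tab) == "probe_id"] <- "region_id"
  tab$gene <- regions$regions$gene
  tab$region <- regions$regions$region
  counts <- do.call(rbind, lapply(split(tab, tab$region), function(d)
    data.frame(region = d$region[1], hyper = sum(d$direction == "hyper"),
               hypo = sum(d$direction == "hypo"),
               ns = sum(d$direction == "ns"), stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  list(counts = counts, table = tab)
}

#' Genome-feature enrichment of a probe set
#'
#' Builds the 2x2 table (in vs out of feature) x (probe set vs reference
#' set), tests it with Fisher's exact test (two-sided), and reports the
#' sample odds ratio `(a*d)/(b*c)` with a Woolf log-OR 95% confidence
#' interval. Zero cells give an infinite OR/CI bound and set the
#' `degenerate` flag.
#'
#' @param probes probe ids of the set of interest (e.g. hyper-CpGs).
#' @param reference probe ids of the comparison set (e.g. hypo-CpGs, or all
#'   retained CpGs).
#' @param annotation probe annotation covering both sets.
#' @param feature one or more labels matched against `cgi_relation` and
#'   `feature` (e.g. `"Island"`, or `c("TSS200", "TSS1500")` for promoters).
#' @param conf_level confidence level of the Woolf interval.
#' @return data.frame row: `feature`, counts `a`..`d`, `odds_ratio`,
#'   `ci_lower`, `ci_upper`, `p_value`, `degenerate`.
#' @export
feature_enrichment <- function(probes, reference, annotation, feature,
                               conf_level = 0.95) {
  .assert(length(probes) > 0 && length(reference) > 0,
          "probe sets must be non-empty")
  ann_feat <- annotation$cgi_relation %in% feature |
    annotation$feature %in% feature
  .assert(any(ann_feat), "feature not present in annotation")
  in_feat <- annotation$probe_id[ann_feat]
  a <- sum(probes %in% in_feat)
  b <- length(probes) - a
  c_ <- sum(reference %in% in_feat)
  d <- length(reference) - c_
  or <- (a * d) / (b * c_)
  degenerate <- (a == 0 || b == 0 || c_ == 0 || d == 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (degenerate) {
    # Woolf interval undefined with a zero cell: report the uninformative
    # (0, Inf) interval and flag it
    ci <- c(0, Inf)
  } else {
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    ci <- exp(log(or) + c(-z, z) * se)
  }
  p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
  data.frame(feature = paste(feature, collapse = "+"), a = a, b = b, c = c_,
             d = d, odds_ratio = or, ci_lower = ci[1], ci_upper = ci[2],
             p_value = p, degenerate = degenerate, stringsAsFactors = FALSE)
}
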