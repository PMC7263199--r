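#' Progressive cohort-specificity cascade for hyper-methylated CpGs
#'
#' Screens for CpGs hyper-methylated specifically in the target cohort:
#' stage 1 keeps paired hyper-DMCs in the target cohort (tumor vs adjacent
#' normal), stage 2 requires the same call in the unpaired comparison,
#' stage 3 (when a healthy cohort is present) requires hyper-methylation vs
#' healthy tissue, and stage 4 requires hyper-methylation vs the tumors AND
#' the normals of every background cohort. All stages use the same
#' delta-beta / FDR rule, with BH correction within each comparison over the
#' candidate set of that stage; stage-4 comparisons are all evaluated on the
#' fixed post-stage-3 candidate set, so the result does not depend on the
#' order of background cohorts.
#'
#' @param beta probes x samples beta matrix spanning all cohorts.
#' @param sheet sample sheet (`cohort`, `tissue`, `patient_id`).
#' @param target target cohort id (must have paired tumor/normal samples).
#' @param healthy_cohort optional cohort id of healthy-tissue samples
#'   (tissue `"healthy"`).
#' @param delta_min,fdr_max thresholds applied at every stage.
#' @param normal_dist logical; t-test family vs Wilcoxon family.
#' @param background optional character vector of background cohort ids
#'   (default: every cohort other than target and healthy).
#' @return a `marker_panel` data.frame: `probe_id`, one logical column per
#'   stage (`passed_paired`, `passed_unpaired`, `passed_healthy`,
#'   `passed_vs_<cohort>_tumor` / `_normal`), and `final`. Flags after the
#'   first failed stage are `NA`. Attributes: `target`, `stages`, `partial`.
#' @export
cascade_filter <- function(beta, sheet, target, healthy_cohort = NULL,
                           delta_min = 0.2, fdr_max = 0.01,
                           normal_dist = TRUE, background = NULL) {
  sh <- sheet[sheet$sample_id %in% colnames(beta), ]
  .assert(any(sh$cohort == target & sh$tissue == "adjacent_normal"),
          "target cohort has no adjacent normal samples")
  if (is.null(background))
    background <- setdiff(unique(sh$cohort), c(target, healthy_cohort))
  .assert(length(background) >= 1, "need at least one background cohort")
  probes <- rownames(beta)
  np <- length(probes)
  panel <- data.frame(probe_id = probes, stringsAsFactors = FALSE)
  partial <- FALSE
  target_tumors <- sh$sample_id[sh$cohort == target & sh$tissue == "tumor"]

  hyper_on <- function(tab) tab$probe_id[tab$direction == "hyper"]

  # stage 1: paired hyper-DMC in target
  d1 <- call_dmcs(beta, sh, mode = "paired", cohort = target,
                  delta_min = delta_min, fdr_max = fdr_max,
                  normal_dist = normal_dist)
  panel$passed_paired <- probes %in% hyper_on(d1)
  # stage 2: unpaired hyper-DMC in target
  d2 <- call_dmcs(beta, sh, mode = "unpaired", cohort = target,
                  delta_min = delta_min, fdr_max = fdr_max,
                  normal_dist = normal_dist)
  panel$passed_unpaired <- ifelse(panel$passed_paired,
                                  probes %in% hyper_on(d2), NA)
  cand <- probes[panel$passed_paired & !is.na(panel$passed_unpaired) &
                   panel$passed_unpaired]

  # stage 3: hyper vs healthy tissue (unpaired), BH over the candidate set
  stage_cols <- c("passed_paired", "passed_unpaired")
  if (!is.null(healthy_cohort)) {
    hcols <- sh$sample_id[sh$cohort == healthy_cohort &
                            sh$tissue == "healthy"]
    .assert(length(hcols) >= 3, "healthy cohort needs >= 3 samples")
    d3 <- .dm_two_group(beta[cand, , drop = FALSE], target_tumors, hcols,
                        paired = FALSE, normal_dist = normal_dist,
                        delta_min = delta_min, fdr_max = fdr_max,
                        test_label = "unpaired_t")
    pass3 <- cand %in% hyper_on(d3)
    panel$passed_healthy <- NA
    panel$passed_healthy[match(cand, probes)] <- pass3
    cand <- cand[pass3]
    stage_cols <- c(stage_cols, "passed_healthy")
  }

  # stage 4: vs every background cohort's tumors and normals, each
  # comparison on the fixed candidate set
  for (bc in background) {
    for (cls in c("tumor", "adjacent_normal")) {
      colname <- paste0("passed_vs_", bc, "_",
                        if (cls == "tumor") "tumor" else "normal")
      other <- sh$sample_id[sh$cohort == bc & sh$tissue == cls]
      panel[[colname]] <- NA
      if (length(other) < 3) {
        warning("background cohort ", bc, " has < 3 ", cls,
                " samples; comparison skipped, panel marked partial")
        partial <- TRUE
        stage_cols <- c(stage_cols, colname)
        next
      }
      if (length(cand)) {
        dd <- .dm_two_group(beta[cand, , drop = FALSE], target_tumors, other,
                            paired = FALSE, normal_dist = normal_dist,
                            delta_min = delta_min, fdr_max = fdr_max,
                            test_label = "unpaired_t")
        panel[[colname]][match(cand, probes)] <- cand %in% hyper_on(dd)
      }
      stage_cols <- c(stage_cols, colname)
    }
  }
  # final = reached the end of the cascade and no evaluated stage failed
  # (a skipped comparison contributes an all-NA column and cannot veto)
  flag_mat <- as.matrix(panel[, stage_cols, drop = FALSE])
  passed_all <- apply(flag_mat, 1, function(fl) all(fl[!is.na(fl)]))
  panel$final <- (panel$probe_id %in% cand) & passed_all
  structure(panel, target = target, stages = stage_cols, partial = partial,
            thresholds = c(delta_min = delta_min, fdr_max = fdr_max),
            class = c("marker_panel", "data.frame"))
}

#' Rank DMCs by adjusted significance
#'
#' Sorts a DMC table ascending by FDR, breaking ties by larger |delta-beta|
#' and then by probe id, and returns the first `top_n` probe ids.
#'
#' @param dmcs DMC table ([call_dmcs()]).
#' @param top_n number of probes to return (>= 1).
#' @return character vector of probe ids (length <= `top_n`).
#' @export
rank_by_fdr <- function(dmcs, top_n = 200) {
  .assert(nrow(dmcs) > 0, "DMC table is empty")
  .assert(top_n >= 1, "top_n must be >= 1")
  d <- dmcs[!is.na(dmcs$fdr), ]
  ord <- order(d$fdr, -abs(d$delta_beta), d$probe_id)
  utils::head(d$probe_id[ord], top_n)
}

#' Hierarchical clustering separation of tumor and normal samples
#'
#' Average-linkage Euclidean clustering of samples on a probe subset; the
#' separation score is the adjusted Rand index between the two-cluster cut
#' of the dendrogram and the true labels (1 = perfect separation, ~0 =
#' chance).
#'
#' @param beta_subset probes x samples matrix.
#' @param labels vector of sample labels (e.g. tumor/normal), aligned with
#'   the columns; both labels must be present.
#' @return list with `hclust` (the dendrogram), `cut` (2-cluster
#'   assignment) and `score` (adjusted Rand index).
#' @export
hierarchical_separation <- function(beta_subset, labels) {
  .assert(length(labels) == ncol(beta_subset),
          "labels must match the sample columns")
  .assert(length(unique(labels)) >= 2, "need >= 2 distinct labels")
  .assert(all(table(labels) >= 2), "need >= 2 samples per label")
  hc <- stats::hclust(stats::dist(t(beta_subset)), method = "average")
  cut2 <- stats::cutree(hc, k = 2)
  list(hclust = hc, cut = cut2,
       score = mclust::adjustedRandIndex(cut2, labels))
}
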