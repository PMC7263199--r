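#' Select variable, tumor-specific CpGs for CIMP clustering
#'
#' Keeps probes whose beta standard deviation across tumor samples exceeds
#' `sd_min` and whose mean beta across normal samples is below
#' `normal_mean_max` — i.e. CpGs unmethylated in normal tissue but variably
#' methylated across tumors.
#'
#' @param tumor_beta,normal_beta beta matrices sharing a probe universe.
#' @param sd_min tumor standard-deviation threshold (default 0.2).
#' @param normal_mean_max normal-mean threshold (default 0.05).
#' @return character vector of selected probe ids.
#' @export
select_variable_cpgs <- function(tumor_beta, normal_beta, sd_min = 0.2,
                                 normal_mean_max = 0.05) {
  .assert(sd_min >= 0 && sd_min <= 1 && normal_mean_max >= 0 &&
            normal_mean_max <= 1, "thresholds must lie in [0, 1]")
  shared <- intersect(rownames(tumor_beta), rownames(normal_beta))
  .assert(length(shared) > 0, "matrices share no probes")
  sds <- .row_sd(tumor_beta[shared, , drop = FALSE])
  nm <- .row_mean(normal_beta[shared, , drop = FALSE])
  shared[!is.na(sds) & sds > sd_min & !is.na(nm) & nm < normal_mean_max]
}

#' Consensus clustering for choosing the cluster number
#'
#' Monti-style subsampled consensus: for each k in `k_range`, repeatedly
#' subsample samples (columns), run K-means, and record how often each
#' sample pair co-clusters among the resamples where both were drawn. The
#' chosen k minimises the PAC score (proportion of ambiguous consensus
#' values, i.e. pairwise consensus in `(0.1, 0.9)`); ties break to the
#' smallest k.
#'
#' @param beta_subset probes x samples matrix (samples are clustered).
#' @param k_range candidate cluster numbers, within `[2, n_samples - 1]`.
#' @param n_resamples number of subsampling rounds per k (>= 2).
#' @param subsample_frac fraction of samples drawn per round.
#' @param seed integer seed.
#' @param n_init K-means restarts per round.
#' @param pac_lower,pac_upper ambiguity window of the PAC score.
#' @return a `consensus_profile` list: `k_range`, `pac`, `mean_consensus`,
#'   `chosen_k`, `consensus` (list of consensus matrices).
#' @export
consensus_cluster <- function(beta_subset, k_range = 2:6, n_resamples = 100,
                              subsample_frac = 0.8, seed = 1L, n_init = 5,
                              pac_lower = 0.1, pac_upper = 0.9) {
  n <- ncol(beta_subset)
  .assert(n_resamples >= 2, "n_resamples must be >= 2")
  if (max(k_range) > n - 1)
    stop("fewer samples than max(k_range) allows", call. = FALSE)
  .assert(min(k_range) >= 2, "k_range must start at >= 2")
  set.seed(seed)
  xs <- t(beta_subset)
  m <- floor(subsample_frac * n)
  pac <- numeric(length(k_range))
  meanc <- numeric(length(k_range))
  cons_list <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co <- matrix(0, n, n)
    tog <- matrix(0, n, n)
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, m)
      cl <- stats::kmeans(xs[idx, , drop = FALSE], centers = k,
                          nstart = n_init, iter.max = 50)$cluster
      same <- outer(cl, cl, "==") * 1
      tog[idx, idx] <- tog[idx, idx] + 1
      co[idx, idx] <- co[idx, idx] + same
    }
    cons <- co / tog
    cons[tog == 0] <- NA_real_
    diag(cons) <- 1
    off <- cons[upper.tri(cons)]
    off <- off[!is.na(off)]
    pac[ki] <- mean(off > pac_lower & off < pac_upper)
    meanc[ki] <- mean(off)
    dimnames(cons) <- list(colnames(beta_subset), colnames(beta_subset))
    cons_list[[ki]] <- cons
  }
  structure(list(k_range = k_range, pac = pac, mean_consensus = meanc,
                 chosen_k = k_range[which.min(pac)], consensus = cons_list),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("Consensus clustering profile\n")
  print(data.frame(k = x$k_range, pac = round(x$pac, 4),
                   mean_consensus = round(x$mean_consensus, 4)))
  cat("chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' K-means clustering of samples on selected CpGs
#'
#' Euclidean K-means of samples (columns) in the space of the selected
#' probes, keeping the best of `n_init` random initialisations by
#' within-cluster sum of squares.
#'
#' @param beta_subset probes x samples matrix.
#' @param k number of clusters, `2 <= k <= n_samples`.
#' @param seed integer seed.
#' @param n_init number of random restarts.
#' @return named integer vector: sample id -> cluster index.
#' @export
kmeans_cluster <- function(beta_subset, k, seed = 1L, n_init = 20) {
  n <- ncol(beta_subset)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  .assert(k >= 2, "k must be >= 2")
  set.seed(seed)
  if (k == n) {
    cl <- seq_len(n)  # degenerate: every sample its own cluster
    names(cl) <- colnames(beta_subset)
    return(cl)
  }
  fit <- stats::kmeans(t(beta_subset), centers = k, nstart = n_init,
                       iter.max = 100)
  cl <- fit$cluster
  names(cl) <- colnames(beta_subset)
  cl
}

#' Call the CIMP cluster from a clustering of tumor samples
#'
#' The cluster with the highest mean beta over the selected probes is
#' labelled the CpG island methylator phenotype (CIMP) cluster; its members
#' are flagged CIMP, all others non-CIMP. Exact ties break to the smallest
#' cluster index with a warning.
#'
#' @param assignment named vector sample id -> cluster index (>= 2 clusters).
#' @param beta_subset probes x samples matrix over the selected CpGs.
#' @return a `cimp_result` list: `selected_probes`, `k`, `assignment`,
#'   `cimp_cluster`, `cimp_flags`, `cluster_mean_beta`.
#' @export
call_cimp <- function(assignment, beta_subset) {
  clusters <- sort(unique(assignment))
  if (length(clusters) < 2)
    stop("need >= 2 clusters to call CIMP", call. = FALSE)
  samples <- names(assignment)
  .assert(all(samples %in% colnames(beta_subset)),
          "assignment samples missing from beta matrix")
  means <- vapply(clusters, function(cl)
    mean(beta_subset[, samples[assignment == cl], drop = FALSE],
         na.rm = TRUE), numeric(1))
  names(means) <- as.character(clusters)
  top <- which(means == max(means))
  if (length(top) > 1)
    warning("tie in cluster mean beta; taking the lowest cluster index")
  cimp_cluster <- clusters[min(top)]
  flags <- assignment == cimp_cluster
  structure(list(selected_probes = rownames(beta_subset),
                 k = length(clusters), assignment = assignment,
                 cimp_cluster = cimp_cluster, cimp_flags = flags,
                 cluster_mean_beta = means),
            class = "cimp_result")
}

#' @export
print.cimp_result <- function(x, ...) {
  cat("CIMP call over", length(x$selected_probes), "CpGs,", x$k, "clusters\n")
  cat("cluster mean beta:\n")
  print(round(x$cluster_mean_beta, 4))
  cat("CIMP cluster:", x$cimp_cluster, "(", sum(x$cimp_flags), "samples )\n")
  invisible(x)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per group and the multi-group log-rank
#' test (chi-square with groups - 1 degrees of freedom, two-sided p).
#'
#' @param sheet sample sheet with `sample_id`, `os_days`, `os_event`.
#' @param groups named vector/factor: sample id -> group label (>= 2 groups,
#'   each non-empty).
#' @return list: `curves` (data.frame `group`, `time`, `n_risk`, `surv`),
#'   `chisq`, `df`, `p_value`, `fit` (the survfit object).
#' @export
km_logrank <- function(sheet, groups) {
  ids <- names(groups)
  .assert(!is.null(ids), "groups must be a named vector (sample ids)")
  sh <- sheet[match(ids, sheet$sample_id), ]
  .assert(!anyNA(sh$sample_id), "groups contain samples absent from sheet")
  ok <- !is.na(sh$os_days) & !is.na(sh$os_event)
  d <- data.frame(time = sh$os_days[ok], event = sh$os_event[ok],
                  group = factor(as.vector(groups)[ok]))
  if (any(table(d$group) == 0) || nlevels(d$group) < 2)
    stop("each group needs at least one sample with survival data",
         call. = FALSE)
  .assert(all(d$time > 0), "survival times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- nlevels(d$group) - 1
  p <- stats::pchisq(sd_$chisq, df, lower.tail = FALSE)
  s <- summary(fit)
  curves <- data.frame(group = sub("^group=", "", as.character(s$strata)),
                       time = s$time, n_risk = s$n.risk, surv = s$surv,
                       stringsAsFactors = FALSE)
  list(curves = curves, chisq = unname(sd_$chisq), df = df, p_value = p,
       fit = fit)
}
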