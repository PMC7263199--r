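#' Simulation configuration for multi-cohort methylation studies
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate a
#' desk-scale version of a multi-cancer 450K study: one target cohort with
#' paired tumor/adjacent-normal samples, several background cancer cohorts,
#' a planted set of target-specific hyper-methylated CpGs, a planted
#' high-methylation (CIMP) tumor subcluster with worse survival, and
#' negative-binomial expression counts negatively coupled to promoter
#' methylation.
#'
#' @param seed integer master seed; identical seeds give identical data.
#' @param n_probes number of CpG probes to simulate.
#' @param cohorts data.frame with columns `cohort`, `n_tumor`, `n_normal`.
#' @param target_cohort cohort id whose tumors carry the planted markers.
#' @param healthy_cohort optional cohort id whose samples are labelled
#'   `healthy` tissue (no tumors); `NULL` to omit.
#' @param n_healthy number of healthy samples when `healthy_cohort` is set.
#' @param n_markers number of planted target-specific hyper-CpGs.
#' @param marker_delta planted beta shift of markers in target tumors.
#' @param background_hyper_frac fraction of probes hyper-methylated in the
#'   tumors of every cohort (pan-cancer background signal).
#' @param background_hyper_delta beta shift of the background-hyper probes.
#' @param beta_dispersion concentration `kappa` of the Beta noise; values are
#'   drawn from `Beta(mu*kappa, (1-mu)*kappa)`.
#' @param n_cimp_extra number of extra high-variance (bimodal) CpGs forming
#'   the CIMP block together with the markers.
#' @param cimp_fraction fraction of target-cohort tumors in the CIMP cluster.
#' @param cimp_delta extra beta shift added to CIMP samples over the block.
#' @param survival_hr hazard ratio of CIMP vs non-CIMP tumors.
#' @param censor_rate expected fraction of censored survival records.
#' @param expr_coupling slope (log2 expression per unit beta) for coupled
#'   probe-gene pairs; negative values plant repressive promoter methylation.
#' @param n_genes number of genes in the expression matrix.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param de_log2fc planted absolute log2 fold change of DE genes.
#' @param nb_size negative-binomial size (inverse dispersion) of counts.
#' @param snp_frac fraction of SNP-flagged probes in the annotation.
#' @param sex_frac fraction of probes placed on chrX/chrY.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 20000L,
                       cohorts = data.frame(
                         cohort   = c("BRCA", "BLCA", "COAD", "LUAD", "KIRC"),
                         n_tumor  = c(50L, 40L, 40L, 40L, 40L),
                         n_normal = c(50L, 20L, 20L, 20L, 20L),
                         stringsAsFactors = FALSE),
                       target_cohort = "BRCA",
                       healthy_cohort = NULL,
                       n_healthy = 50L,
                       n_markers = 8L,
                       marker_delta = 0.4,
                       background_hyper_frac = 0.02,
                       background_hyper_delta = 0.3,
                       beta_dispersion = 50,
                       n_cimp_extra = 200L,
                       cimp_fraction = 0.2,
                       cimp_delta = 0.3,
                       survival_hr = 3,
                       censor_rate = 0.3,
                       expr_coupling = -2,
                       n_genes = 2000L,
                       n_de_genes = 200L,
                       de_log2fc = 2,
                       nb_size = 20,
                       snp_frac = 0.05,
                       sex_frac = 0.03) {
  cfg <- list(seed = as.integer(seed), n_probes = as.integer(n_probes),
              cohorts = cohorts, target_cohort = target_cohort,
              healthy_cohort = healthy_cohort, n_healthy = as.integer(n_healthy),
              n_markers = as.integer(n_markers), marker_delta = marker_delta,
              background_hyper_frac = background_hyper_frac,
              background_hyper_delta = background_hyper_delta,
              beta_dispersion = beta_dispersion,
              n_cimp_extra = as.integer(n_cimp_extra),
              cimp_fraction = cimp_fraction, cimp_delta = cimp_delta,
              survival_hr = survival_hr, censor_rate = censor_rate,
              expr_coupling = expr_coupling, n_genes = as.integer(n_genes),
              n_de_genes = as.integer(n_de_genes), de_log2fc = de_log2fc,
              nb_size = nb_size, snp_frac = snp_frac, sex_frac = sex_frac)
  .assert(cfg$n_probes >= 1, "n_probes must be >= 1")
  .assert(all(c("cohort", "n_tumor", "n_normal") %in% names(cohorts)),
          "cohorts needs columns cohort, n_tumor, n_normal")
  .assert(cfg$target_cohort %in% cohorts$cohort,
          "target_cohort must appear in cohorts")
  fracs <- c(cfg$background_hyper_frac, cfg$cimp_fraction, cfg$censor_rate,
             cfg$snp_frac, cfg$sex_frac, cfg$marker_delta, cfg$cimp_delta)
  .assert(all(fracs >= 0 & fracs <= 1), "fractions/deltas must lie in [0, 1]")
  .assert(cfg$n_markers <= cfg$n_probes, "n_markers must be <= n_probes")
  .assert(cfg$survival_hr > 0, "survival_hr must be > 0")
  .assert(cfg$beta_dispersion > 0, "beta_dispersion must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a 450K-style probe annotation manifest
#'
#' Probes are scattered across autosomes and (a small fraction) the sex
#' chromosomes, each with exactly one CpG-island relation (Island, shores,
#' shelves, open sea), one gene feature (promoter windows TSS200/TSS1500,
#' 5'UTR, first exon, body, 3'UTR) or intergenic status, and a SNP flag, so
#' that the probe-exclusion rules of [filter_probes()] are exercisable.
#'
#' @param n_probes number of probes (>= 1).
#' @param seed integer seed.
#' @param snp_frac fraction of SNP-flagged probes.
#' @param sex_frac fraction of probes on chrX/chrY.
#' @param n_genes size of the gene symbol universe.
#' @return data.frame with columns `probe_id`, `chrom`, `pos`, `cgi_relation`,
#'   `gene`, `feature`, `snp`.
#' @export
simulate_annotation <- function(n_probes, seed = 1L, snp_frac = 0.05,
                                sex_frac = 0.03, n_genes = 2000L) {
  .assert(length(n_probes) == 1 && n_probes >= 1, "n_probes must be >= 1")
  n_probes <- as.integer(n_probes)
  set.seed(seed)
  chrom <- sample(paste0("chr", 1:22), n_probes, replace = TRUE)
  on_sex <- stats::runif(n_probes) < sex_frac
  chrom[on_sex] <- sample(c("chrX", "chrY"), sum(on_sex), replace = TRUE,
                          prob = c(0.85, 0.15))
  cgi_levels <- c("Island", "NShore", "NShelf", "SShore", "SShelf", "OpenSea")
  feat_levels <- c("TSS200", "TSS1500", "5'UTR", "FirstExon", "Body", "3'UTR",
                   "Intergenic")
  cgi <- sample(cgi_levels, n_probes, replace = TRUE,
                prob = c(0.31, 0.12, 0.05, 0.12, 0.05, 0.35))
  feature <- sample(feat_levels, n_probes, replace = TRUE,
                    prob = c(0.10, 0.12, 0.08, 0.06, 0.32, 0.04, 0.28))
  gene <- sprintf("G%04d", sample.int(n_genes, n_probes, replace = TRUE))
  gene[feature == "Intergenic"] <- NA_character_
  data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chrom = chrom,
    pos = sample.int(1e8L, n_probes, replace = TRUE),
    cgi_relation = cgi,
    gene = gene,
    feature = feature,
    snp = stats::runif(n_probes) < snp_frac,
    stringsAsFactors = FALSE)
}

#' Simulate multi-cohort beta values with planted structure
#'
#' Draws per-probe baseline methylation from a bimodal mixture (mostly
#' unmethylated promoters plus a methylated-body mode), then plants:
#' target-cohort-specific hyper-CpGs (`n_markers` at `marker_delta`),
#' pan-cancer background hyper probes, and a CIMP block (the markers plus
#' `n_cimp_extra` bimodal high-variance CpGs) on which a `cimp_fraction`
#' subset of target tumors gains `cimp_delta`. Noise is
#' `Beta(mu*kappa, (1-mu)*kappa)` with `kappa = beta_dispersion`. Paired
#' tumor/normal samples share a patient id.
#'
#' @param config a [sim_config()].
#' @param annotation manifest from [simulate_annotation()]; must have at
#'   least `config$n_probes` rows.
#' @param marker_probes optional probe ids at which to plant the markers
#'   (e.g. to generate an independent testing cohort sharing the training
#'   cohort's marker positions); must be autosomal, non-SNP and
#'   gene-annotated.
#' @return list with elements `beta` (probes x samples matrix), `sheet`
#'   (sample sheet data.frame) and `truth` (planted ground truth: marker,
#'   background and CIMP-block probe ids, CIMP sample ids, DE genes, coupled
#'   probe-gene pairs).
#' @export
simulate_cohorts <- function(config, annotation, marker_probes = NULL) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  .assert(nrow(annotation) >= config$n_probes,
          "annotation must cover n_probes probes")
  ann <- annotation[seq_len(config$n_probes), ]
  set.seed(.derive_seed(config$seed, 1L))
  n <- config$n_probes
  kappa <- config$beta_dispersion

  # baseline per-probe means: bimodal like array data
  lo <- stats::rbeta(n, 1.5, 15)
  hi <- stats::rbeta(n, 15, 1.5)
  mu0 <- ifelse(stats::runif(n) < 0.55, lo, hi)
  mu0 <- pmin(pmax(mu0, 0.02), 0.98)

  # planted probe sets: markers must survive the sex/SNP filters and carry an
  # annotated gene so cis coupling is definable
  eligible <- which(!(ann$chrom %in% c("chrX", "chrY")) & !ann$snp &
                      !is.na(ann$gene))
  .assert(length(eligible) >= config$n_markers + config$n_cimp_extra,
          "not enough autosomal non-SNP annotated probes for planting")
  if (is.null(marker_probes)) {
    marker_idx <- sample(eligible, config$n_markers)
  } else {
    marker_idx <- match(marker_probes, ann$probe_id)
    .assert(!anyNA(marker_idx) && all(marker_idx %in% eligible),
            "marker_probes must be eligible probes of the annotation")
  }
  extra_idx <- sample(setdiff(eligible, marker_idx), config$n_cimp_extra)
  picked <- c(marker_idx, extra_idx)
  mu0[c(marker_idx, extra_idx)] <- 0.03  # low baseline: selectable vs normals
  bg_pool <- setdiff(seq_len(n), picked)
  bg_idx <- sample(bg_pool, floor(config$background_hyper_frac * n))

  # sample sheet
  co <- config$cohorts
  rows <- list()
  for (i in seq_len(nrow(co))) {
    cid <- co$cohort[i]
    nt <- co$n_tumor[i]; nn <- co$n_normal[i]
    npair <- min(nt, nn)
    pid_t <- c(sprintf("%s-P%03d", cid, seq_len(npair)),
               rep(NA_character_, max(0, nt - npair)))
    pid_n <- c(sprintf("%s-P%03d", cid, seq_len(npair)),
               rep(NA_character_, max(0, nn - npair)))
    if (nt > 0)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s-T%03d", cid, seq_len(nt)), cohort = cid,
        tissue = "tumor", patient_id = pid_t, stringsAsFactors = FALSE)
    if (nn > 0)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s-N%03d", cid, seq_len(nn)), cohort = cid,
        tissue = "adjacent_normal", patient_id = pid_n,
        stringsAsFactors = FALSE)
  }
  if (!is.null(config$healthy_cohort) && config$n_healthy > 0)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("%s-H%03d", config$healthy_cohort,
                          seq_len(config$n_healthy)),
      cohort = config$healthy_cohort, tissue = "healthy",
      patient_id = NA_character_, stringsAsFactors = FALSE)
  sheet <- do.call(rbind, rows)
  sheet$os_days <- NA_real_
  sheet$os_event <- NA_integer_
  ns <- nrow(sheet)
  is_tumor <- sheet$tissue == "tumor"

  # CIMP samples: subset of target tumors
  target_tumors <- sheet$sample_id[is_tumor &
                                     sheet$cohort == config$target_cohort]
  n_cimp <- round(config$cimp_fraction * length(target_tumors))
  cimp_ids <- if (n_cimp > 0) sort(sample(target_tumors, n_cimp)) else character(0)

  # per-sample mean matrix, then Beta noise
  mu <- matrix(mu0, nrow = n, ncol = ns)
  if (length(bg_idx))
    mu[bg_idx, is_tumor] <- mu[bg_idx, is_tumor] + config$background_hyper_delta
  tcol <- which(is_tumor & sheet$cohort == config$target_cohort)
  mu[marker_idx, tcol] <- mu[marker_idx, tcol] + config$marker_delta
  # bimodal high-variance block in every cohort's tumors
  tum <- which(is_tumor)
  if (length(extra_idx)) {
    flip <- matrix(stats::runif(length(extra_idx) * length(tum)) < 0.5,
                   nrow = length(extra_idx))
    mu[extra_idx, tum][flip] <- 0.60
  }
  cimp_col <- which(sheet$sample_id %in% cimp_ids)
  block_idx <- c(marker_idx, extra_idx)
  if (length(cimp_col))
    mu[block_idx, cimp_col] <- mu[block_idx, cimp_col] + config$cimp_delta
  mu <- pmin(pmax(mu, 0.01), 0.99)

  beta <- matrix(stats::rbeta(length(mu), mu * kappa, (1 - mu) * kappa),
                 nrow = n, ncol = ns,
                 dimnames = list(ann$probe_id, sheet$sample_id))

  # planted expression structure: DE genes and coupled probe-gene pairs
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  marker_genes <- ann$gene[marker_idx]
  n_de <- min(config$n_de_genes, config$n_genes)
  de_pool <- setdiff(genes, marker_genes)
  de_genes <- sample(de_pool, n_de)
  de_dir <- rep(c("up", "down"), length.out = n_de)
  # cis coupling: each marker with its own annotated gene; trans coupling:
  # each marker additionally drives one distinct down-regulated DE gene
  down_genes <- de_genes[de_dir == "down"]
  trans_genes <- utils::head(down_genes, config$n_markers)
  sgn <- rep(sign(config$expr_coupling), length(marker_idx))
  coupled <- rbind(
    data.frame(probe_id = ann$probe_id[marker_idx], gene = marker_genes,
               mode = rep("cis", length(marker_idx)), sign = sgn,
               stringsAsFactors = FALSE),
    data.frame(probe_id = ann$probe_id[marker_idx][seq_along(trans_genes)],
               gene = trans_genes,
               mode = rep("trans", length(trans_genes)),
               sign = sgn[seq_along(trans_genes)],
               stringsAsFactors = FALSE))

  truth <- list(
    marker_probe_ids = ann$probe_id[marker_idx],
    background_probe_ids = ann$probe_id[bg_idx],
    cimp_block_probe_ids = ann$probe_id[block_idx],
    cimp_extra_probe_ids = ann$probe_id[extra_idx],
    cimp_sample_ids = cimp_ids,
    planted_k = 2L,
    de_genes = data.frame(gene = de_genes, direction = de_dir,
                          stringsAsFactors = FALSE),
    coupled_pairs = coupled)
  list(beta = beta, sheet = sheet, truth = truth)
}

#' Simulate methylated/unmethylated intensities from beta values
#'
#' Inverse model of [compute_beta()]: with noise off and offset 0,
#' `compute_beta(meth, unmeth)` reproduces the input betas exactly.
#' A configurable fraction of entries per probe receives a failed detection
#' p-value (> 0.01).
#'
#' @param beta probes x samples beta matrix, values in \[0, 1\].
#' @param scale total intensity per probe (must be > 0).
#' @param noise_sd multiplicative log-normal noise sd (0 = exact inversion).
#' @param failed_frac scalar or per-probe vector: fraction of samples whose
#'   detection p-value exceeds 0.01.
#' @param seed integer seed.
#' @return list with matrices `meth`, `unmeth`, `detection_p`.
#' @export
simulate_intensities <- function(beta, scale = 2000, noise_sd = 0,
                                 failed_frac = 0, seed = 1L) {
  .assert(scale > 0, "scale must be > 0")
  .assert(all(beta >= 0 & beta <= 1, na.rm = TRUE), "beta must lie in [0, 1]")
  set.seed(seed)
  meth <- beta * scale
  unmeth <- (1 - beta) * scale
  if (noise_sd > 0) {
    meth <- meth * exp(stats::rnorm(length(meth), 0, noise_sd))
    unmeth <- unmeth * exp(stats::rnorm(length(unmeth), 0, noise_sd))
  }
  detp <- matrix(stats::runif(length(beta), 0, 0.005), nrow = nrow(beta),
                 dimnames = dimnames(beta))
  ff <- rep_len(failed_frac, nrow(beta))
  for (i in which(ff > 0)) {
    nf <- round(ff[i] * ncol(beta))
    if (nf > 0)
      detp[i, sample.int(ncol(beta), nf)] <- stats::runif(nf, 0.02, 1)
  }
  list(meth = meth, unmeth = unmeth, detection_p = detp)
}

#' Simulate gene expression counts coupled to methylation
#'
#' Negative-binomial counts with gene baselines on the log2 scale. Planted DE
#' genes are shifted by `de_log2fc` in tumors; coupled probe-gene pairs add
#' `expr_coupling * beta` to the gene's log2 mean, planting the negative
#' methylation-expression correlations screened by the regulation module.
#'
#' @param beta probes x samples beta matrix (must contain coupled probes).
#' @param sheet sample sheet matching `colnames(beta)`.
#' @param truth ground-truth list from [simulate_cohorts()].
#' @param config the [sim_config()] used to generate `beta`.
#' @return genes x samples integer count matrix.
#' @export
simulate_expression <- function(beta, sheet, truth, config) {
  .assert(all(truth$coupled_pairs$probe_id %in% rownames(beta)),
          "coupled probes missing from beta matrix")
  set.seed(.derive_seed(config$seed, 2L))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  ns <- ncol(beta)
  base <- stats::runif(config$n_genes, 4, 10)
  log2mu <- matrix(base, nrow = config$n_genes, ncol = ns,
                   dimnames = list(genes, colnames(beta)))
  tum <- sheet$tissue[match(colnames(beta), sheet$sample_id)] == "tumor"
  de <- truth$de_genes
  if (nrow(de)) {
    shift <- ifelse(de$direction == "up", config$de_log2fc, -config$de_log2fc)
    log2mu[de$gene, tum] <- log2mu[de$gene, tum] + shift
  }
  cp <- truth$coupled_pairs
  for (i in seq_len(nrow(cp)))
    log2mu[cp$gene[i], ] <- log2mu[cp$gene[i], ] +
      config$expr_coupling * beta[cp$probe_id[i], ]
  counts <- matrix(stats::rnbinom(length(log2mu), mu = 2^log2mu,
                                  size = config$nb_size),
                   nrow = config$n_genes, dimnames = dimnames(log2mu))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate survival times under proportional hazards
#'
#' Exponential event times with hazard multiplied by `hr` for CIMP samples;
#' censoring uniform on (0, event time) applied to a `censor_rate` fraction.
#'
#' @param sheet sample sheet; tumor samples receive times.
#' @param cimp_ids sample ids in the high-hazard (CIMP) group.
#' @param hr hazard ratio CIMP vs non-CIMP (> 0).
#' @param censor_rate expected censoring fraction in \[0, 1\].
#' @param baseline_rate baseline hazard per day.
#' @param seed integer seed.
#' @return the sheet with `os_days` / `os_event` filled for tumor samples.
#' @export
simulate_survival <- function(sheet, cimp_ids, hr, censor_rate = 0.3,
                              baseline_rate = 1 / 1095, seed = 1L) {
  .assert(hr > 0, "hr must be > 0")
  .assert(censor_rate >= 0 && censor_rate <= 1, "censor_rate must be in [0, 1]")
  set.seed(seed)
  tum <- which(sheet$tissue == "tumor")
  rate <- baseline_rate * ifelse(sheet$sample_id[tum] %in% cimp_ids, hr, 1)
  t_event <- stats::rexp(length(tum), rate)
  censored <- stats::runif(length(tum)) < censor_rate
  obs <- ifelse(censored, stats::runif(length(tum), 0, t_event), t_event)
  sheet$os_days[tum] <- pmax(obs, 1e-3)
  sheet$os_event[tum] <- as.integer(!censored)
  sheet
}
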