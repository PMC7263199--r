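#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `paths` (a list with
#' `beta`, `annotation`, `sheet`, and optionally `counts` TSV paths) must be
#' supplied. Thresholds default to the standard rules: site delta-beta 0.2 /
#' FDR 0.01, DEG log2 FC 1 / FDR 0.01, correlation alpha 0.05, CIMP
#' selection sd 0.2 / normal mean 0.05.
#'
#' @param simulation optional [sim_config()].
#' @param paths optional list of input file paths.
#' @param target target cohort id.
#' @param thresholds optional named list overriding defaults.
#' @param k_range candidate cluster numbers for consensus clustering.
#' @param seed integer master seed.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            target = "BRCA", thresholds = NULL,
                            k_range = 2:6, seed = 1L) {
  if (!is.null(simulation) && !is.null(paths))
    stop("supply exactly one of simulation or paths, not both", call. = FALSE)
  if (is.null(simulation) && is.null(paths))
    stop("supply one of simulation or paths", call. = FALSE)
  th <- list(delta_min = 0.2, fdr_max = 0.01, log2fc_min = 1,
             deg_fdr_max = 0.01, corr_alpha = 0.05, cimp_sd_min = 0.2,
             cimp_normal_mean_max = 0.05)
  for (nm in names(thresholds)) th[[nm]] <- thresholds[[nm]]
  .assert(all(unlist(th) > 0), "thresholds must be positive")
  structure(list(simulation = simulation, paths = paths, target = target,
                 thresholds = th, k_range = k_range, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full marker-discovery pipeline
#'
#' Executes, in order: data simulation (or loading), probe filtering,
#' paired/unpaired differential methylation, CIMP identification (variable
#' CpG selection, consensus clustering for k, K-means, CIMP call, survival
#' comparison), expression screens (DEGs, cis/trans correlations, sign-bias
#' summary), the cohort-specificity cascade, and the progressive diagnostic
#' model with cross-cohort misclassification. All artifacts are written to
#' `outdir` as TSV/JSON and indexed in a manifest with md5 checksums, so a
#' rerun with the same config is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return the manifest list, invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config, outdir) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  target <- config$target
  art <- list()
  save_tsv <- function(obj, name) {
    p <- file.path(outdir, name)
    if (is.matrix(obj)) write_matrix_tsv(obj, p) else write_table_tsv(obj, p)
    art[[name]] <<- p
    p
  }
  save_json <- function(obj, name) {
    p <- file.path(outdir, name)
    write_json_file(obj, p)
    art[[name]] <<- p
    p
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    ann <- simulate_annotation(sim_cfg$n_probes, seed = sim_cfg$seed,
                               snp_frac = sim_cfg$snp_frac,
                               sex_frac = sim_cfg$sex_frac,
                               n_genes = sim_cfg$n_genes)
    sim <- simulate_cohorts(sim_cfg, ann)
    beta <- sim$beta; sheet <- sim$sheet; truth <- sim$truth
    sheet <- simulate_survival(sheet, truth$cimp_sample_ids,
                               hr = sim_cfg$survival_hr,
                               censor_rate = sim_cfg$censor_rate,
                               seed = .derive_seed(sim_cfg$seed, 3L))
    counts <- simulate_expression(beta, sheet, truth, sim_cfg)
    save_tsv(beta, "beta.tsv"); save_tsv(ann, "annotation.tsv")
    save_tsv(sheet, "sample_sheet.tsv"); save_tsv(counts, "counts.tsv")
    save_json(truth, "truth.json")
  } else {
    ann <- read_table_tsv(config$paths$annotation)
    beta <- read_matrix_tsv(config$paths$beta)
    sheet <- read_table_tsv(config$paths$sheet)
    counts <- if (!is.null(config$paths$counts))
      read_matrix_tsv(config$paths$counts) else NULL
    truth <- NULL
  }

  # --- preprocess ---------------------------------------------------------
  fb <- filter_probes(beta, ann)
  report <- attr(fb, "filter_report")
  save_json(report, "filter_report.json")
  save_tsv(fb, "beta_filtered.tsv")

  # --- differential methylation ------------------------------------------
  dmc_paired <- call_dmcs(fb, sheet, "paired", cohort = target,
                          delta_min = th$delta_min, fdr_max = th$fdr_max)
  dmc_unpaired <- call_dmcs(fb, sheet, "unpaired", cohort = target,
                            delta_min = th$delta_min, fdr_max = th$fdr_max)
  save_tsv(dmc_paired, "dmc_paired.tsv")
  save_tsv(dmc_unpaired, "dmc_unpaired.tsv")
  hyper <- dmc_unpaired$probe_id[dmc_unpaired$direction == "hyper"]
  hypo <- dmc_unpaired$probe_id[dmc_unpaired$direction == "hypo"]
  enrich <- NULL
  if (length(hyper) && length(hypo)) {
    enrich <- rbind(
      feature_enrichment(hyper, hypo, ann, "Island"),
      feature_enrichment(hyper, rownames(fb), ann, "Island"),
      feature_enrichment(hyper, hypo, ann, c("TSS200", "TSS1500")))
    save_tsv(enrich, "feature_enrichment.tsv")
  }

  # --- CIMP ---------------------------------------------------------------
  sh <- sheet[sheet$sample_id %in% colnames(fb), ]
  t_cols <- sh$sample_id[sh$cohort == target & sh$tissue == "tumor"]
  n_cols <- sh$sample_id[sh$cohort == target & sh$tissue == "adjacent_normal"]
  sel <- select_variable_cpgs(fb[, t_cols, drop = FALSE],
                              fb[, n_cols, drop = FALSE],
                              sd_min = th$cimp_sd_min,
                              normal_mean_max = th$cimp_normal_mean_max)
  cimp_out <- NULL
  if (length(sel) >= 2) {
    bs <- fb[sel, t_cols, drop = FALSE]
    prof <- consensus_cluster(bs, k_range = config$k_range,
                              seed = .derive_seed(config$seed, 11L))
    cl <- kmeans_cluster(bs, prof$chosen_k,
                         seed = .derive_seed(config$seed, 12L))
    cimp <- call_cimp(cl, bs)
    surv <- if (!all(is.na(sheet$os_days[match(t_cols, sheet$sample_id)]))) {
      grp <- stats::setNames(ifelse(cimp$cimp_flags, "CIMP", "nonCIMP"),
                             names(cimp$cimp_flags))
      km_logrank(sheet, grp)
    } else NULL
    save_tsv(data.frame(sample_id = names(cimp$assignment),
                        cluster = unname(cimp$assignment),
                        cimp = unname(cimp$cimp_flags)), "cimp_samples.tsv")
    save_json(list(k_range = prof$k_range, pac = prof$pac,
                   chosen_k = prof$chosen_k,
                   cimp_cluster = cimp$cimp_cluster,
                   n_selected_cpgs = length(sel),
                   logrank_chisq = if (!is.null(surv)) surv$chisq else NULL,
                   logrank_p = if (!is.null(surv)) surv$p_value else NULL),
              "cimp_profile.json")
    if (!is.null(surv)) save_tsv(surv$curves, "km_curves.tsv")
    cimp_out <- list(profile = prof, cimp = cimp, surv = surv)
  }

  # --- regulation ---------------------------------------------------------
  reg_out <- NULL
  if (!is.null(counts)) {
    degs <- call_degs(counts, sheet, log2fc_min = th$log2fc_min,
                      fdr_max = th$deg_fdr_max, cohort = target)
    expr <- log_cpm(counts)
    cis <- cis_correlation(fb, expr, ann, dmc_unpaired,
                           alpha = th$corr_alpha)
    trans <- trans_correlation(fb, expr, dmc_unpaired, degs, ann,
                               alpha = th$corr_alpha, max_pairs = 50000,
                               seed = .derive_seed(config$seed, 21L))
    save_tsv(degs, "degs.tsv")
    if (nrow(cis)) save_tsv(cis, "correlation_cis.tsv")
    if (nrow(trans)) save_tsv(trans, "correlation_trans.tsv")
    if (nrow(trans))
      save_json(bias_summary(trans, dmc_unpaired, degs = degs),
                "bias_summary_trans.json")
    reg_out <- list(degs = degs, cis = cis, trans = trans)
  }

  # --- marker cascade -----------------------------------------------------
  healthy <- if (!is.null(config$simulation)) config$simulation$healthy_cohort
  panel <- cascade_filter(fb, sheet, target, healthy_cohort = healthy,
                          delta_min = th$delta_min, fdr_max = th$fdr_max)
  final_markers <- panel$probe_id[panel$final]
  save_tsv(as.data.frame(panel), "marker_panel.tsv")
  writeLines(final_markers, file.path(outdir, "final_markers.txt"))
  art[["final_markers.txt"]] <- file.path(outdir, "final_markers.txt")

  # --- diagnostic model ---------------------------------------------------
  diag_out <- NULL
  if (length(final_markers) >= 1) {
    lab <- stats::setNames(c(rep(1, length(t_cols)), rep(0, length(n_cols))),
                           c(t_cols, n_cols))
    Xtr <- t(fb[final_markers, names(lab), drop = FALSE])
    ranking <- rank_features(fb[final_markers, names(lab), drop = FALSE], lab)
    # independent testing cohort from the same generative process
    if (!is.null(config$simulation)) {
      test_cfg <- config$simulation
      test_cfg$seed <- .derive_seed(config$seed, 31L)
      test_cfg$cohorts <- data.frame(cohort = target, n_tumor = 80L,
                                     n_normal = 40L)
      test_cfg$cimp_fraction <- 0
      test_sim <- simulate_cohorts(test_cfg, ann,
                                   marker_probes = truth$marker_probe_ids)
      te_sh <- test_sim$sheet
      te_lab <- stats::setNames(as.numeric(te_sh$tissue == "tumor"),
                                te_sh$sample_id)
      Xte <- t(test_sim$beta[final_markers, names(te_lab), drop = FALSE])
      prog <- progressive_evaluation(ranking$probe_id, Xtr, lab[rownames(Xtr)],
                                     Xte, te_lab[rownames(Xte)])
      save_tsv(prog, "progressive_auc.tsv")
    } else prog <- NULL
    model <- fit_logistic(Xtr, lab[rownames(Xtr)])
    misc <- cross_cohort_misclassification(model, fb, sheet)
    save_json(list(probes = model$probes, intercept = model$intercept,
                   coefficients = as.list(model$coefficients),
                   l2_lambda = model$l2_lambda,
                   decision_threshold = model$decision_threshold,
                   ig_ranking = ranking), "model.json")
    save_tsv(misc, "misclassification.tsv")
    diag_out <- list(model = model, ranking = ranking, progressive = prog,
                     misclassification = misc)
  }

  manifest <- list(
    package = "methylmark",
    seed = config$seed,
    target = target,
    thresholds = th,
    stage_counts = list(
      probes_input = nrow(beta),
      probes_retained = report$n_retained,
      dmc_paired = sum(dmc_paired$direction != "ns"),
      dmc_unpaired = sum(dmc_unpaired$direction != "ns"),
      hyper = length(hyper), hypo = length(hypo),
      cimp_selected_cpgs = length(sel),
      final_markers = length(final_markers)),
    artifacts = names(art),
    md5 = as.list(stats::setNames(as.vector(tools::md5sum(unlist(art))),
                                  names(art))))
  write_json_file(manifest, file.path(outdir, "manifest.json"))
  invisible(list(manifest = manifest, panel = panel, cimp = cimp_out,
                 regulation = reg_out, diagnostic = diag_out,
                 truth = truth))
}
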