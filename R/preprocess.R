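#' Compute beta values from methylated/unmethylated intensities
#'
#' beta = meth / (meth + unmeth + offset), the methylated fraction of total
#' probe intensity, in \[0, 1\]. The offset defaults to 0 (the plain ratio);
#' the conventional Illumina offset of 100 can be supplied instead. A zero
#' denominator yields a missing value.
#'
#' @param meth,unmeth non-negative intensities (vector or matrix, same shape).
#' @param offset non-negative intensity added to the denominator.
#' @return beta values with the shape of `meth`; `NA` where the denominator
#'   is zero.
#' @export
compute_beta <- function(meth, unmeth, offset = 0) {
  .assert(all(meth >= 0, na.rm = TRUE) && all(unmeth >= 0, na.rm = TRUE),
          "intensities must be non-negative")
  .assert(length(offset) == 1 && offset >= 0, "offset must be a scalar >= 0")
  denom <- meth + unmeth + offset
  beta <- meth / denom
  beta[denom == 0] <- NA_real_
  beta
}

#' Apply probe-exclusion rules to a beta matrix
#'
#' Removes, in order: probes on the sex chromosomes, SNP-flagged probes, and
#' (when a detection p-value matrix is supplied) probes whose detection
#' p-value exceeds 0.01 in strictly more than half of all samples. Probe
#' order is preserved; per-rule exclusion counts are attached as the
#' `"filter_report"` attribute.
#'
#' @param beta probes x samples beta matrix with probe-id rownames.
#' @param annotation probe annotation covering every probe in `beta`.
#' @param detection_p optional matrix aligned with `beta`.
#' @param detection_p_max detection p-value threshold (default 0.01).
#' @return the retained beta matrix, with attribute `filter_report` listing
#'   `n_input`, `removed_sex`, `removed_snp`, `removed_detection`,
#'   `n_retained`.
#' @export
filter_probes <- function(beta, annotation, detection_p = NULL,
                          detection_p_max = 0.01) {
  probes <- rownames(beta)
  .assert(!is.null(probes), "beta must have probe-id rownames")
  missing <- setdiff(probes, annotation$probe_id)
  if (length(missing))
    stop("probes absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  ann <- annotation[match(probes, annotation$probe_id), ]
  keep <- !(ann$chrom %in% c("chrX", "chrY"))
  removed_sex <- sum(!keep)
  snp_drop <- keep & ann$snp
  removed_snp <- sum(snp_drop)
  keep <- keep & !ann$snp
  removed_det <- 0L
  if (!is.null(detection_p)) {
    .assert(all(dim(detection_p) == dim(beta)),
            "detection_p must match beta dimensions")
    n_fail <- rowSums(detection_p > detection_p_max, na.rm = TRUE)
    det_drop <- keep & (n_fail * 2 > ncol(beta))  # strictly more than half
    removed_det <- sum(det_drop)
    keep <- keep & !det_drop
  }
  out <- beta[keep, , drop = FALSE]
  attr(out, "filter_report") <- list(
    n_input = length(probes), removed_sex = removed_sex,
    removed_snp = removed_snp, removed_detection = removed_det,
    n_retained = sum(keep))
  out
}
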