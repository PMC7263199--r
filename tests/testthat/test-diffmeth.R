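test_that("ks_normality separates normal from uniform data", {
  set.seed(1)
  hits <- vapply(1:20, function(i) {
    set.seed(i)
    ks_normality(stats::rnorm(1000))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  set.seed(2)
  expect_false(ks_normality(stats::runif(1000)))
  expect_error(ks_normality(rep(0.4, 20)), "constant")
  expect_error(ks_normality(stats::rnorm(5)), "8")
})

test_that("test_site picks the right test and is symmetric", {
  set.seed(3)
  x <- stats::rnorm(20, 0.5, 0.05)
  same <- test_site(x, x, paired = TRUE, normal_dist = FALSE)
  expect_equal(same$delta_beta, 0)
  expect_equal(same$p_value, 1)

  n <- stats::rnorm(20, 0.3, 0.05)
  t_ <- n + 0.4 + stats::rnorm(20, 0, 0.02)
  res <- test_site(t_, n, paired = TRUE, normal_dist = TRUE)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$delta_beta, mean(t_) - mean(n), tolerance = 1e-12)
  expect_identical(res$test, "paired_t")
  # swapping groups negates delta and keeps p
  rev <- test_site(n, t_, paired = TRUE, normal_dist = TRUE)
  expect_equal(rev$delta_beta, -res$delta_beta)
  expect_equal(rev$p_value, res$p_value)
  # agreement with stats::t.test (paired and Welch)
  expect_equal(res$p_value, stats::t.test(t_, n, paired = TRUE)$p.value)
  u <- test_site(t_, n, paired = FALSE, normal_dist = TRUE)
  expect_equal(u$p_value, stats::t.test(t_, n)$p.value)
  w <- test_site(t_, n, paired = FALSE, normal_dist = FALSE)
  expect_equal(w$p_value,
               suppressWarnings(stats::wilcox.test(t_, n,
                                                   exact = TRUE)$p.value))
  expect_error(test_site(t_, n[1:5], paired = TRUE), "equal-length")
})

test_that("call_dmcs recovers planted effects and gates on delta-beta", {
  sim <- small_sim(seed = 50)
  d <- call_dmcs(sim$beta, sim$sheet, "paired", cohort = "BRCA")
  hyper <- d$probe_id[d$direction == "hyper"]
  expect_true(all(sim$truth$marker_probe_ids %in% hyper))
  expect_false(any(d$direction == "hypo"))

  # strong p but small delta stays ns: shift of 0.15 with many pairs
  set.seed(7)
  n_ <- matrix(stats::rnorm(50 * 60, 0.3, 0.03), 50)
  t_ <- n_ + 0.15
  t_[1, ] <- n_[1, ] + 0.4
  beta <- cbind(t_, n_)
  rownames(beta) <- paste0("p", 1:50)
  colnames(beta) <- c(paste0("T", 1:60), paste0("N", 1:60))
  sheet <- data.frame(
    sample_id = colnames(beta), cohort = "X",
    tissue = rep(c("tumor", "adjacent_normal"), each = 60),
    patient_id = rep(paste0("P", 1:60), 2), stringsAsFactors = FALSE)
  dd <- call_dmcs(beta, sheet, "paired")
  expect_lt(dd$p_value[2], 1e-10)
  expect_identical(dd$direction[2], "ns")     # delta 0.15 < 0.2
  expect_identical(dd$direction[1], "hyper")  # delta 0.4

  # antisymmetry under label swap
  sheet_sw <- sheet
  sheet_sw$tissue <- rep(c("adjacent_normal", "tumor"), each = 60)
  ds <- call_dmcs(beta, sheet_sw, "paired")
  expect_equal(ds$delta_beta, -dd$delta_beta)
  expect_equal(ds$p_value, dd$p_value, tolerance = 1e-12)

  # unpaired mode is invariant to sample-column permutation
  du <- call_dmcs(beta, sheet, "unpaired")
  perm <- sample(ncol(beta))
  du2 <- call_dmcs(beta[, perm], sheet, "unpaired")
  expect_equal(du$p_value, du2$p_value, tolerance = 1e-12)

  # BH fdr is monotone in p and >= p
  ok <- !is.na(dd$p_value)
  expect_true(all(dd$fdr[ok] >= dd$p_value[ok]))
  o <- order(dd$p_value[ok])
  expect_true(all(diff(dd$fdr[ok][o]) >= -1e-15))
})

test_that("null data stays within the FDR budget", {
  set.seed(99)
  beta <- matrix(stats::rbeta(5000 * 40, 2, 5), 5000,
                 dimnames = list(paste0("p", 1:5000),
                                 c(paste0("T", 1:20), paste0("N", 1:20))))
  sheet <- data.frame(
    sample_id = colnames(beta), cohort = "X",
    tissue = rep(c("tumor", "adjacent_normal"), each = 20),
    patient_id = rep(paste0("P", 1:20), 2), stringsAsFactors = FALSE)
  d <- call_dmcs(beta, sheet, "unpaired")
  expect_lte(mean(d$direction != "ns"), 0.01 + 0.005)
})

test_that("region summarisation averages member CpGs, missing-aware", {
  ann <- data.frame(
    probe_id = paste0("p", 1:4), chrom = "chr1", pos = 1:4,
    cgi_relation = c("Island", "Island", "Island", "OpenSea"),
    gene = c("A", "A", "A", "A"),
    feature = c("TSS200", "TSS200", "Body", "Body"),
    snp = FALSE, stringsAsFactors = FALSE)
  beta <- matrix(c(0.2, 0.4, NA, 0.9,
                   0.2, NA, 0.6, 0.9), 4, 2,
                 dimnames = list(ann$probe_id, c("s1", "s2")))
  rs <- summarize_regions(beta, ann, scheme = "cgi")
  expect_equal(unname(rs$values["A|Island", "s1"]), 0.3)   # mean(0.2, 0.4)
  expect_equal(unname(rs$values["A|Island", "s2"]), 0.4)   # mean(0.2, 0.6)
  rs2 <- summarize_regions(beta, ann, scheme = "tss")
  expect_equal(unname(rs2$values["A|Body", "s1"]), 0.9)  # NA member dropped
  expect_equal(unname(rs2$values["A|Body", "s2"]), mean(c(0.6, 0.9)))
  # region reduced to one non-missing CpG equals that CpG
  expect_equal(unname(rs2$values["A|TSS200", "s2"]), 0.2)
})

test_that("region_differential counts planted shifts and nulls", {
  set.seed(12)
  ann <- data.frame(
    probe_id = paste0("p", 1:40), chrom = "chr1", pos = 1:40,
    cgi_relation = rep("Island", 40),
    gene = rep(paste0("G", 1:10), each = 4), feature = "Body",
    snp = FALSE, stringsAsFactors = FALSE)
  n_ <- matrix(stats::rnorm(40 * 30, 0.2, 0.03), 40)
  t_ <- n_
  t_[1:4, ] <- t_[1:4, ] + 0.4   # gene G1 hyper at the island level
  beta <- cbind(t_, n_)
  rownames(beta) <- ann$probe_id
  colnames(beta) <- c(paste0("T", 1:30), paste0("N", 1:30))
  sheet <- data.frame(
    sample_id = colnames(beta), cohort = "X",
    tissue = rep(c("tumor", "adjacent_normal"), each = 30),
    patient_id = rep(paste0("P", 1:30), 2), stringsAsFactors = FALSE)
  rs <- summarize_regions(beta, ann, "cgi")
  rd <- region_differential(rs, sheet)
  expect_equal(rd$counts$hyper[rd$counts$region == "Island"], 1)
  expect_gt(rd$counts$ns[rd$counts$region == "Island"], 0)
  expect_equal(sum(rd$counts$hypo), 0)
  # identical matrices -> all ns
  beta0 <- cbind(n_, n_)
  rownames(beta0) <- ann$probe_id; colnames(beta0) <- colnames(beta)
  rd0 <- region_differential(summarize_regions(beta0, ann, "cgi"), sheet)
  expect_true(all(rd0$table$direction == "ns"))
  # unpaired-only data errors with guidance
  sheet_un <- sheet; sheet_un$patient_id <- NA
  expect_error(region_differential(rs, sheet_un), "unpaired")
})

test_that("feature enrichment matches the hypergeometric oracle", {
  ann <- data.frame(
    probe_id = paste0("p", 1:60), chrom = "chr1", pos = 1:60,
    cgi_relation = rep(c("Island", "OpenSea"), times = c(30, 30)),
    gene = "G1", feature = "Body", snp = FALSE, stringsAsFactors = FALSE)
  # balanced table: no association
  hyper <- c(paste0("p", 1:10), paste0("p", 31:40))
  ref <- c(paste0("p", 11:20), paste0("p", 41:50))
  e0 <- feature_enrichment(hyper, ref, ann, "Island")
  expect_equal(e0$odds_ratio, 1)
  expect_equal(e0$p_value, 1)
  # a=20 b=5 c=5 d=20
  hyper2 <- c(paste0("p", 1:20), paste0("p", 31:35))
  ref2 <- c(paste0("p", 21:25), paste0("p", 36:55))
  e2 <- feature_enrichment(hyper2, ref2, ann, "Island")
  expect_equal(e2$odds_ratio, 16)
  expect_equal(e2$p_value, fisher_p_enum(20, 5, 5, 20), tolerance = 1e-10)
  expect_false(e2$degenerate)
  expect_true(e2$ci_lower > 1 && e2$ci_upper > e2$ci_lower)
  # zero cell: infinite OR, flagged
  hyper3 <- paste0("p", 1:10)         # all in Island (b = 0)
  ref3 <- c(paste0("p", 11:15), paste0("p", 31:40))
  e3 <- feature_enrichment(hyper3, ref3, ann, "Island")
  expect_true(is.infinite(e3$odds_ratio))
  expect_true(is.infinite(e3$ci_upper))
  expect_true(e3$degenerate)
  expect_error(feature_enrichment(character(0), ref, ann, "Island"),
               "non-empty")
})

test_that("Fisher p equals full enumeration over random small tables", {
  set.seed(123)
  ann <- data.frame(
    probe_id = paste0("p", 1:400), chrom = "chr1", pos = 1:400,
    cgi_relation = rep(c("Island", "OpenSea"), each = 200),
    gene = "G", feature = "Body", snp = FALSE, stringsAsFactors = FALSE)
  island <- paste0("p", 1:200); sea <- paste0("p", 201:400)
  for (rep_i in 1:25) {
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    c_ <- sample(0:40, 1); d <- sample(0:40, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    hyper <- c(sample(island, a), sample(sea, b))
    ref <- c(sample(island, c_), sample(sea, d))
    e <- feature_enrichment(hyper, ref, ann, "Island")
    expect_equal(e$p_value, fisher_p_enum(a, b, c_, d), tolerance = 1e-8)
  }
})
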