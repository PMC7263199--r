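test_that("information gain matches direct entropy enumeration", {
  # perfectly separating feature on balanced classes: 1 bit
  v <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(information_gain(v, y, n_bins = 2), 1)
  # independent feature: IG near 0 at large n
  set.seed(2)
  v2 <- stats::runif(5000)
  y2 <- rep(0:1, 2500)
  expect_lt(information_gain(v2, y2), 0.01)
  # oracle agreement on random inputs
  for (i in 1:20) {
    set.seed(i)
    n <- sample(50:200, 1)
    vv <- stats::rbeta(n, 2, 2)
    yy <- stats::rbinom(n, 1, stats::plogis(3 * (vv - 0.5)))
    if (length(unique(yy)) < 2) next
    nb <- sample(2:10, 1)
    expect_equal(information_gain(vv, yy, n_bins = nb),
                 ig_direct(vv, yy, nb), tolerance = 1e-12)
  }
  expect_error(information_gain(v, rep(1, 6)), "classes")
  expect_error(information_gain(rep(0.5, 6), y), "distinct")
})

test_that("feature ranking orders planted effect sizes", {
  set.seed(9)
  n <- 100
  y <- rep(0:1, each = n / 2)
  strong <- ifelse(y == 1, 0.8, 0.1) + stats::rnorm(n, 0, 0.05)
  weak <- ifelse(y == 1, 0.35, 0.25) + stats::rnorm(n, 0, 0.1)
  noise <- stats::runif(n)
  x <- rbind(strong = strong, weak = weak, noise = noise)
  colnames(x) <- paste0("s", 1:n)
  rk <- rank_features(x, y)
  expect_identical(rk$probe_id[1], "strong")
  expect_gt(rk$ig[1], rk$ig[3])
  # singleton ranking
  expect_identical(rank_features(x[1, , drop = FALSE], y)$probe_id, "strong")
  # equal-IG duplicate resolves by id
  x2 <- rbind(a_dup = strong, b_dup = strong)
  colnames(x2) <- colnames(x)
  expect_identical(rank_features(x2, y)$probe_id, c("a_dup", "b_dup"))
})

test_that("ridge logistic fit satisfies its optimality conditions", {
  set.seed(33)
  n <- 200
  X <- matrix(stats::rbeta(n * 3, 2, 2), n,
              dimnames = list(NULL, c("cg1", "cg2", "cg3")))
  y <- stats::rbinom(n, 1, 0.3)  # independent of X
  # under a strong penalty the null fit shrinks to the prevalence model
  fit_null <- fit_logistic(X, y, l2_lambda = 10)
  expect_lt(max(abs(fit_null$coefficients)), 0.05)
  expect_equal(fit_null$intercept, stats::qlogis(mean(y)), tolerance = 0.05)
  fit <- fit_logistic(X, y)
  # penalised-likelihood gradient vanishes at the solution
  eta <- fit$intercept + drop(X %*% fit$coefficients)
  mu <- stats::plogis(eta)
  grad_b <- drop(crossprod(X, y - mu)) / n - fit$l2_lambda * fit$coefficients
  grad_0 <- mean(y - mu)
  expect_lt(max(abs(c(grad_0, grad_b))), 1e-6)
  # agreement with glm at vanishing penalty
  fit0 <- fit_logistic(X, y, l2_lambda = 1e-10)
  ref <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(unname(fit0$coefficients), unname(stats::coef(ref)[-1]),
               tolerance = 1e-4)
  # separation stays finite and reaches training AUC 1
  ys <- as.integer(X[, 1] > 0.5)
  fs <- fit_logistic(X[, 1, drop = FALSE], ys)
  expect_true(is.finite(fs$coefficients))
  pr <- predict(fs, X[, 1, drop = FALSE])$prob
  expect_equal(roc_auc(pr, ys)$auc, 1)
  # duplicating every sample leaves the fit unchanged (lambda is per-obs)
  fit2 <- fit_logistic(rbind(X, X), c(y, y))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-6)
  expect_error(fit_logistic(X, rep(1, n)), "binary")
})

test_that("prediction follows the logistic closed form", {
  model <- structure(list(probes = "cg1", intercept = 0,
                          coefficients = c(cg1 = 2), l2_lambda = 1e-4,
                          decision_threshold = 0.5),
                     class = "methylmark_logit")
  X <- matrix(c(0.5, 0, 1), 3, dimnames = list(NULL, "cg1"))
  pr <- predict(model, X)
  expect_equal(pr$prob[1], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(pr$prob[2], 0.5)
  expect_true(pr$call[3])
  # monotone in a positive-coefficient feature
  expect_true(all(diff(predict(model,
                               matrix(seq(0, 1, 0.1),
                                      dimnames = list(NULL, "cg1")))$prob) > 0))
  # zero model predicts 0.5 everywhere
  m0 <- model; m0$coefficients <- c(cg1 = 0)
  expect_true(all(predict(m0, X)$prob == 0.5))
  expect_error(predict(model, matrix(1, 1, 1, dimnames = list(NULL, "cgX"))),
               "cg1")
})

test_that("AUC equals concordant-pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  # label swap maps AUC to 1 - AUC
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.2), c(0, 0, 1, 1))$auc, 0.25)
  # oracle agreement on random data with ties
  for (i in 1:15) {
    set.seed(i)
    n <- sample(20:500, 1)
    s <- round(stats::runif(n), 2)  # force ties
    l <- stats::rbinom(n, 1, 0.4)
    if (sum(l) == 0 || sum(l) == n) next
    r <- roc_auc(s, l)
    expect_equal(r$auc, auc_pairs(s, l), tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
    expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
    expect_equal(c(max(r$tpr), max(r$fpr)), c(1, 1))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "classes")
})

test_that("AUC implementation agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(77)
  s <- stats::rnorm(100)
  l <- stats::rbinom(100, 1, 0.5)
  expect_equal(roc_auc(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("progressive evaluation tracks panel size correctly", {
  set.seed(44)
  n <- 120
  y <- rep(0:1, each = n / 2)
  sep <- vapply(1:4, function(i)
    ifelse(y == 1, 0.7, 0.1) + stats::rnorm(n, 0, 0.04), numeric(n))
  colnames(sep) <- paste0("m", 1:4)
  noise <- matrix(stats::runif(n * 4), n, dimnames = list(NULL, paste0("z", 1:4)))
  yt <- rep(0:1, each = 30)
  sep_t <- vapply(1:4, function(i)
    ifelse(yt == 1, 0.7, 0.1) + stats::rnorm(60, 0, 0.04), numeric(60))
  colnames(sep_t) <- paste0("m", 1:4)
  noise_t <- matrix(stats::runif(60 * 4), 60,
                    dimnames = list(NULL, paste0("z", 1:4)))
  # separable planted markers: AUC 1 at every k
  pe <- progressive_evaluation(paste0("m", 1:4), sep, y, sep_t, yt)
  expect_true(all(pe$test_auc == 1))
  # training log-likelihood non-decreasing in k
  expect_true(all(diff(pe$train_loglik) >= -1e-8))
  # pure noise: test AUC hovers around 0.5
  pn <- progressive_evaluation(paste0("z", 1:4), noise, y, noise_t, yt)
  expect_true(all(abs(pn$test_auc - 0.5) < 0.25))
  expect_error(progressive_evaluation(paste0("m", 1:4), sep, y, sep_t, yt,
                                      k_max = 5),
               "k_max")
})

test_that("cross-cohort misclassification separates target-like cohorts", {
  set.seed(55)
  n <- 40
  mk <- function(mu) matrix(pmin(pmax(stats::rnorm(2 * n, mu, 0.05), 0), 1),
                            2, dimnames = list(c("cg1", "cg2"), NULL))
  tum <- mk(0.6); nor <- mk(0.1)
  X <- t(cbind(tum, nor))
  y <- rep(1:0, each = n)
  model <- fit_logistic(X, y)
  hi <- mk(0.6); lo <- mk(0.1); single <- mk(0.6)[, 1, drop = FALSE]
  beta <- cbind(hi, lo, single)
  colnames(beta) <- c(paste0("H", 1:n), paste0("L", 1:n), "S1")
  sheet <- data.frame(
    sample_id = colnames(beta),
    cohort = c(rep("LIKE", n), rep("UNLIKE", n), "ONE"),
    tissue = "tumor", patient_id = NA, stringsAsFactors = FALSE)
  mm <- cross_cohort_misclassification(model, beta, sheet)
  expect_gt(mm$pct_called_target[mm$cohort == "LIKE"], 95)
  expect_lt(mm$pct_called_target[mm$cohort == "UNLIKE"], 5)
  expect_true(mm$pct_called_target[mm$cohort == "ONE"] %in% c(0, 100))
})
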