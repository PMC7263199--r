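#' Information gain of a continuous feature for a binary label
#'
#' Discretises the feature into equal-frequency quantile bins and computes
#' `IG = H(labels) - sum_b p(b) H(labels | bin b)` in bits (log base 2).
#'
#' @param values numeric feature vector (>= 2 distinct values).
#' @param labels binary labels (two classes present), same length.
#' @param n_bins number of quantile bins (default 10).
#' @return information gain in bits (non-negative).
#' @export
information_gain <- function(values, labels, n_bins = 10) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  .assert(length(unique(labels)) == 2, "labels must contain both classes")
  .assert(length(unique(values)) >= 2, "need >= 2 distinct values")
  breaks <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(values, breaks = breaks, include.lowest = TRUE)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_y <- h(prop.table(table(labels)))
  tab <- table(bins, labels)
  pb <- rowSums(tab) / sum(tab)
  h_cond <- sum(vapply(seq_len(nrow(tab)), function(i) {
    if (pb[i] == 0) return(0)
    pb[i] * h(tab[i, ] / sum(tab[i, ]))
  }, numeric(1)))
  max(h_y - h_cond, 0)
}

#' Rank probes by information gain
#'
#' Computes the information gain of each probe's beta values for the binary
#' sample labels and returns the probes in descending IG order, ties broken
#' by probe id.
#'
#' @param beta_subset probes x samples beta matrix.
#' @param labels binary labels aligned with the columns.
#' @param n_bins quantile bins passed to [information_gain()].
#' @return data.frame `probe_id`, `ig`, sorted.
#' @export
rank_features <- function(beta_subset, labels, n_bins = 10) {
  .assert(nrow(beta_subset) >= 1, "need >= 1 probe")
  ig <- vapply(seq_len(nrow(beta_subset)), function(i)
    information_gain(beta_subset[i, ], labels, n_bins), numeric(1))
  d <- data.frame(probe_id = rownames(beta_subset), ig = ig,
                  stringsAsFactors = FALSE)
  d[order(-d$ig, d$probe_id), , drop = FALSE]
}

#' Fit a ridge-penalised logistic regression
#'
#' Maximum penalised likelihood by iteratively reweighted least squares
#' (Newton iterations on the average log-likelihood plus
#' `lambda/2 * ||coef||^2`; the intercept is not penalised). The
#' per-observation scaling of the penalty makes the fit invariant to
#' duplicating every sample, and the penalty keeps coefficients finite
#' under complete separation.
#'
#' @param X samples x probes matrix of beta values.
#' @param y binary response (0/1, logical, or two-level factor).
#' @param l2_lambda ridge penalty (default 1e-4).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   max absolute coefficient change.
#' @return a `methylmark_logit` model: `probes`, `intercept`,
#'   `coefficients`, `l2_lambda`, `n_iter`, `converged`,
#'   `decision_threshold`.
#' @export
fit_logistic <- function(X, y, l2_lambda = 1e-4, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  .assert(length(unique(y)) == 2 && all(y %in% c(0, 1)),
          "y must be binary with both classes present")
  .assert(nrow(X) == length(y), "X rows must match y")
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, p + 1)
  pen <- c(0, rep(l2_lambda, p))  # intercept unpenalised
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xa, y - mu)) / n - pen * beta
    hess <- crossprod(Xa * w, Xa) / n + diag(pen, p + 1)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- simpleError("IRLS did not converge")
    cond$last_iterate <- beta
    stop(cond)
  }
  structure(list(probes = colnames(X), intercept = unname(beta[1]),
                 coefficients = stats::setNames(beta[-1], colnames(X)),
                 l2_lambda = l2_lambda, n_iter = it, converged = converged,
                 decision_threshold = 0.5),
            class = "methylmark_logit")
}

#' @export
print.methylmark_logit <- function(x, ...) {
  cat("Ridge logistic diagnostic model (", length(x$probes), " CpGs, lambda=",
      x$l2_lambda, ")\n", sep = "")
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Predict with a diagnostic logistic model
#'
#' @param object a `methylmark_logit` model.
#' @param X samples x probes matrix; columns must cover the model's probes
#'   (matched by name).
#' @param threshold probability cut for class calls (default the model's
#'   `decision_threshold`).
#' @param ... unused.
#' @return data.frame `prob` (predicted target-class probability) and
#'   `call` (logical class call).
#' @export
predict.methylmark_logit <- function(object, X, threshold = NULL, ...) {
  X <- as.matrix(X)
  missing <- setdiff(object$probes, colnames(X))
  if (length(missing))
    stop("X lacks model probes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(threshold)) threshold <- object$decision_threshold
  eta <- object$intercept +
    drop(X[, object$probes, drop = FALSE] %*% object$coefficients)
  prob <- stats::plogis(eta)
  data.frame(prob = prob, call = prob >= threshold,
             row.names = rownames(X), stringsAsFactors = FALSE)
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney concordance identity (ties credited 0.5); the
#' curve is traced over the sorted unique score thresholds.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1/TRUE = positive), both classes present.
#' @return a `roc_result` list: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  .assert(npos > 0 && nneg > 0, "both classes must be present")
  r <- rank(scores)  # midranks: ties get 0.5 credit
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over", length(x$thresholds), "thresholds; AUC =",
      round(x$auc, 4), "\n")
  invisible(x)
}

# average (per-observation) unpenalised log-likelihood of a fitted model
.logit_loglik <- function(model, X, y) {
  eta <- model$intercept +
    drop(as.matrix(X)[, model$probes, drop = FALSE] %*% model$coefficients)
  # numerically stable log-likelihood via log-scale logistic cdf
  mean(y * stats::plogis(eta, log.p = TRUE) +
         (1 - y) * stats::plogis(-eta, log.p = TRUE))
}

#' Progressive model evaluation over a feature ranking
#'
#' For k = 1..`k_max`, fits the logistic model on the top-k ranked probes of
#' the training set and evaluates the AUC on the test set, mirroring a
#' cost-effectiveness curve over panel size.
#'
#' @param ranking ordered probe ids (e.g. from [rank_features()]).
#' @param X_train,y_train training design (samples x probes) and labels.
#' @param X_test,y_test test design and labels.
#' @param k_max largest panel size (<= length of ranking).
#' @param l2_lambda ridge penalty passed to [fit_logistic()].
#' @return data.frame `k`, `probe_added`, `train_loglik`, `train_auc`,
#'   `test_auc`.
#' @export
progressive_evaluation <- function(ranking, X_train, y_train, X_test, y_test,
                                   k_max = length(ranking),
                                   l2_lambda = 1e-4) {
  .assert(k_max <= length(ranking), "k_max exceeds the ranking length")
  out <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    probes <- ranking[seq_len(k)]
    fit <- fit_logistic(as.matrix(X_train)[, probes, drop = FALSE], y_train,
                        l2_lambda = l2_lambda)
    pr_tr <- predict(fit, as.matrix(X_train)[, probes, drop = FALSE])$prob
    pr_te <- predict(fit, as.matrix(X_test)[, probes, drop = FALSE])$prob
    out[[k]] <- data.frame(
      k = k, probe_added = probes[k],
      train_loglik = .logit_loglik(fit, as.matrix(X_train)[, probes,
                                                           drop = FALSE],
                                   as.numeric(y_train)),
      train_auc = roc_auc(pr_tr, y_train)$auc,
      test_auc = roc_auc(pr_te, y_test)$auc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cross-cohort misclassification of a diagnostic model
#'
#' Applies the model to every (cohort, tissue class) group and reports the
#' percentage of samples classified as the target class at the decision
#' threshold — the specificity screen against other cancers and normals.
#'
#' @param model a `methylmark_logit`.
#' @param beta probes x samples beta matrix covering the model's probes.
#' @param sheet sample sheet for the columns of `beta`.
#' @param threshold probability cut (default the model's).
#' @return data.frame `cohort`, `tissue`, `n`, `pct_called_target`.
#' @export
cross_cohort_misclassification <- function(model, beta, sheet,
                                           threshold = NULL) {
  sh <- sheet[sheet$sample_id %in% colnames(beta), ]
  .assert(nrow(sh) > 0, "no samples shared between beta and sheet")
  key <- paste(sh$cohort, sh$tissue, sep = "|")
  out <- lapply(split(seq_len(nrow(sh)), key), function(idx) {
    ids <- sh$sample_id[idx]
    pr <- predict(model, t(beta[model$probes, ids, drop = FALSE]),
                  threshold = threshold)
    data.frame(cohort = sh$cohort[idx[1]], tissue = sh$tissue[idx[1]],
               n = length(ids), pct_called_target = 100 * mean(pr$call),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
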