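# Internal row-wise statistics tolerant of missing values. These back the
# genome-scale differential paths where per-row t.test() calls are too slow.

.row_n <- function(x) rowSums(!is.na(x))

.row_mean <- function(x) rowMeans(x, na.rm = TRUE)

.row_var <- function(x) {
  n <- .row_n(x)
  m <- .row_mean(x)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  v <- ss / (n - 1)
  v[n < 2] <- NA_real_
  v
}

.row_sd <- function(x) sqrt(.row_var(x))

# Paired t on a matrix of per-pair differences (rows = features).
.paired_t_rows <- function(d) {
  n <- .row_n(d)
  m <- .row_mean(d)
  s <- .row_sd(d)
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  # constant differences: no sampling variance left
  degen <- !is.na(s) & s == 0
  p[degen & m == 0] <- 1
  p[degen & m != 0] <- 0
  p[n < 2] <- NA_real_
  list(estimate = m, p = p, n = n)
}

# Welch two-sample t, row-wise.
.welch_t_rows <- function(x, y) {
  nx <- .row_n(x); ny <- .row_n(y)
  mx <- .row_mean(x); my <- .row_mean(y)
  vx <- .row_var(x); vy <- .row_var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- !is.na(se2) & se2 == 0
  p[degen & mx == my] <- 1
  p[degen & mx != my] <- 0
  p[nx < 2 | ny < 2] <- NA_real_
  list(estimate = mx - my, p = p, n = pmin(nx, ny))
}

# Wilcoxon row-wise fallback for non-normal beta distributions. Exact
# enumeration up to n = 25, normal approximation with continuity correction
# above; zero differences dropped (signed-rank convention).
.wilcox_rows <- function(x, y, paired) {
  nr <- nrow(x)
  p <- rep(NA_real_, nr)
  for (i in seq_len(nr)) {
    xi <- x[i, ]; yi <- y[i, ]
    if (paired) {
      ok <- !is.na(xi) & !is.na(yi)
      xi <- xi[ok]; yi <- yi[ok]
      if (all(xi == yi)) { p[i] <- 1; next }  # all zero diffs: degenerate
      n_eff <- sum(xi != yi)
    } else {
      xi <- xi[!is.na(xi)]; yi <- yi[!is.na(yi)]
      n_eff <- min(length(xi), length(yi))
    }
    p[i] <- tryCatch(
      suppressWarnings(stats::wilcox.test(
        xi, yi, paired = paired, exact = n_eff <= 25,
        correct = TRUE)$p.value),
      error = function(e) NA_real_)
  }
  list(estimate = .row_mean(x) - .row_mean(y), p = p,
       n = pmin(.row_n(x), .row_n(y)))
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Seeds derived from a master seed stay below 2^31.
.derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
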