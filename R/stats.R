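# Group-comparison machinery: normality-gated two-sample tests, an exact
# rank-sum test (dynamic programming over midranks, exact for the study's
# n <= 25 scale), Pearson chi-square, Benjamini-Hochberg FDR with the
# study's correction families, and percentile bootstrap CIs.

#' Exact/two-sided Wilcoxon rank-sum test
#'
#' For combined sample sizes up to `exact_limit` the two-sided p-value is
#' computed from the exact permutation distribution of the rank sum, with
#' ties handled by midranks (dynamic programming over doubled midranks, so
#' the null distribution is exact even with ties). Larger samples use the
#' normal approximation with tie-corrected variance and no continuity
#' correction.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param exact_limit Maximum combined size for exact enumeration
#'   (default 25).
#' @return List with `statistic` (rank sum W of `a`), `u` (Mann-Whitney U),
#'   `p`, and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 25L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))                       # midranks
  w <- sum(r[seq_len(n_a)])
  u <- w - n_a * (n_a + 1) / 2
  if (n <= exact_limit) {
    d <- as.integer(round(2 * r))          # doubled midranks: integers
    p <- .exact_ranksum_p(d, n_a, w_obs = 2 * w)
    method <- "exact"
  } else {
    mu <- n_a * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(statistic = w, u = u, p = min(1, p), method = method)
}

# Exact two-sided p for the rank-sum statistic on integer scores `d`
# (doubled midranks), choosing n_a of them. Distribution by DP over
# (count chosen, score sum); p = P(|S - E S| >= |w_obs - E S|).
.exact_ranksum_p <- function(d, n_a, w_obs) {
  n <- length(d)
  s_max <- sum(d)
  # f[k+1, s+1] = number of size-k subsets with sum s
  f <- matrix(0, n_a + 1L, s_max + 1L)
  f[1L, 1L] <- 1
  for (x in d) {
    for (k in n_a:1L) {
      src <- f[k, seq_len(s_max + 1L - x)]
      idx <- (x + 1L):(s_max + 1L)
      f[k + 1L, idx] <- f[k + 1L, idx] + src
    }
  }
  counts <- f[n_a + 1L, ]
  total <- sum(counts)
  sums <- 0:s_max
  e_s <- sum(counts * sums) / total
  dev <- abs(w_obs - e_s)
  sum(counts[abs(sums - e_s) >= dev - 1e-9]) / total
}

#' Normality-gated two-sample comparison
#'
#' Shapiro-Wilk on each sample at level `alpha`; if both pass, an
#' independent two-sample Student t-test with mean (SD) summaries, otherwise
#' the Wilcoxon rank-sum test with median (IQR) summaries. Degenerate
#' zero-variance inputs return p = 1 with a warning.
#'
#' @param a,b Numeric samples, each with >= 3 values.
#' @param alpha Shapiro-Wilk gate level (default 0.05).
#' @param feature Optional feature identifier carried into the result.
#' @return A one-row data frame of class `comparison_result`: feature, test,
#'   statistic, p_raw, and per-group summary strings.
#' @export
normality_gate_compare <- function(a, b, alpha = 0.05, feature = NA_character_) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) stop("each sample needs >= 3 values")
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate) {
    warning("both samples constant; comparison is degenerate")
    normal <- FALSE
  } else {
    sw_ok <- function(x) {
      if (stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value > alpha
    }
    normal <- sw_ok(a) && sw_ok(b)
  }
  if (normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value; test <- "t"
    summ <- function(x) sprintf("%.4g (%.4g)", mean(x), stats::sd(x))
  } else {
    if (degenerate) {
      stat <- NA_real_; p <- 1; test <- "degenerate"
    } else {
      wr <- wilcoxon_rank_sum(a, b)
      stat <- wr$statistic; p <- wr$p; test <- paste0("wilcoxon_", wr$method)
    }
    summ <- function(x) sprintf("%.4g (%.4g-%.4g)", stats::median(x),
                                stats::quantile(x, 0.25),
                                stats::quantile(x, 0.75))
  }
  out <- data.frame(feature = feature, test = test, statistic = stat,
                    p_raw = p, summary_a = summ(a), summary_b = summ(b),
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction,
#' `X2 = sum (O - E)^2 / E`, df = (r-1)(k-1).
#'
#' @param table Matrix of non-negative integer counts with positive margins.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_counts <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table")
  }
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard BH step-up: sort ascending, `adj(i) = min_{j >= i} N p(j) / j`,
#' clipped to 1, returned in the input order. Monotone in the raw p-values.
#'
#' @param pvalues Numeric vector in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  n <- length(pv)
  if (n) {
    o <- order(pv)
    adj <- pmin(1, rev(cummin(rev(n * pv[o] / seq_len(n)))))
    tmp <- rep(NA_real_, n)
    tmp[o] <- adj
    out[ok] <- tmp
  }
  out
}

#' Apply an FDR correction scheme to a table of comparisons
#'
#' Adds a `p_fdr` column by applying [bh_fdr()] within each correction
#' family:
#' * `per_band_across_electrodes` - one family per band, across channels
#'   (N = 19 for the full montage); used for spectral power, complexity maps
#'   (band = scale) and nodal efficiency.
#' * `per_connection_across_bands` - one family per connection, across the
#'   five bands (N = 5); used for pairwise wPLI.
#' * `none` - no correction (`p_fdr = NA`); used for the global/local
#'   efficiency and small-world sparsity sweeps.
#'
#' @param results Data frame with a `p_raw` column plus the grouping keys the
#'   scheme needs (`band` and `channel`, or `chan_i`/`chan_j` and `band`).
#' @param scheme One of `"per_band_across_electrodes"`,
#'   `"per_connection_across_bands"`, `"none"`.
#' @return `results` with a `p_fdr` column appended.
#' @export
fdr_scheme <- function(results,
                       scheme = c("per_band_across_electrodes",
                                  "per_connection_across_bands", "none")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(results), "p_raw" %in% names(results))
  if (scheme == "none") {
    results$p_fdr <- NA_real_
    return(results)
  }
  key <- switch(scheme,
    per_band_across_electrodes = {
      if (!"band" %in% names(results)) stop("scheme needs a 'band' column")
      results$band
    },
    per_connection_across_bands = {
      if (!all(c("chan_i", "chan_j") %in% names(results))) {
        stop("scheme needs 'chan_i' and 'chan_j' columns")
      }
      paste(results$chan_i, results$chan_j)
    })
  results$p_fdr <- NA_real_
  for (k in unique(key)) {
    idx <- which(key == k)
    results$p_fdr[idx] <- bh_fdr(results$p_raw[idx])
  }
  results
}

#' Percentile bootstrap confidence interval for the mean
#'
#' Resamples with replacement `n_boot` times, recomputes the mean, and
#' returns the percentile interval of the bootstrap distribution.
#'
#' @param x Numeric sample with >= 2 values.
#' @param n_boot Number of resamples (default 1000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param seed Integer seed.
#' @return Numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(x, n_boot = 1000L, level = 0.95, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("sample too small for a bootstrap interval")
  if (!(level > 0 && level < 1)) stop("level must lie in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                nrow = length(x))
  means <- colMeans(matrix(x[idx], nrow = length(x)))
  alpha <- (1 - level) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
}

#' Group contrast over a long-format feature table
#'
#' Runs the Wilcoxon rank-sum test for every feature (combination of the
#' `by` columns) between the two groups, with optional bootstrap CIs on the
#' group means, and applies an FDR scheme.
#'
#' @param df Long data frame with columns `group`, `value`, plus feature
#'   keys.
#' @param by Character vector of feature-key column names.
#' @param groups Two group labels, `c(a, b)`; defaults to sorted unique.
#' @param scheme Passed to [fdr_scheme()].
#' @param n_boot Bootstrap resamples per group mean (0 = skip CIs).
#' @param seed Bootstrap seed.
#' @return Data frame: one row per feature with medians, statistic, p_raw,
#'   p_fdr, and optional CI bounds.
#' @export
group_contrast_table <- function(df, by, groups = NULL, scheme = "none",
                                 n_boot = 0L, seed = 1L) {
  stopifnot(all(c("group", "value", by) %in% names(df)))
  if (is.null(groups)) groups <- sort(unique(df$group))
  stopifnot(length(groups) == 2L)
  keys <- unique(df[, by, drop = FALSE])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(df))
    for (col in by) sel <- sel & df[[col]] == keys[[col]][i]
    a <- df$value[sel & df$group == groups[1]]
    b <- df$value[sel & df$group == groups[2]]
    wr <- wilcoxon_rank_sum(a, b)
    row <- keys[i, , drop = FALSE]
    row$median_a <- stats::median(a)
    row$median_b <- stats::median(b)
    row$statistic <- wr$statistic
    row$p_raw <- wr$p
    if (n_boot > 0) {
      ci_a <- bootstrap_ci(a, n_boot, seed = seed + 2L * i)
      ci_b <- bootstrap_ci(b, n_boot, seed = seed + 2L * i + 1L)
      row$ci_lo_a <- ci_a[1]; row$ci_hi_a <- ci_a[2]
      row$ci_lo_b <- ci_b[1]; row$ci_hi_b <- ci_b[2]
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fdr_scheme(out, scheme)
}
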