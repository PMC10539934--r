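test_that("exact rank-sum p equals full enumeration on small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p, 1 / 3,
               tolerance = 1e-12)
  # identical samples with ties: exchangeable, p = 1
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p, 1)
  # against explicit enumeration for all splits with combined n <= 10
  enum_p <- function(a, b) {
    x <- c(a, b); n_a <- length(a)
    r <- rank(x)
    w_obs <- sum(r[seq_len(n_a)])
    combs <- combn(length(x), n_a)
    ws <- apply(combs, 2, function(idx) sum(r[idx]))
    e <- mean(ws)
    mean(abs(ws - e) >= abs(w_obs - e) - 1e-9)
  }
  set.seed(20)
  for (rep in 1:10) {
    n_a <- sample(2:5, 1); n_b <- sample(2:5, 1)
    a <- round(rnorm(n_a), 1)   # rounding induces occasional ties
    b <- round(rnorm(n_b), 1)
    expect_equal(wilcoxon_rank_sum(a, b)$p, enum_p(a, b), tolerance = 1e-12)
  }
  # agrees with stats::wilcox.test exact p when there are no ties
  a <- c(0.3, 1.7, -0.4, 2.2, 0.9); b <- c(-1.1, 0.1, 0.5, -0.8)
  expect_equal(wilcoxon_rank_sum(a, b)$p,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("rank-sum power at the study scale is adequate for a 2 SD shift", {
  set.seed(31)
  rej <- mean(vapply(1:200, function(i) {
    a <- rnorm(13); b <- rnorm(12, mean = 2)
    wilcoxon_rank_sum(a, b)$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.9)
})

test_that("normality gate routes to the right test", {
  set.seed(5)
  a <- rnorm(100); b <- rnorm(100)
  res <- normality_gate_compare(a, b)
  expect_identical(res$test, "t")
  expect_gt(res$p_raw, 0.5)
  # identical large Gaussian samples: p ~ 1
  res_same <- normality_gate_compare(a, a)
  expect_gt(res_same$p_raw, 0.9)
  # skewed samples fail the Shapiro gate almost surely at n = 50
  routed <- vapply(1:20, function(i) {
    normality_gate_compare(rexp(50), rexp(50))$test
  }, character(1))
  expect_gt(mean(grepl("wilcoxon", routed)), 0.9)
  expect_warning(res_deg <- normality_gate_compare(rep(1, 5), rep(1, 5)),
                 "degenerate")
  expect_equal(res_deg$p_raw, 1)
  expect_error(normality_gate_compare(1:2, 1:5), ">= 3")
})

test_that("chi-square matches the hand formula", {
  tab <- rbind(c(8, 5), c(5, 7))
  res <- chi_square_counts(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expd)^2 / expd), tolerance = 1e-12)
  expect_identical(res$df, 1)
  # perfectly proportional table: statistic 0, p 1
  prop <- rbind(c(10, 20), c(5, 10))
  expect_equal(chi_square_counts(prop)$statistic, 0)
  expect_equal(chi_square_counts(prop)$p, 1)
  expect_error(chi_square_counts(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  # against stats::p.adjust on random vectors, including permutation
  set.seed(6)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  }
  # monotone in raw p
  p <- runif(25)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fdr_scheme applies the study's correction families", {
  df <- data.frame(band = rep(c("delta", "theta"), each = 19),
                   channel = rep(MONTAGE_19, 2),
                   p_raw = runif(38))
  out <- fdr_scheme(df, "per_band_across_electrodes")
  for (b in c("delta", "theta")) {
    sel <- out$band == b
    expect_equal(out$p_fdr[sel], bh_fdr(out$p_raw[sel]))
  }
  # per connection across the five bands: N = 5 families
  df2 <- expand.grid(band = names(eeg_bands()), chan_i = "Fp1",
                     chan_j = c("F3", "F4"), stringsAsFactors = FALSE)
  df2$p_raw <- runif(nrow(df2))
  out2 <- fdr_scheme(df2, "per_connection_across_bands")
  sel <- out2$chan_j == "F3"
  expect_equal(out2$p_fdr[sel], bh_fdr(out2$p_raw[sel]))
  out3 <- fdr_scheme(df, "none")
  expect_true(all(is.na(out3$p_fdr)))
  expect_error(fdr_scheme(data.frame(p_raw = 0.5), "per_band_across_electrodes"),
               "band")
})

test_that("bootstrap CI is deterministic, degenerate-safe and calibrated", {
  expect_equal(bootstrap_ci(rep(3, 10), 200, seed = 1), c(3, 3))
  ci1 <- bootstrap_ci(rnorm(25), 500, seed = 7)
  ci2 <- bootstrap_ci(rnorm(25), 500, seed = 7)  # RNG state restored inside
  set.seed(99); x <- rnorm(25)
  expect_identical(bootstrap_ci(x, 500, seed = 7), bootstrap_ci(x, 500, seed = 7))
  expect_lt(bootstrap_ci(x, 500, seed = 7)[1], bootstrap_ci(x, 500, seed = 7)[2])
  expect_error(bootstrap_ci(1, 100), "too small")
})

test_that("group_contrast_table runs per feature and corrects within families", {
  set.seed(12)
  df <- expand.grid(subject = paste0("s", 1:10), channel = MONTAGE_19[1:4],
                    band = c("delta", "theta"), stringsAsFactors = FALSE)
  df$group <- ifelse(as.integer(sub("s", "", df$subject)) <= 5, "HC", "MCI")
  df$value <- rnorm(nrow(df)) +
    ifelse(df$channel == "Fp1" & df$band == "theta" & df$group == "MCI", 3, 0)
  out <- group_contrast_table(df, by = c("band", "channel"),
                              groups = c("HC", "MCI"),
                              scheme = "per_band_across_electrodes")
  expect_identical(nrow(out), 8L)
  hit <- out[out$band == "theta" & out$channel == "Fp1", ]
  expect_lt(hit$p_raw, 0.01)
  expect_true(hit$median_a < hit$median_b)
  expect_true(all(out$p_fdr >= out$p_raw - 1e-12))
})
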