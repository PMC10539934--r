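# Independent brute-force oracles, deliberately written with the plainest
# possible algorithms (double loops, Floyd-Warshall, explicit enumeration)
# so they share no code path with the package implementations.

# --- entropy ---------------------------------------------------------------

# Sample entropy by explicit O(N^2) template comparison (Chebyshev distance,
# self-matches excluded, both template sets of size N - m).
oracle_sampen <- function(y, m = 1L, r = 0.25, r_abs = NULL) {
  n <- length(y)
  if (is.null(r_abs)) r_abs <- r * sd(y)
  nm <- n - m
  B <- 0; A <- 0
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      dm <- max(abs(y[i:(i + m - 1)] - y[j:(j + m - 1)]))
      if (dm <= r_abs) {
        B <- B + 1
        if (abs(y[i + m] - y[j + m]) <= r_abs) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NaN)
  -log(A / B)
}

# Permutation entropy by explicit motif enumeration.
oracle_pe <- function(y, m = 3L) {
  n <- length(y)
  pats <- character(0)
  for (i in seq_len(n - m + 1)) {
    pats <- c(pats, paste(order(y[i:(i + m - 1)]), collapse = "-"))
  }
  p <- table(pats) / length(pats)
  -sum(p * log2(p))
}

# --- wPLI ------------------------------------------------------------------

oracle_wpli <- function(terms) {
  num <- 0; den <- 0
  for (z in terms) {
    num <- num + Im(z)
    den <- den + abs(Im(z))
  }
  if (den == 0) return(0)
  abs(num / length(terms)) / (den / length(terms))
}

# --- graphs ----------------------------------------------------------------

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    vals[i] <- if (length(nb) < 2) 0 else
      oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_nodal_efficiency <- function(adj, i) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  tot <- 0
  for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  tot / (n - 1)
}

# clustering by explicit triangle counting
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (adj[nb[a], nb[b]] != 0) tri <- tri + 1
    }
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  list(per_node = ci, mean = mean(ci))
}

oracle_path_length <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# random small adjacency matrix (symmetric, zero diagonal)
random_adj <- function(n, p = 0.4) {
  a <- matrix(runif(n * n) < p, n, n)
  a[lower.tri(a, diag = TRUE)] <- FALSE
  a <- a | t(a)
  a
}

# --- signal fixtures -------------------------------------------------------

# epoch_set holding one channel, built from a vector
es_from_vector <- function(x, fs = 200, epoch_length = 2, channel = "Cz") {
  n_samp <- round(fs * epoch_length)
  n_ep <- length(x) %/% n_samp
  arr <- array(NA_real_, c(n_ep, 1, n_samp))
  for (e in seq_len(n_ep)) {
    arr[e, 1, ] <- x[((e - 1) * n_samp + 1):(e * n_samp)]
  }
  epoch_set(arr, fs, epoch_length, channels = channel)
}

# epoch_set from a channels x samples matrix
es_from_matrix <- function(m, fs = 200, epoch_length = 2,
                           channels = MONTAGE_19[seq_len(nrow(m))]) {
  n_samp <- round(fs * epoch_length)
  n_ep <- ncol(m) %/% n_samp
  arr <- array(NA_real_, c(n_ep, nrow(m), n_samp))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- m[, ((e - 1) * n_samp + 1):(e * n_samp)]
  }
  epoch_set(arr, fs, epoch_length, channels = channels)
}

# small cohort spec used by pipeline-level tests (scaled down for runtime;
# group effects identical in kind to the defaults)
small_cohort_spec <- function(seed = 1L, n_hc = 5L, n_mci = 5L,
                              duration = 24) {
  cohort_spec(n_hc = n_hc, n_mci = n_mci, duration = duration, seed = seed)
}
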