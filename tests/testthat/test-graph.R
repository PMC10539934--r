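test_that("binarize_top_n retains exactly the strongest N edges", {
  set.seed(1)
  w <- matrix(runif(19 * 19), 19, 19)
  w <- (w + t(w)) / 2; diag(w) <- 0
  rownames(w) <- colnames(w) <- MONTAGE_19
  g <- binarize_top_n(w, 0.1)
  expect_identical(graph_edge_count(g), 17L)          # round(0.1 * 171)
  expect_identical(graph_edge_count(binarize_top_n(w, 1)), 171L)
  # retained edges are the largest weights
  ut <- w[upper.tri(w)]
  thr <- sort(ut, decreasing = TRUE)[17]
  expect_true(all(w[g$adj & upper.tri(w)] >= thr))
  # a matrix with exactly 5 positive weights
  w2 <- matrix(0, 6, 6)
  w2[1, 2] <- w2[2, 3] <- w2[3, 4] <- w2[4, 5] <- w2[5, 6] <- 0.5
  w2 <- w2 + t(w2)
  g2 <- binarize_top_n(w2, 5 / 15)
  expect_identical(unname(graph_edges(g2)),
                   cbind(c("v1", "v2", "v3", "v4", "v5"),
                         c("v2", "v3", "v4", "v5", "v6")))
  expect_error(binarize_top_n(w, 0), "sparsity")
})

test_that("shortest paths, efficiency, clustering and L match closed forms", {
  k4 <- make_graph_fixture("complete", 4)
  expect_true(all(shortest_path_lengths(k4)[upper.tri(diag(4))] == 1))
  expect_equal(global_efficiency(k4), 1)
  expect_equal(local_efficiency(k4), 1)
  expect_equal(clustering_coefficient(k4)$mean, 1)
  expect_equal(characteristic_path_length(k4), 1)

  p4 <- make_graph_fixture("path", 4)
  d <- shortest_path_lengths(p4)
  expect_equal(d[1, 4], 3)
  expect_equal(global_efficiency(p4), 13 / 18)
  expect_equal(characteristic_path_length(p4), 5 / 3)
  expect_equal(nodal_efficiency(p4, 1), 11 / 18)

  star4 <- make_graph_fixture("star", 4)
  expect_equal(local_efficiency(star4), 0)
  expect_equal(clustering_coefficient(star4)$mean, 0)

  tri <- binary_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  expect_equal(local_efficiency(tri), 1)
  expect_equal(clustering_coefficient(tri)$mean, 1)

  ring4 <- make_graph_fixture("ring_lattice", 4, list(k = 2))
  expect_equal(characteristic_path_length(ring4), 4 / 3)

  # empty graph
  empty <- binary_graph(matrix(FALSE, 4, 4))
  expect_equal(global_efficiency(empty), 0)
  expect_true(is.infinite(shortest_path_lengths(empty)[1, 2]))
  expect_true(is.nan(characteristic_path_length(empty)))

  # disconnected pairs: Inf under the strict convention, dropped by default
  two <- binary_graph(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                            c(0, 0, 0, 1), c(0, 0, 1, 0)))
  expect_true(is.infinite(shortest_path_lengths(two)[1, 3]))
  expect_equal(characteristic_path_length(two), 1)
  expect_true(is.infinite(characteristic_path_length(two, "inf")))
})

test_that("all metrics equal brute-force oracles on random small graphs", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    adj <- random_adj(n, p = runif(1, 0.2, 0.7))
    g <- binary_graph(adj)
    expect_equal(unname(shortest_path_lengths(g)), oracle_distances(adj))
    expect_equal(global_efficiency(g), oracle_global_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(g), oracle_local_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(g)$mean,
                 oracle_clustering(adj)$mean, tolerance = 1e-12)
    i <- sample(n, 1)
    expect_equal(nodal_efficiency(g, i), oracle_nodal_efficiency(adj, i),
                 tolerance = 1e-12)
    if (any(is.finite(oracle_distances(adj)[upper.tri(adj)]))) {
      expect_equal(characteristic_path_length(g), oracle_path_length(adj),
                   tolerance = 1e-12)
    }
  }
})

test_that("relabeling leaves all metrics invariant", {
  set.seed(8)
  adj <- random_adj(9, 0.4)
  g <- binary_graph(adj)
  perm <- sample(9)
  g2 <- binary_graph(adj[perm, perm])
  expect_equal(global_efficiency(g), global_efficiency(g2))
  expect_equal(local_efficiency(g), local_efficiency(g2))
  expect_equal(clustering_coefficient(g)$mean, clustering_coefficient(g2)$mean)
  expect_equal(characteristic_path_length(g), characteristic_path_length(g2))
})

test_that("random references preserve degrees and are seed-reproducible", {
  ws <- make_graph_fixture("watts_strogatz", 40, list(k = 4, p = 0.1), seed = 2)
  refs <- random_references(ws, n_refs = 10, seed = 5)
  expect_length(refs, 10)
  deg <- rowSums(ws$adj)
  for (r in refs) expect_equal(rowSums(r$adj), deg)
  refs2 <- random_references(ws, n_refs = 10, seed = 5)
  expect_identical(lapply(refs, `[[`, "adj"), lapply(refs2, `[[`, "adj"))
  # star admits no degree-preserving swap: falls back with a warning
  star <- make_graph_fixture("star", 6)
  expect_warning(random_references(star, n_refs = 3, seed = 1),
                 "falling back")
})

test_that("small-world sigma separates lattice-like from random graphs", {
  ws <- make_graph_fixture("watts_strogatz", 100, list(k = 4, p = 0.1),
                           seed = 3)
  sig_ws <- small_world_sigma(ws, n_refs = 30, seed = 7)
  expect_gt(sig_ws, 1)
  # degree-matched random graphs: sigma ~ 1 on average, and below WS
  sig_er <- vapply(1:10, function(s) {
    er <- make_graph_fixture("erdos_renyi", 100,
                             list(m = graph_edge_count(ws)), seed = s)
    small_world_sigma(er, n_refs = 20, seed = s + 50)
  }, numeric(1))
  expect_gt(mean(sig_er), 0.8)
  expect_lt(mean(sig_er), 1.2)
  expect_gt(sig_ws, max(sig_er) * 0.9)
  # regular ring lattice: strong clustering AND long paths vs references
  ring <- make_graph_fixture("ring_lattice", 100, list(k = 4))
  refs <- random_references(ring, n_refs = 20, seed = 9)
  C <- clustering_coefficient(ring)$mean
  expect_equal(C, 0.5)  # closed form for k = 4 ring lattice
  Cr <- mean(vapply(refs, function(r) clustering_coefficient(r)$mean,
                    numeric(1)))
  Lr <- mean(vapply(refs, characteristic_path_length, numeric(1)))
  expect_gt(C / Cr, 3)
  expect_gt(characteristic_path_length(ring) / Lr, 2)
})

test_that("sparsity sweep is monotone in E_glob and matches pointwise calls", {
  set.seed(4)
  w <- matrix(runif(19 * 19), 19, 19)
  w <- (w + t(w)) / 2; diag(w) <- 0
  rownames(w) <- colnames(w) <- MONTAGE_19
  grid <- seq(0.1, 0.3, by = 0.05)
  sw <- sparsity_sweep(w, grid)
  expect_true(all(diff(sw$e_glob) >= 0))
  for (i in seq_along(grid)) {
    g <- binarize_top_n(w, grid[i])
    expect_equal(sw$e_glob[i], global_efficiency(g))
    expect_equal(sw$e_loc[i], local_efficiency(g))
  }
  full <- graph_metrics(w, 1.0)
  expect_equal(full$e_glob, 1)
  expect_equal(full$e_loc, 1)
  expect_equal(full$clustering, 1)
  expect_equal(full$path_length, 1)
  expect_error(sparsity_sweep(w, c(0.3, 0.2)), "increasing")
})

test_that("graph fixtures have their defining properties", {
  expect_identical(graph_edge_count(make_graph_fixture("complete", 19)), 171L)
  p4 <- make_graph_fixture("path", 4)
  expect_identical(graph_edge_count(p4), 3L)
  expect_equal(unname(sort(rowSums(p4$adj))), c(1, 1, 2, 2))
  ws1 <- make_graph_fixture("watts_strogatz", 100, list(k = 4, p = 0.1), seed = 6)
  ws2 <- make_graph_fixture("watts_strogatz", 100, list(k = 4, p = 0.1), seed = 6)
  expect_identical(ws1$adj, ws2$adj)
  expect_error(make_graph_fixture("tree", 10), "unknown fixture")
})

test_that("edge-list round trip preserves graphs", {
  set.seed(10)
  g <- binary_graph(random_adj(8, 0.3))
  path <- tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_identical(g2$adj, g$adj)
})
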