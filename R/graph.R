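# Binary graph metrics on thresholded connectivity matrices: efficiency
# (global / local / nodal), clustering, characteristic path length, and the
# small-world coefficient sigma against degree-preserving random references.
# Metrics are computed directly on the adjacency matrix with an internal BFS;
# igraph is used only to generate and rewire graphs.

#' Construct a binary graph
#'
#' Undirected, unweighted, no self-loops, stored as a logical adjacency
#' matrix.
#'
#' @param adjacency Square matrix (logical or 0/1); symmetrised by `|`.
#' @param labels Node labels (default rownames or `v1..vn`).
#' @return Object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, labels = NULL) {
  adjacency <- as.matrix(adjacency) != 0
  n <- nrow(adjacency)
  stopifnot(n == ncol(adjacency))
  adjacency <- adjacency | t(adjacency)
  diag(adjacency) <- FALSE
  if (is.null(labels)) {
    labels <- rownames(adjacency)
    if (is.null(labels)) labels <- paste0("v", seq_len(n))
  }
  dimnames(adjacency) <- list(labels, labels)
  structure(list(adj = adjacency, labels = labels), class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges\n",
              length(x$labels), graph_edge_count(x)))
  invisible(x)
}

#' Number of edges in a binary graph
#' @param g A [binary_graph()].
#' @return Integer edge count.
#' @export
graph_edge_count <- function(g) sum(g$adj[upper.tri(g$adj)])

#' Edge list of a binary graph
#' @param g A [binary_graph()].
#' @return Two-column matrix of node labels, one row per edge (i < j).
#' @export
graph_edges <- function(g) {
  idx <- which(g$adj & upper.tri(g$adj), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cbind(from = g$labels[idx[, 1]], to = g$labels[idx[, 2]])
}

#' Threshold a connectivity matrix to its top-N strongest edges
#'
#' Binarisation at a sparsity threshold `S`: the `N = round(S * n(n-1)/2)`
#' largest off-diagonal weights become edges. Ties at the N-th largest weight
#' are broken deterministically by lexicographic (row, column) order of the
#' upper triangle.
#'
#' @param cm A [connectivity_matrix()] or a plain symmetric numeric matrix.
#' @param sparsity Fraction of possible edges to retain, in `(0, 1]`.
#' @return A [binary_graph()] with exactly `N` edges.
#' @export
binarize_top_n <- function(cm, sparsity) {
  if (inherits(cm, "connectivity_matrix")) {
    w <- cm$values; labels <- cm$channels
  } else {
    w <- as.matrix(cm); labels <- rownames(w)
  }
  if (!(is.numeric(sparsity) && length(sparsity) == 1L &&
        sparsity > 0 && sparsity <= 1)) {
    stop("sparsity must lie in (0, 1]")
  }
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  n_possible <- nrow(ut)
  n_edges <- round(sparsity * n_possible)
  vals <- w[ut]
  # stable order: decreasing weight, ties by (row, col)
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(n_edges)]
  adj <- matrix(FALSE, n, n)
  adj[ut[keep, , drop = FALSE]] <- TRUE
  binary_graph(adj, labels = labels)
}

#' All-pairs shortest path lengths (hop counts)
#'
#' Breadth-first search from every node; `Inf` for disconnected pairs and 0
#' on the diagonal.
#'
#' @param g A [binary_graph()].
#' @return Symmetric numeric matrix of distances.
#' @export
shortest_path_lengths <- function(g) {
  adj <- g$adj
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- lev
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Global efficiency
#'
#' Mean inverse shortest path length over ordered node pairs,
#' `E_glob = 1/(n(n-1)) * sum_{i != j} 1/d(i,j)`; disconnected pairs
#' contribute 0. Lies in `[0, 1]`; 1 for the complete graph, 0 for the empty
#' graph. Graphs with fewer than 2 nodes return 0.
#'
#' @param g A [binary_graph()].
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  n <- length(g$labels)
  if (n < 2) return(0)
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean, over all nodes, of the global efficiency of the subgraph induced by
#' each node's neighbours (the node itself excluded); nodes with fewer than
#' two neighbours contribute 0.
#'
#' @param g A [binary_graph()].
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  n <- length(g$labels)
  if (n < 1) return(0)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(g$adj[i, ])
    if (length(nb) < 2) return(0)
    sub <- binary_graph(g$adj[nb, nb, drop = FALSE])
    global_efficiency(sub)
  }, numeric(1))
  mean(vals)
}

#' Nodal efficiency
#'
#' Per-node mean inverse distance to every other node,
#' `E_nodal(i) = 1/(n-1) * sum_{j != i} 1/d(i,j)`; an isolated node scores 0.
#'
#' @param g A [binary_graph()].
#' @param node Node label or index, or `NULL` for all nodes.
#' @return Scalar, or named vector over all nodes when `node` is `NULL`.
#' @export
nodal_efficiency <- function(g, node = NULL) {
  n <- length(g$labels)
  if (n < 2) stop("need >= 2 nodes")
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  all_vals <- stats::setNames(rowSums(inv) / (n - 1), g$labels)
  if (is.null(node)) return(all_vals)
  if (is.character(node)) node <- match(node, g$labels)
  unname(all_vals[node])
}

#' Clustering coefficient
#'
#' Per-node `C_i = 2 e_i / (k_i (k_i - 1))` where `e_i` counts edges among
#' the neighbours of node i; nodes of degree < 2 get `C_i = 0`. The network
#' value is the mean of `C_i` over all nodes.
#'
#' @param g A [binary_graph()].
#' @return List with `per_node` (named vector) and `mean`.
#' @export
clustering_coefficient <- function(g) {
  n <- length(g$labels)
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(g$adj[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    e_i <- sum(g$adj[nb, nb]) / 2
    2 * e_i / (k * (k - 1))
  }, numeric(1))
  list(per_node = stats::setNames(ci, g$labels), mean = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest path length over ordered node pairs. For disconnected
#' graphs the default averages over connected pairs only
#' (`disconnected = "drop"`); `disconnected = "inf"` returns `Inf` whenever
#' any pair is unreachable. A graph with no connected pair returns `NaN`.
#'
#' @param g A [binary_graph()].
#' @param disconnected `"drop"` (default) or `"inf"`.
#' @return Scalar (possibly `Inf` or `NaN`).
#' @export
characteristic_path_length <- function(g, disconnected = c("drop", "inf")) {
  disconnected <- match.arg(disconnected)
  n <- length(g$labels)
  if (n < 2) stop("need >= 2 nodes")
  d <- shortest_path_lengths(g)
  off <- d[row(d) != col(d)]
  if (disconnected == "inf") return(mean(off))
  fin <- off[is.finite(off)]
  if (!length(fin)) return(NaN)
  mean(fin)
}

#' Degree-preserving random reference graphs
#'
#' Rewires the input by double edge swaps (degree sequence preserved),
#' producing `n_refs` independent references; reproducible by seed. If the
#' graph admits no swap (e.g. a star), edge-count-matched Erdos-Renyi
#' references are returned with a warning.
#'
#' @param g A [binary_graph()] with >= 2 edges.
#' @param n_refs Number of references (default 100).
#' @param seed Integer seed.
#' @param n_swaps Swap attempts per reference; default `10 * n_edges`.
#' @return List of `binary_graph`.
#' @export
random_references <- function(g, n_refs = 100L, seed = 1L, n_swaps = NULL) {
  m <- graph_edge_count(g)
  if (m < 2) stop("need >= 2 edges to rewire")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  ig <- igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
  can_swap <- .has_degree_preserving_swap(g)
  out <- vector("list", n_refs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  for (r in seq_len(n_refs)) {
    if (can_swap) {
      rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = n_swaps))
    } else {
      if (r == 1L) warning("degree-preserving rewiring impossible; ",
                           "falling back to edge-count-matched random graphs")
      rg <- igraph::sample_gnm(length(g$labels), m)
    }
    out[[r]] <- binary_graph(
      as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE)) > 0,
      labels = g$labels)
  }
  out
}

# a double edge swap exists iff two independent edges (no shared endpoint)
# exist whose swap introduces a new edge; conservative quick check
.has_degree_preserving_swap <- function(g) {
  e <- which(g$adj & upper.tri(g$adj), arr.ind = TRUE)
  m <- nrow(e)
  if (m < 2) return(FALSE)
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      v <- c(e[a, ], e[b, ])
      if (length(unique(v)) < 4) next
      i <- e[a, 1]; j <- e[a, 2]; k <- e[b, 1]; l <- e[b, 2]
      if ((!g$adj[i, l] && !g$adj[k, j]) || (!g$adj[i, k] && !g$adj[j, l])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Small-world coefficient sigma
#'
#' `sigma = (C / C_r) / (L / L_r)` where `C`, `L` are the mean clustering
#' coefficient and characteristic path length of the graph and `C_r`, `L_r`
#' the ensemble means over degree-preserving random references. `sigma > 1`
#' is the conventional small-world classification. Returns `NaN` when the
#' reference clustering or path length is degenerate.
#'
#' @param g A [binary_graph()].
#' @param n_refs Reference ensemble size (default 100).
#' @param seed Integer seed for the rewiring.
#' @param refs Optional pre-built reference list (overrides `n_refs`/`seed`).
#' @return Scalar sigma.
#' @export
small_world_sigma <- function(g, n_refs = 100L, seed = 1L, refs = NULL) {
  C <- clustering_coefficient(g)$mean
  L <- characteristic_path_length(g)
  if (!is.finite(L)) return(NaN)
  if (is.null(refs)) refs <- random_references(g, n_refs, seed)
  Cr <- mean(vapply(refs, function(r) clustering_coefficient(r)$mean,
                    numeric(1)))
  Lr <- mean(vapply(refs, characteristic_path_length, numeric(1)))
  if (!is.finite(Lr) || Cr == 0 || Lr == 0) return(NaN)
  (C / Cr) / (L / Lr)
}

#' All graph metrics at one sparsity threshold
#'
#' @param cm A [connectivity_matrix()] or weight matrix.
#' @param sparsity Sparsity threshold in `(0, 1]`.
#' @param n_refs Random references for sigma; `0` skips sigma.
#' @param seed Seed for the references.
#' @return One-row data frame: sparsity, e_glob, e_loc, clustering,
#'   path_length, sigma, plus attribute `nodal` (named vector).
#' @export
graph_metrics <- function(cm, sparsity, n_refs = 0L, seed = 1L) {
  g <- binarize_top_n(cm, sparsity)
  sig <- if (n_refs > 0) small_world_sigma(g, n_refs, seed) else NA_real_
  out <- data.frame(
    sparsity = sparsity,
    e_glob = global_efficiency(g),
    e_loc = local_efficiency(g),
    clustering = clustering_coefficient(g)$mean,
    path_length = characteristic_path_length(g),
    sigma = sig)
  attr(out, "nodal") <- nodal_efficiency(g)
  out
}

#' Sparsity threshold sweep
#'
#' Computes graph metrics over a grid of sparsity thresholds (default
#' 10-70 percent in 1 percent steps for efficiency metrics; use
#' `seq(0.70, 0.85, 0.01)` for the small-world analysis).
#'
#' @param cm A [connectivity_matrix()] or weight matrix.
#' @param grid Increasing vector of sparsity fractions in `(0, 1]`.
#' @param n_refs Random references per grid point for sigma (0 = skip).
#' @param seed Base seed; each grid point uses `seed + point index`.
#' @param nodal Include per-node efficiencies (long format) as attribute.
#' @return Data frame with one row per grid point (class `sweep_result`);
#'   attribute `nodal` holds a long data frame (sparsity, channel, value).
#' @export
sparsity_sweep <- function(cm, grid = seq(0.10, 0.70, by = 0.01),
                           n_refs = 0L, seed = 1L, nodal = TRUE) {
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1)) {
    stop("grid must be strictly increasing within (0, 1]")
  }
  rows <- vector("list", length(grid))
  nodal_rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    gm <- graph_metrics(cm, grid[i], n_refs = n_refs, seed = seed + i)
    rows[[i]] <- gm
    if (nodal) {
      nv <- attr(gm, "nodal")
      nodal_rows[[i]] <- data.frame(sparsity = grid[i], channel = names(nv),
                                    value = unname(nv),
                                    stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "nodal") <- if (nodal) do.call(rbind, nodal_rows) else NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}
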