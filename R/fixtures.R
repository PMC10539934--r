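#' Canonical graph fixtures
#'
#' Deterministic or seed-reproducible graphs for testing the graph metrics:
#' `complete`, `star` (node 1 is the hub), `path`, `ring_lattice` (each node
#' joined to its `k/2` nearest neighbours on each side), `watts_strogatz`
#' (ring lattice with rewiring probability `p`) and `erdos_renyi`
#' (`G(n, m)` with `m` edges, or `G(n, p)` if `p` is given instead).
#'
#' @param kind Fixture name.
#' @param n_nodes Number of nodes (>= 2).
#' @param params Named list of parameters: `k` (even neighbour count) for
#'   `ring_lattice`/`watts_strogatz`; `p` for `watts_strogatz`/`erdos_renyi`;
#'   `m` (edge count) for `erdos_renyi`.
#' @param seed Integer seed for the stochastic kinds.
#' @return A [binary_graph()].
#' @export
make_graph_fixture <- function(kind, n_nodes, params = list(), seed = 1L) {
  kinds <- c("complete", "star", "path", "ring_lattice", "watts_strogatz",
             "erdos_renyi")
  if (!kind %in% kinds) {
    stop("unknown fixture kind '", kind, "'; expected one of ",
         paste(kinds, collapse = ", "))
  }
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  n <- as.integer(n_nodes)
  adj <- matrix(FALSE, n, n)
  if (kind == "complete") {
    adj[] <- TRUE
  } else if (kind == "star") {
    adj[1, 2:n] <- TRUE
  } else if (kind == "path") {
    adj[cbind(1:(n - 1), 2:n)] <- TRUE
  } else if (kind == "ring_lattice") {
    k <- params$k %||% 4L
    if (k %% 2 != 0 || k >= n) stop("ring lattice needs even k < n")
    for (d in seq_len(k / 2)) {
      j <- ((1:n - 1 + d) %% n) + 1
      adj[cbind(1:n, j)] <- TRUE
    }
  } else {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    if (kind == "watts_strogatz") {
      k <- params$k %||% 4L
      p <- params$p %||% 0.1
      if (k %% 2 != 0) stop("watts_strogatz needs even k")
      ig <- igraph::sample_smallworld(1, n, k / 2, p)
    } else {
      if (!is.null(params$m)) {
        ig <- igraph::sample_gnm(n, params$m)
      } else {
        ig <- igraph::sample_gnp(n, params$p %||% 0.1)
      }
    }
    return(binary_graph(
      as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE)) > 0))
  }
  binary_graph(adj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a binary graph as an edge-list text file
#'
#' Tab-separated, two columns (`from`, `to`), one row per undirected edge.
#' Isolated nodes are recorded on a leading comment line so the graph can be
#' reconstructed exactly.
#'
#' @param g A [binary_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", paste(g$labels, collapse = "\t")), con)
  e <- graph_edges(g)
  if (nrow(e)) {
    utils::write.table(e, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a binary graph from an edge-list text file
#'
#' @param path File written by [write_edge_list()].
#' @return A [binary_graph()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  if (!startsWith(header, "# nodes: ")) stop("missing node header line")
  labels <- strsplit(sub("^# nodes: ", "", header), "\t")[[1]]
  n <- length(labels)
  adj <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  body <- lines[-1]
  body <- body[nzchar(body)]
  for (ln in body) {
    parts <- strsplit(ln, "\t")[[1]]
    i <- match(parts[1], labels)
    j <- match(parts[2], labels)
    if (is.na(i) || is.na(j)) stop("edge references unknown node: ", ln)
    adj[i, j] <- TRUE
  }
  binary_graph(adj, labels = labels)
}
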