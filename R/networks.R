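# Social networks constraining the role-model pool.
#
# A `culture_graph` is an undirected simple graph over the N population
# slots (node i is individual i, in every generation). It stores the edge
# list plus a flattened adjacency (all neighbour lists concatenated, with
# per-node offsets) so that one generation of network-constrained copying is
# a single vectorised lookup.

#' Create a graph over population slots
#'
#' @param edges Two-column integer matrix of undirected edges (1-based node
#'   indices). Self-loops and duplicate edges are rejected.
#' @param n Number of nodes; node `i` maps to individual `i` of a
#'   [culture_pop()] of the same size.
#' @param params Optional named list describing how the graph was generated.
#' @return An object of class `culture_graph`.
#' @examples
#' star <- culture_graph(cbind(1, 2:5), n = 5)
#' graph_degrees(star)
#' @export
culture_graph <- function(edges, n, params = list()) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1) || any(edges > n)) stop("edge endpoints must be in 1..n")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  ends <- c(edges[, 1], edges[, 2])
  nbrs <- c(edges[, 2], edges[, 1])
  deg <- tabulate(ends, n)
  ord <- order(ends)
  structure(list(n = as.integer(n), edges = edges, deg = deg,
                 offsets = c(0L, cumsum(deg))[seq_len(n)],
                 flat = nbrs[ord], params = params),
            class = "culture_graph")
}

#' @export
print.culture_graph <- function(x, ...) {
  cat(sprintf("<culture_graph> %d nodes, %d edges%s\n", x$n, nrow(x$edges),
              if (length(x$params)) {
                paste0(" (", paste(names(x$params), unlist(x$params),
                                   sep = " = ", collapse = ", "), ")")
              } else ""))
  invisible(x)
}

#' Node degrees of a graph
#' @param graph A [culture_graph()].
#' @return Integer vector of degrees, one per node.
#' @export
graph_degrees <- function(graph) {
  stopifnot(inherits(graph, "culture_graph"))
  graph$deg
}

from_igraph <- function(g, params) {
  culture_graph(igraph::as_edgelist(g, names = FALSE),
                n = igraph::vcount(g), params = params)
}

#' Random (Erdos-Renyi) graph
#'
#' Each of the `n * (n - 1) / 2` possible undirected edges is present
#' independently with probability `p` (the expected network density).
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @return A [culture_graph()].
#' @export
graph_erdos_renyi <- function(n, p) {
  check_rate(p, "p")
  from_igraph(igraph::sample_gnp(n, p), params = list(p = p))
}

#' Scale-free (Barabasi-Albert) graph with tunable attachment power
#'
#' Grows from a two-node connected seed; every arriving node attaches by two
#' edges to distinct existing nodes chosen with probability proportional to
#' `degree^power`. `power = 1` is linear preferential attachment, `power = 0`
#' uniform attachment, and large powers approach a star. The grown graph is
#' connected with exactly `2 * (n - 2) + 1` edges.
#'
#' @param n Number of nodes (`>= 3`).
#' @param power Preferential-attachment exponent (`>= 0`).
#' @return A [culture_graph()].
#' @export
graph_barabasi_albert <- function(n, power = 1) {
  if (!is.numeric(n) || n < 3) stop("`n` must be at least 3")
  if (!is.numeric(power) || length(power) != 1 || power < 0) {
    stop("`power` must be a single non-negative number")
  }
  g <- igraph::sample_pa(n, power = power, m = 2, directed = FALSE,
                         algorithm = "psumtree")
  from_igraph(g, params = list(power = power))
}

#' Small-world (Watts-Strogatz) graph
#'
#' Starts from a ring lattice where each node is connected to its `k` closest
#' neighbours on either side (`n * k` edges), then rewires each edge with
#' probability `p_rewire` by replacing its clockwise endpoint with a uniform
#' target, avoiding self-loops and duplicates, so the edge count is preserved
#' exactly.
#'
#' @param n Number of nodes.
#' @param k Neighbours on each side in the initial lattice, `1 <= k < n / 2`.
#' @param p_rewire Rewiring probability in `[0, 1]`.
#' @return A [culture_graph()].
#' @export
graph_watts_strogatz <- function(n, k, p_rewire) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k >= n / 2) {
    stop("`k` must satisfy 1 <= k < n / 2")
  }
  check_rate(p_rewire, "p_rewire")
  k <- as.integer(k)
  u <- rep(seq_len(n), k)
  v <- ((u - 1 + rep(seq_len(k), each = n)) %% n) + 1
  edges <- cbind(u, v)
  if (p_rewire > 0) {
    nbr <- lapply(seq_len(n), function(i) integer(0))
    for (i in seq_len(nrow(edges))) {
      nbr[[edges[i, 1]]] <- c(nbr[[edges[i, 1]]], edges[i, 2])
      nbr[[edges[i, 2]]] <- c(nbr[[edges[i, 2]]], edges[i, 1])
    }
    rewire <- which(stats::runif(nrow(edges)) < p_rewire)
    for (i in rewire) {
      a <- edges[i, 1]; b <- edges[i, 2]
      if (length(nbr[[a]]) >= n - 1) next  # a already connected to everyone
      repeat {
        cand <- sample.int(n, 1)
        if (cand != a && !(cand %in% nbr[[a]])) break
      }
      nbr[[a]] <- c(setdiff(nbr[[a]], b), cand)
      nbr[[b]] <- setdiff(nbr[[b]], a)
      nbr[[cand]] <- c(nbr[[cand]], a)
      edges[i, 2] <- cand
    }
  }
  culture_graph(edges, n, params = list(k = k, p_rewire = p_rewire))
}

#' One generation of network-constrained transmission
#'
#' The learner occupying node v innovates with probability `mu`, otherwise
#' copies a uniformly random direct neighbour of v in the parental
#' generation (never itself). Node positions are heritable slots: the learner
#' at node v becomes the next generation's parent at node v. Isolated nodes
#' have no role models and retain their current variant unless they innovate.
#'
#' @param pop A [culture_pop()] whose size equals the node count.
#' @param graph A [culture_graph()], fixed across the generations of a run.
#' @param mu Innovation probability in `[0, 1]`.
#' @return As [step_unbiased()]; influence counts are indexed by node.
#' @export
step_network <- function(pop, graph, mu) {
  check_pop(pop); check_mu(mu)
  stopifnot(inherits(graph, "culture_graph"))
  if (census_size(pop) != graph$n) {
    stop("graph node count must equal the population census size")
  }
  package_step(pop, kernel_network(pop$variants, pop$next_label, graph, mu))
}

#' Read or write a graph as a plain edge list
#'
#' The on-disk format is two whitespace-separated columns of 0-based node
#' indices, one undirected edge per line.
#'
#' @param path File path.
#' @param n Node count; defaults to the largest index seen plus one.
#' @param graph A [culture_graph()].
#' @return `read_edgelist()` returns a [culture_graph()]; `write_edgelist()`
#'   returns `graph` invisibly.
#' @export
read_edgelist <- function(path, n = NULL) {
  m <- as.matrix(utils::read.table(path, col.names = c("u", "v")))
  if (is.null(n)) n <- max(m) + 1
  culture_graph(m + 1L, n = n)
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "culture_graph"))
  utils::write.table(graph$edges - 1L, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(graph)
}
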