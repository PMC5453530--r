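## Structural characterization of an inferred network: connected
## components, neighborhood function, clustering, path length, random-graph
## null comparison, modularity scoring of a supplied partition.

#' Connected-component census
#'
#' @param g an undirected `igraph` graph.
#' @return a `component_summary`: list with a `data.frame` `components`
#'   (`nodes`, `edges`, sorted by size descending), `n_nodes`, `n_edges`,
#'   giant node/edge fractions and singleton count/fraction (exact), and
#'   the same fractions as percentages rounded to 2 decimals
#'   (`giant_node_pct`, `giant_edge_pct`, `singleton_pct`).
#' @export
component_summary <- function(g) {
  stopifnot(inherits(g, "igraph"))
  comp <- igraph::components(g)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  edge_comp <- if (m) comp$membership[el[, 1L]] else integer()
  edges_per <- tabulate(edge_comp, nbins = comp$no)
  tab <- data.frame(nodes = as.integer(comp$csize),
                    edges = as.integer(edges_per))
  tab <- tab[order(-tab$nodes, -tab$edges), , drop = FALSE]
  rownames(tab) <- NULL
  giant_nodes <- if (comp$no) tab$nodes[1L] else 0L
  giant_edges <- if (comp$no) tab$edges[1L] else 0L
  singletons <- sum(tab$nodes == 1L)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    components = tab,
    n_components = comp$no,
    n_nodes = n, n_edges = m,
    giant_nodes = giant_nodes, giant_edges = giant_edges,
    giant_node_fraction = pct(giant_nodes, n) / 100,
    giant_edge_fraction = pct(giant_edges, m) / 100,
    singleton_count = singletons,
    singleton_fraction = pct(singletons, n) / 100,
    giant_node_pct = round(pct(giant_nodes, n), 2),
    giant_edge_pct = round(pct(giant_edges, m), 2),
    singleton_pct = round(pct(singletons, n), 2)
  ), class = "component_summary")
}

#' @export
print.component_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<component_summary> %d components over %d nodes / %d edges\n",
           "  giant: %d nodes (%.2f%%), %d edges (%.2f%%); ",
           "%d singletons (%.2f%%)\n"),
    x$n_components, x$n_nodes, x$n_edges,
    x$giant_nodes, x$giant_node_pct, x$giant_edges, x$giant_edge_pct,
    x$singleton_count, x$singleton_pct))
  invisible(x)
}

#' Neighborhood function NF(l)
#'
#' `NF(l)` counts ordered node pairs `(u, v)` with `d(u, v) <= l`,
#' self-pairs included, so `NF(0) = N` and, for a connected graph of
#' diameter `D`, `NF(D) = N^2`. `p(l) = NF(l) / N^2` is the fraction of
#' pairs within `l` hops. Computed by exact BFS from every node.
#'
#' @param g an undirected `igraph` graph.
#' @param l_max largest hop count to evaluate; defaults to the largest
#'   finite eccentricity (so NF saturates by `l_max`).
#' @return a `data.frame` with columns `l`, `NF`, `p`.
#' @export
neighborhood_function <- function(g, l_max = NULL) {
  stopifnot(inherits(g, "igraph"))
  n <- igraph::vcount(g)
  if (n == 0L) svcn_abort("parameter_error", "graph has no nodes")
  d <- igraph::distances(g)
  finite <- d[is.finite(d)]
  if (is.null(l_max)) l_max <- max(finite, 0)
  if (l_max < 0) svcn_abort("parameter_error", "l_max must be >= 0")
  l <- 0:l_max
  nf <- vapply(l, function(h) sum(finite <= h), numeric(1))
  data.frame(l = l, NF = nf, p = nf / n^2)
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient; nodes of degree
#' below 2 contribute 0 (they close no triangles).
#'
#' @param g an undirected `igraph` graph with at least one node.
#' @return the average clustering coefficient.
#' @export
average_clustering <- function(g) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) == 0L) {
    svcn_abort("parameter_error", "clustering undefined on an empty graph")
  }
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

#' Average shortest-path length
#'
#' @param g an undirected `igraph` graph.
#' @param scope `"giant"` (default): mean over unordered pairs of the
#'   largest connected component; `"all_connected_pairs"`: mean over every
#'   connected unordered pair in the graph.
#' @return mean shortest-path distance (exact BFS).
#' @export
average_path_length <- function(g, scope = c("giant",
                                             "all_connected_pairs")) {
  scope <- match.arg(scope)
  stopifnot(inherits(g, "igraph"))
  if (scope == "giant") {
    comp <- igraph::components(g)
    if (comp$no == 0L) svcn_abort("parameter_error", "graph has no nodes")
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
    if (igraph::vcount(g) < 2L) {
      svcn_abort("parameter_error",
                 "giant component has < 2 nodes; path length undefined")
    }
    return(igraph::mean_distance(g))
  }
  d <- igraph::distances(g)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    svcn_abort("parameter_error", "no connected pairs in scope")
  }
  mean(vals)
}

#' Erdos-Renyi G(n, m) null metrics
#'
#' Mean clustering coefficient and giant-component average path length over
#' seeded draws of the uniform random graph with the same number of nodes
#' and edges, the standard null against which small-world structure is
#' judged.
#'
#' @param n,m nodes and edges (`0 <= m <= choose(n, 2)`).
#' @param seed integer seed.
#' @param n_rep number of draws to average over (default 10).
#' @return list with `clustering`, `path_length` (means across draws),
#'   their per-draw values `clustering_draws`, `path_length_draws`, and
#'   `n_rep`.
#' @export
er_null_metrics <- function(n, m, seed = 1L, n_rep = 10L) {
  if (!is_count(n) || n < 1 || !is_count(m) || m < 0 || m > choose(n, 2)) {
    svcn_abort("parameter_error",
               "need integer n >= 1 and 0 <= m <= choose(n, 2)")
  }
  draws <- withr_seed(seed, {
    lapply(seq_len(n_rep), function(r) {
      g <- igraph::sample_gnm(n, m)
      pl <- if (m > 0 && max(igraph::components(g)$csize) >= 2) {
        average_path_length(g, scope = "giant")
      } else NA_real_
      list(cc = average_clustering(g), pl = pl)
    })
  })
  cc <- vapply(draws, `[[`, numeric(1), "cc")
  pl <- vapply(draws, `[[`, numeric(1), "pl")
  list(clustering = mean(cc),
       path_length = mean(pl, na.rm = TRUE),
       clustering_draws = cc, path_length_draws = pl,
       n_rep = as.integer(n_rep))
}

#' Newman modularity of a supplied partition
#'
#' `Q = sum_c (e_cc - a_c^2)` where `e` is the community mixing matrix of
#' edge fractions and `a_c` its row sums. Community detection itself is out
#' of scope; this scores a partition produced elsewhere.
#'
#' @param g an undirected `igraph` graph with at least one edge.
#' @param partition named vector (names = node names) or unnamed vector in
#'   vertex order, giving each node's community label.
#' @return modularity `Q`.
#' @export
modularity_score <- function(g, partition) {
  stopifnot(inherits(g, "igraph"))
  m <- igraph::ecount(g)
  if (m == 0L) svcn_abort("parameter_error", "modularity undefined: no edges")
  vn <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (!is.null(names(partition))) {
    miss <- setdiff(vn, names(partition))
    if (length(miss)) {
      svcn_abort("parameter_error",
                 sprintf("partition misses node(s): %s",
                         paste(head(miss, 3), collapse = ", ")))
    }
    memb <- partition[vn]
  } else {
    if (length(partition) != length(vn)) {
      svcn_abort("parameter_error", "partition length != node count")
    }
    memb <- partition
  }
  memb <- as.character(memb)
  labs <- unique(memb)
  el <- igraph::as_edgelist(g, names = FALSE)
  c1 <- match(memb[el[, 1L]], labs)
  c2 <- match(memb[el[, 2L]], labs)
  k <- length(labs)
  e <- matrix(0, k, k)
  for (idx in seq_len(nrow(el))) {
    # each undirected edge contributes 1/(2m) to e[c1,c2] and e[c2,c1]
    e[c1[idx], c2[idx]] <- e[c1[idx], c2[idx]] + 1
    e[c2[idx], c1[idx]] <- e[c2[idx], c1[idx]] + 1
  }
  e <- e / (2 * m)
  a <- rowSums(e)
  sum(diag(e)) - sum(a^2)
}
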