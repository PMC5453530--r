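## Concordance of an inferred network with a reference tie network:
## dyad-level confusion rates and QAP matrix correlation.

#' Dyad confusion rates between inferred and reference networks
#'
#' Every unordered pair of the shared node set is classified: a dyad is a
#' true positive when it is an edge in both networks, a true negative when
#' it is an edge in neither, and so on. TPR = TP / (TP + FN),
#' TNR = TN / (TN + FP).
#'
#' @param inferred,reference undirected `igraph` graphs with named nodes.
#' @param node_policy `"intersection"` (default) or `"union"` of the two
#'   node sets; with `"union"`, absent nodes contribute non-edges.
#' @return a `dyad_comparison`: list with `nodes`, counts `TP`, `FP`,
#'   `TN`, `FN`, rates `TPR`, `TNR`, `FPR`, `FNR`, and `n_dyads`.
#' @export
confusion_rates <- function(inferred, reference,
                            node_policy = c("intersection", "union")) {
  node_policy <- match.arg(node_policy)
  ni <- igraph::V(inferred)$name
  nr <- igraph::V(reference)$name
  nodes <- switch(node_policy,
                  intersection = intersect(ni, nr),
                  union = union(ni, nr))
  if (!length(nodes)) {
    svcn_abort("parameter_error", "shared node set is empty")
  }
  edge_keys <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    keep <- el[, 1L] %in% nodes & el[, 2L] %in% nodes & el[, 1L] != el[, 2L]
    el <- el[keep, , drop = FALSE]
    op <- order_pair(el[, 1L], el[, 2L])
    unique(paste(op$a, op$b, sep = "\r"))
  }
  ei <- edge_keys(inferred)
  er <- edge_keys(reference)
  n <- length(nodes)
  n_dyads <- choose(n, 2)
  tp <- length(intersect(ei, er))
  fp <- length(setdiff(ei, er))
  fn <- length(setdiff(er, ei))
  tn <- n_dyads - tp - fp - fn
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(nodes = nodes, n_dyads = n_dyads,
                 TP = tp, FP = fp, TN = tn, FN = fn,
                 TPR = rate(tp, tp + fn), TNR = rate(tn, tn + fp),
                 FPR = rate(fp, fp + tn), FNR = rate(fn, fn + tp)),
            class = "dyad_comparison")
}

#' @export
print.dyad_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<dyad_comparison> %d nodes, %d dyads\n",
           "  TP=%d FP=%d TN=%d FN=%d | TPR=%.3f TNR=%.3f\n"),
    length(x$nodes), x$n_dyads, x$TP, x$FP, x$TN, x$FN, x$TPR, x$TNR))
  invisible(x)
}

#' QAP correlation between two networks
#'
#' Pearson correlation of the off-diagonal adjacency entries of two graphs
#' on the same node set, with significance from the quadratic assignment
#' procedure: the rows and columns of one matrix are permuted
#' simultaneously `n_perm` times and the one-sided p-value uses the add-one
#' estimator `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`, so it is never
#' exactly zero.
#'
#' @param a,b undirected `igraph` graphs over the same named node set.
#' @param n_perm number of permutations (>= 1; default 999).
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
qap_correlation <- function(a, b, n_perm = 999L, seed = 1L) {
  if (!is_count(n_perm) || n_perm < 1) {
    svcn_abort("parameter_error", "n_perm must be a positive integer")
  }
  na <- igraph::V(a)$name
  nb <- igraph::V(b)$name
  if (!setequal(na, nb)) {
    svcn_abort("parameter_error", "graphs must share the same node set")
  }
  A <- as.matrix(igraph::as_adjacency_matrix(a))
  B <- as.matrix(igraph::as_adjacency_matrix(b))[na, na]
  n <- nrow(A)
  off <- upper.tri(A)  # symmetric matrices: upper triangle carries all info
  va <- A[off]
  vb <- B[off]
  if (var(va) == 0 || var(vb) == 0) {
    svcn_abort("undefined_coefficient",
               "QAP undefined: zero variance in an adjacency matrix")
  }
  r_obs <- cor(va, vb)
  r_perm <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      cor(va, B[p, p][off])
    }, numeric(1))
  })
  list(r = r_obs,
       p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
       n_perm = as.integer(n_perm))
}
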