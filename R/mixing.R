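## Mixing patterns: global degree assortativity, its group-pair
## ("universal") decomposition, scalar and categorical attribute
## assortativity, and the tie-formation preference index (TFPI).

# ---- grouping schemes ------------------------------------------------------

#' Partition network nodes by a categorical attribute
#'
#' @param values named vector (names = subject ids) of group labels, or an
#'   `attribute_table` together with `attribute`.
#' @param attribute attribute column name when `values` is an
#'   `attribute_table`.
#' @param labels optional explicit label ordering; defaults to sorted
#'   distinct labels.
#' @return a `grouping_scheme`: list with `attribute`, `labels`,
#'   `membership` (named character vector), `sizes` (`N_i`), `fractions`
#'   (`w_i = N_i / N`), `N`.
#' @export
grouping_scheme <- function(values, attribute = NULL, labels = NULL) {
  if (inherits(values, "attribute_table")) {
    if (is.null(attribute) || !attribute %in% names(values)) {
      svcn_abort("parameter_error",
                 "attribute must name a column of the attribute table")
    }
    membership <- setNames(as.character(values[[attribute]]),
                           values$subject_id)
  } else {
    if (is.null(names(values))) {
      svcn_abort("parameter_error", "values must be named by subject id")
    }
    membership <- setNames(as.character(values), names(values))
  }
  if (anyNA(membership)) {
    svcn_abort("parameter_error", "missing group label for some subject")
  }
  labels <- labels %||% sort(unique(unname(membership)))
  if (!all(membership %in% labels)) {
    svcn_abort("parameter_error", "membership contains label not in labels")
  }
  sizes <- vapply(labels, function(l) sum(membership == l), integer(1))
  structure(list(attribute = attribute %||% "group",
                 labels = labels,
                 membership = membership,
                 sizes = sizes,
                 fractions = sizes / length(membership),
                 N = length(membership)),
            class = "grouping_scheme")
}

## Restrict a grouping to the nodes of a graph (sizes/fractions recomputed
## over network nodes, which is the population the mixing statistics see).
restrict_grouping <- function(g, grouping) {
  vn <- igraph::V(g)$name
  miss <- setdiff(vn, names(grouping$membership))
  if (length(miss)) {
    svcn_abort("parameter_error",
               sprintf("no group for node(s): %s",
                       paste(head(miss, 3), collapse = ", ")))
  }
  grouping_scheme(grouping$membership[vn], labels = grouping$labels)
}

# ---- degree assortativity --------------------------------------------------

edge_end_excess <- function(g) {
  m <- igraph::ecount(g)
  if (m < 2L) {
    svcn_abort("parameter_error", "assortativity needs >= 2 edges")
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  list(el = el, j = deg[el[, 1L]] - 1, k = deg[el[, 2L]] - 1, m = m)
}

#' Global degree assortativity coefficient
#'
#' Pearson correlation of the (excess) degrees at the two ends of every
#' edge, computed over the `2|E|` ordered edge-end pairs. The correlation
#' is shift-invariant, so raw and excess degrees give the same value.
#'
#' @param g an undirected `igraph` graph with at least 2 edges and
#'   non-constant edge-end degrees.
#' @return the assortativity coefficient `r` in `[-1, 1]`.
#' @export
degree_assortativity_global <- function(g) {
  ee <- edge_end_excess(g)
  q <- c(ee$j, ee$k)
  if (var(q) == 0) {
    svcn_abort("undefined_coefficient",
               "degree assortativity undefined: constant edge-end degrees")
  }
  mu <- mean(q)
  s2 <- mean((q - mu)^2)  # population variance over edge ends
  sum((ee$j - mu) * (ee$k - mu)) / (ee$m * s2)
}

#' Universal (group-pair) assortativity decomposition
#'
#' Each edge contributes
#' `rho_e = (j_e - mu_q) * (k_e - mu_q) / (|E| * sigma_q^2)`
#' where `j_e`, `k_e` are the endpoint excess degrees and `mu_q`,
#' `sigma_q^2` the mean and variance over all edge ends. `r(g, h)` sums the
#' contributions of edges whose endpoint groups are `{g, h}`, so the sum
#' over unordered group pairs recovers the global coefficient exactly.
#'
#' @param g an undirected `igraph` graph.
#' @param grouping a `grouping_scheme` (or named label vector) covering all
#'   nodes.
#' @return symmetric matrix `r[g, h]`; the full unordered-pair contribution
#'   is stored at both `[g, h]` and `[h, g]`, so conservation is the sum of
#'   the upper triangle including the diagonal.
#' @export
universal_assortativity_matrix <- function(g, grouping) {
  if (!inherits(grouping, "grouping_scheme")) {
    grouping <- grouping_scheme(grouping)
  }
  grouping <- restrict_grouping(g, grouping)
  ee <- edge_end_excess(g)
  q <- c(ee$j, ee$k)
  if (var(q) == 0) {
    svcn_abort("undefined_coefficient",
               "degree assortativity undefined: constant edge-end degrees")
  }
  mu <- mean(q)
  s2 <- mean((q - mu)^2)
  rho <- (ee$j - mu) * (ee$k - mu) / (ee$m * s2)
  vn <- igraph::V(g)$name
  memb <- grouping$membership[vn]
  labs <- grouping$labels
  g1 <- match(memb[ee$el[, 1L]], labs)
  g2 <- match(memb[ee$el[, 2L]], labs)
  lo <- pmin(g1, g2)
  hi <- pmax(g1, g2)
  k <- length(labs)
  r <- matrix(0, k, k, dimnames = list(labs, labs))
  for (e in seq_along(rho)) {
    r[lo[e], hi[e]] <- r[lo[e], hi[e]] + rho[e]
  }
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  r
}

# ---- attribute assortativity -----------------------------------------------

edge_end_values <- function(g, values) {
  m <- igraph::ecount(g)
  if (m < 1L) svcn_abort("parameter_error", "graph has no edges")
  vn <- igraph::V(g)$name
  miss <- setdiff(vn, names(values))
  if (length(miss)) {
    svcn_abort("parameter_error",
               sprintf("no attribute value for node(s): %s",
                       paste(head(miss, 3), collapse = ", ")))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  list(x = values[el[, 1L]], y = values[el[, 2L]], m = m)
}

#' Scalar attribute assortativity
#'
#' Pearson correlation of a numeric node attribute across the two ends of
#' every edge (both orderings), i.e. Newman's assortativity coefficient
#' for scalar attributes.
#'
#' @param g an undirected `igraph` graph with edges.
#' @param values named numeric vector of attribute values (names = node
#'   names).
#' @return `r_x` in `[-1, 1]`.
#' @export
attribute_assortativity_scalar <- function(g, values) {
  ev <- edge_end_values(g, values)
  a <- as.numeric(c(ev$x, ev$y))
  b <- as.numeric(c(ev$y, ev$x))
  if (var(a) == 0) {
    svcn_abort("undefined_coefficient",
               "scalar assortativity undefined: constant edge-end values")
  }
  mu <- mean(a)
  s2 <- mean((a - mu)^2)
  mean((a - mu) * (b - mu)) / s2
}

#' Categorical attribute assortativity
#'
#' `r = (sum_c e_cc - sum_c a_c * b_c) / (1 - sum_c a_c * b_c)` where `e`
#' is the label mixing matrix over edge ends and `a`, `b` its marginals
#' (equal for an undirected graph).
#'
#' @param g an undirected `igraph` graph with edges.
#' @param labels named vector of categorical labels (names = node names).
#' @return `r` in `[-1, 1]`; 1 iff all edges are intra-label with at least
#'   two labels present.
#' @export
attribute_assortativity_categorical <- function(g, labels) {
  ev <- edge_end_values(g, labels)
  labs <- sort(unique(c(ev$x, ev$y)))
  if (length(labs) < 2L) {
    svcn_abort("undefined_coefficient",
               "categorical assortativity undefined with a single label")
  }
  k <- length(labs)
  e <- matrix(0, k, k, dimnames = list(labs, labs))
  i1 <- match(ev$x, labs)
  i2 <- match(ev$y, labs)
  for (idx in seq_along(i1)) {
    e[i1[idx], i2[idx]] <- e[i1[idx], i2[idx]] + 1
    e[i2[idx], i1[idx]] <- e[i2[idx], i1[idx]] + 1
  }
  e <- e / (2 * ev$m)
  ab <- sum(rowSums(e) * colSums(e))
  (sum(diag(e)) - ab) / (1 - ab)
}

# ---- tie formation preference index ----------------------------------------

#' Tie-formation preference index (TFPI) matrix
#'
#' For groups i, j: `s_ij` is the mean number of edge ends per member of
#' group i whose opposite endpoint lies in group j (both ends of an
#' intra-group edge count), so `s_i = sum_j s_ij` is the mean degree of
#' group i. `p_ij = s_ij / s_i` is the fraction of group i's ties that go
#' to group j, and the TFPI normalizes it against group size:
#' `q_ij = (p_ij - w_j) / (1 - w_j)`.
#'
#' `q_ij = 0` under proportional (size-blind) mixing, `q_ij > 0` when group
#' i over-connects to group j, with maximum 1 (all ties to j); the matrix
#' is generally asymmetric. Rows for groups with no edges are flagged
#' undefined (`NA`), never silently zero.
#'
#' @param g an undirected `igraph` graph.
#' @param grouping a `grouping_scheme` (or named label vector) covering all
#'   nodes.
#' @return a `tfpi_matrix`: list with matrices `s`, `p`, `q`, vector `w`,
#'   `s_i` (group mean degrees), and logical `defined` per row.
#' @export
tfpi_matrix <- function(g, grouping) {
  if (!inherits(grouping, "grouping_scheme")) {
    grouping <- grouping_scheme(grouping)
  }
  grouping <- restrict_grouping(g, grouping)
  labs <- grouping$labels
  k <- length(labs)
  w <- setNames(grouping$fractions, labs)
  vn <- igraph::V(g)$name
  memb <- grouping$membership[vn]
  ends <- matrix(0, k, k, dimnames = list(labs, labs))
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    i1 <- match(memb[el[, 1L]], labs)
    i2 <- match(memb[el[, 2L]], labs)
    for (idx in seq_len(nrow(el))) {
      # end in group of node1 looking at group of node2, and vice versa
      ends[i1[idx], i2[idx]] <- ends[i1[idx], i2[idx]] + 1
      ends[i2[idx], i1[idx]] <- ends[i2[idx], i1[idx]] + 1
    }
  }
  sizes <- grouping$sizes
  s <- sweep(ends, 1L, sizes, "/")
  s_i <- rowSums(s)
  defined <- s_i > 0
  p <- s
  p[defined, ] <- s[defined, , drop = FALSE] / s_i[defined]
  p[!defined, ] <- NA_real_
  q <- sweep(p, 2L, w, "-") / rep(1 - w, each = k)
  structure(list(s = s, p = p, q = q, w = w, s_i = s_i,
                 defined = defined, labels = labs),
            class = "tfpi_matrix")
}

#' @export
print.tfpi_matrix <- function(x, ...) {
  cat("<tfpi_matrix> q (rows: subject group, cols: partner group)\n")
  print(round(x$q, 4))
  if (any(!x$defined)) {
    cat("undefined rows (no edges):",
        paste(x$labels[!x$defined], collapse = ", "), "\n")
  }
  invisible(x)
}

#' All mixing statistics for one attribute
#'
#' Convenience wrapper computing the global degree assortativity, its
#' universal (group-pair) decomposition, the attribute assortativity
#' (scalar or categorical according to the attribute's type tag), and the
#' TFPI matrix.
#'
#' @param g an undirected `igraph` graph.
#' @param attrs an `attribute_table` covering all nodes.
#' @param attribute attribute column to analyse.
#' @return list with `attribute`, `type`, `degree_assortativity`,
#'   `universal_matrix`, `attribute_assortativity`, `tfpi`.
#' @export
mixing_summary <- function(g, attrs, attribute) {
  stopifnot(inherits(attrs, "attribute_table"))
  if (!attribute %in% names(attrs)) {
    svcn_abort("parameter_error",
               sprintf("attribute '%s' not in table", attribute))
  }
  type <- attribute_types(attrs)[[attribute]]
  vals <- setNames(attrs[[attribute]], attrs$subject_id)
  grouping <- grouping_scheme(setNames(as.character(vals), names(vals)),
                              attribute = attribute)
  attr_r <- if (type == "scalar") {
    attribute_assortativity_scalar(g, vals)
  } else {
    attribute_assortativity_categorical(g, setNames(as.character(vals),
                                                    names(vals)))
  }
  list(attribute = attribute,
       type = type,
       degree_assortativity = degree_assortativity_global(g),
       universal_matrix = universal_assortativity_matrix(g, grouping),
       attribute_assortativity = attr_r,
       tfpi = tfpi_matrix(g, grouping))
}
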