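## Core inference: segment the event stream, count pairwise co-occurrences,
## evaluate the Poisson null, correct for multiple testing, build the
## statistically validated co-occurrence network (SVCN).

# ---- segmentation ----------------------------------------------------------

#' Segment an event stream into (location, timeslot) bins
#'
#' Time is split into consecutive slots of length `tau` seconds starting at
#' an origin `t0`; a segment is the set of distinct subjects checked in at
#' one location during one slot. Multiple check-ins by the same subject in
#' the same segment collapse to a single occurrence. Empty segments are
#' never materialized.
#'
#' @param events an `event_stream` (see [read_events()]); must be non-empty.
#' @param tau timeslot length in seconds (> 0). Default 300 s (5 minutes).
#' @param t0_policy slot origin: `"midnight_of_first_day"` (default; slots
#'   align with the wall clock so daily activity peaks fall consistently),
#'   `"stream_min"` (first event time), or `"explicit"` (supply `t0`).
#' @param t0 explicit origin (`POSIXct` or epoch seconds) when
#'   `t0_policy = "explicit"`.
#' @return a `segmentation` object: list with
#'   \describe{
#'     \item{occ}{`data.table` of distinct (subject_id, location_id, slot,
#'       seg) occurrences; `seg` is a dense segment index `1..K`.}
#'     \item{segments}{`data.table` with one row per non-empty segment:
#'       `seg`, `location_id`, `slot`, size `L_k`.}
#'     \item{n}{named integer vector: `n_i`, segments containing subject i.}
#'     \item{K, M}{number of non-empty segments; `M = sum(L_k) = sum(n_i)`.}
#'     \item{S}{`sum(L_k * (L_k - 1))`, the segment-size factor of the
#'       expected co-occurrence count.}
#'     \item{tau, t0}{binning parameters actually used.}
#'   }
#' @export
segment_events <- function(events, tau = 300,
                           t0_policy = c("midnight_of_first_day",
                                         "stream_min", "explicit"),
                           t0 = NULL) {
  t0_policy <- match.arg(t0_policy)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    svcn_abort("parameter_error", "tau must be a positive number of seconds")
  }
  if (!inherits(events, "event_stream") || nrow(events) == 0L) {
    svcn_abort("parameter_error", "events must be a non-empty event_stream")
  }
  tsec <- as.numeric(events$timestamp)
  t0 <- switch(t0_policy,
    midnight_of_first_day = floor(tsec[1L] / 86400) * 86400,
    stream_min = min(tsec),
    explicit = {
      if (is.null(t0)) {
        svcn_abort("parameter_error", "t0_policy='explicit' requires t0")
      }
      as.numeric(t0)
    })
  occ <- data.table::data.table(
    subject_id = events$subject_id,
    location_id = events$location_id,
    slot = as.integer(floor((tsec - t0) / tau)))
  occ <- unique(occ, by = c("subject_id", "location_id", "slot"))
  segs <- occ[, list(L_k = .N), by = c("location_id", "slot")]
  data.table::setorder(segs, location_id, slot)
  segs[, seg := seq_len(.N)]
  occ <- segs[, c("location_id", "slot", "seg"), with = FALSE][
    occ, on = c("location_id", "slot")]
  n_i <- occ[, .N, by = "subject_id"]
  n <- setNames(n_i$N, n_i$subject_id)
  structure(list(
    occ = occ[, c("subject_id", "location_id", "slot", "seg"), with = FALSE],
    segments = segs[, c("seg", "location_id", "slot", "L_k"), with = FALSE],
    n = n,
    K = nrow(segs),
    M = sum(segs$L_k),
    S = sum(segs$L_k * (segs$L_k - 1)),
    tau = tau, t0 = t0
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "<segmentation> K=%d segments, M=%d occurrences, %d subjects, tau=%gs\n",
    x$K, x$M, length(x$n), x$tau))
  invisible(x)
}

# ---- co-occurrence counting ------------------------------------------------

#' Count pairwise co-occurrences
#'
#' `X_ij` is the number of segments containing both subjects i and j. Only
#' pairs with at least one shared segment are enumerated.
#'
#' @param seg a `segmentation` from [segment_events()].
#' @return `data.table` with columns `i`, `j` (with `i < j`
#'   lexicographically) and `x_obs`.
#' @export
count_cooccurrences <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  occ <- seg$occ[, c("subject_id", "seg"), with = FALSE]
  multi <- seg$segments$seg[seg$segments$L_k >= 2L]
  if (!length(multi)) {
    return(data.table::data.table(i = character(), j = character(),
                                  x_obs = integer()))
  }
  occ <- occ[occ$seg %in% multi]
  data.table::setkey(occ, seg)
  pairs <- occ[occ, on = "seg", allow.cartesian = TRUE][
    subject_id < i.subject_id]
  out <- pairs[, list(x_obs = .N),
               by = list(i = subject_id, j = i.subject_id)]
  data.table::setorder(out, i, j)
  out[]
}

# ---- null model ------------------------------------------------------------

#' Expected co-occurrence count under the random-appearance null
#'
#' Under the null that each of a subject's `n` occurrences lands in segment
#' k with probability proportional to segment size, the expected number of
#' shared segments for subjects i and j is
#' `n_i * n_j / (M * (M - 1)) * sum_k L_k * (L_k - 1)`.
#'
#' @param seg a `segmentation`.
#' @param i,j subject ids (vectorized; recycled to common length).
#' @return numeric vector of expected counts.
#' @export
expected_cooccurrence <- function(seg, i, j) {
  stopifnot(inherits(seg, "segmentation"))
  if (seg$M < 2) {
    svcn_abort("parameter_error",
               "expected co-occurrence undefined for M < 2 occurrences")
  }
  n_i <- seg$n[as.character(i)]
  n_j <- seg$n[as.character(j)]
  if (anyNA(n_i) || anyNA(n_j)) {
    svcn_abort("parameter_error", "subject not present in segmentation")
  }
  unname(n_i * n_j / (seg$M * (seg$M - 1)) * seg$S)
}

#' Upper-tail Poisson probability
#'
#' `P(X >= x_obs)` for `X ~ Poisson(mu)`, evaluated through the regularized
#' lower incomplete gamma function in log space, so that relative accuracy
#' is retained down to the ~1e-300 scale (validated-network thresholds sit
#' around 1e-10 and far below).
#'
#' @param x_obs non-negative integer count(s).
#' @param mu positive Poisson mean(s).
#' @return `P(Poisson(mu) >= x_obs)`; exactly 1 when `x_obs = 0`.
#' @export
poisson_upper_tail <- function(x_obs, mu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    svcn_abort("parameter_error", "mu must be positive and finite")
  }
  if (any(x_obs < 0) || any(x_obs != trunc(x_obs))) {
    svcn_abort("parameter_error", "x_obs must be non-negative integer(s)")
  }
  n <- max(length(x_obs), length(mu))
  x_obs <- rep_len(x_obs, n)
  mu <- rep_len(mu, n)
  p <- numeric(n)
  zero <- x_obs == 0
  p[zero] <- 1
  if (any(!zero)) {
    # P(Pois(mu) >= x) = P(Gamma(x, 1) <= mu), the regularized lower
    # incomplete gamma; exp(log p) keeps relative accuracy for tiny p.
    p[!zero] <- exp(stats::pgamma(mu[!zero], shape = x_obs[!zero],
                                  lower.tail = TRUE, log.p = TRUE))
  }
  p
}

#' Multiple-testing corrected significance threshold
#'
#' @param alpha0 base significance level (the validated-network default is
#'   0.01).
#' @param n_tests number of tests performed (`N_T >= 1`).
#' @param method only `"bonferroni"` is implemented:
#'   `p_b = alpha0 / n_tests`.
#' @return the corrected threshold `p_b`.
#' @export
corrected_threshold <- function(alpha0, n_tests, method = "bonferroni") {
  method <- match.arg(method, "bonferroni")
  if (!is.numeric(alpha0) || alpha0 <= 0 || alpha0 > 1) {
    svcn_abort("parameter_error", "alpha0 must be in (0, 1]")
  }
  if (!is_count(n_tests) || n_tests < 1) {
    svcn_abort("parameter_error", "n_tests must be a positive integer")
  }
  alpha0 / n_tests
}

# ---- network construction --------------------------------------------------

#' Build the statistically validated co-occurrence network
#'
#' Runs the full pipeline: segmentation, co-occurrence counting, Poisson
#' null evaluation per candidate pair, Bonferroni correction, and edge
#' selection (a pair becomes an edge iff its p-value is strictly below the
#' corrected threshold). All subjects observed in the stream are nodes, so
#' singletons with no validated tie are preserved.
#'
#' @param events an `event_stream`; an empty stream yields an empty network.
#' @param attributes optional `attribute_table` carried into the result for
#'   export and mixing analyses.
#' @param tau timeslot length in seconds (default 300).
#' @param alpha0 base significance level before correction (default 0.01).
#' @param n_t_policy how the number of tests `N_T` is counted:
#'   `"candidate_pairs"` (default; pairs with `X_ij >= 1` — only these are
#'   testable), `"all_pairs"` (`choose(N, 2)`), or `"explicit"` (supply
#'   `n_tests`).
#' @param n_tests explicit `N_T` when `n_t_policy = "explicit"`.
#' @param t0_policy,t0 slot origin, see [segment_events()].
#' @return an `svcn_result`: list with `nodes`, `pair_stats` (all candidate
#'   pairs with `x_obs`, `x_exp`, `p_value`, `significant`), `edges` (the
#'   validated subset), `alpha0`, `n_tests`, `corrected_threshold`,
#'   `correction`, `tau`, `t0`, `segmentation_summary`, and `attributes`.
#' @export
build_svcn <- function(events, attributes = NULL, tau = 300, alpha0 = 0.01,
                       n_t_policy = c("candidate_pairs", "all_pairs",
                                      "explicit"),
                       n_tests = NULL,
                       t0_policy = "midnight_of_first_day", t0 = NULL) {
  n_t_policy <- match.arg(n_t_policy)
  if (!inherits(events, "event_stream")) {
    svcn_abort("parameter_error", "events must be an event_stream")
  }
  empty_pairs <- data.table::data.table(
    i = character(), j = character(), x_obs = integer(),
    x_exp = numeric(), p_value = numeric(), significant = logical())
  if (nrow(events) == 0L) {
    return(new_svcn_result(nodes = character(), pair_stats = empty_pairs,
                           alpha0 = alpha0, n_tests = 0L,
                           p_b = NA_real_, tau = tau, t0 = NA_real_,
                           seg = NULL, attributes = attributes))
  }
  seg <- segment_events(events, tau = tau, t0_policy = t0_policy, t0 = t0)
  nodes <- sort(names(seg$n))
  pairs <- count_cooccurrences(seg)
  n_pairs <- nrow(pairs)
  n_t <- switch(n_t_policy,
    candidate_pairs = n_pairs,
    all_pairs = choose(length(nodes), 2),
    explicit = {
      if (!is_count(n_tests) || n_tests < 1) {
        svcn_abort("parameter_error",
                   "n_t_policy='explicit' requires integer n_tests >= 1")
      }
      n_tests
    })
  if (n_pairs == 0L) {
    p_b <- if (n_t >= 1) corrected_threshold(alpha0, n_t) else NA_real_
    return(new_svcn_result(nodes = nodes, pair_stats = empty_pairs,
                           alpha0 = alpha0, n_tests = n_t, p_b = p_b,
                           tau = tau, t0 = seg$t0, seg = seg,
                           attributes = attributes))
  }
  p_b <- corrected_threshold(alpha0, n_t)
  pairs[, x_exp := expected_cooccurrence(seg, i, j)]
  pairs[, p_value := poisson_upper_tail(x_obs, x_exp)]
  pairs[, significant := p_value < p_b]
  new_svcn_result(nodes = nodes, pair_stats = pairs, alpha0 = alpha0,
                  n_tests = n_t, p_b = p_b, tau = tau, t0 = seg$t0,
                  seg = seg, attributes = attributes)
}

new_svcn_result <- function(nodes, pair_stats, alpha0, n_tests, p_b,
                            tau, t0, seg, attributes) {
  structure(list(
    nodes = nodes,
    pair_stats = pair_stats,
    edges = pair_stats[pair_stats$significant %in% TRUE, , drop = FALSE],
    alpha0 = alpha0,
    n_tests = n_tests,
    corrected_threshold = p_b,
    correction = "bonferroni",
    tau = tau, t0 = t0,
    segmentation_summary = if (is.null(seg)) NULL else
      list(K = seg$K, M = seg$M, S = seg$S),
    attributes = attributes
  ), class = "svcn_result")
}

#' @export
print.svcn_result <- function(x, ...) {
  cat(sprintf(
    paste0("<svcn_result> %d nodes, %d validated edges ",
           "(of %d candidate pairs)\n",
           "  alpha0=%g, N_T=%d, p_b=%s (bonferroni)\n"),
    length(x$nodes), nrow(x$edges), nrow(x$pair_stats),
    x$alpha0, x$n_tests,
    if (is.na(x$corrected_threshold)) "NA" else
      formatC(x$corrected_threshold, format = "e", digits = 3)))
  invisible(x)
}

#' Convert a validated network to an igraph object
#'
#' @param svcn an `svcn_result`.
#' @param attributes optional `attribute_table` overriding the one stored in
#'   the result; columns become node attributes.
#' @return an undirected `igraph` graph over all nodes (isolates included)
#'   with edge attributes `x_obs`, `x_exp`, `p_value`.
#' @export
as_igraph <- function(svcn, attributes = NULL) {
  stopifnot(inherits(svcn, "svcn_result"))
  attributes <- attributes %||% svcn$attributes
  verts <- data.frame(name = svcn$nodes, stringsAsFactors = FALSE)
  if (!is.null(attributes)) {
    at <- as.data.frame(attributes)
    idx <- match(verts$name, at$subject_id)
    for (cn in setdiff(names(at), "subject_id")) {
      verts[[cn]] <- at[[cn]][idx]
    }
  }
  ed <- as.data.frame(svcn$edges)
  if (nrow(ed)) {
    ed <- data.frame(from = ed$i, to = ed$j, x_obs = ed$x_obs,
                     x_exp = ed$x_exp, p_value = ed$p_value,
                     stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(from = character(), to = character())
  }
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

# ---- Monte-Carlo oracle ----------------------------------------------------

#' Monte-Carlo p-value under the random-appearance null
#'
#' An independent check on the Poisson approximation: in each replicate the
#' two subjects are re-seated independently — each draws its `n` occupied
#' segments by weighted sampling without replacement with weights `L_k` —
#' and the overlap is compared with the observed count.
#'
#' @param seg a `segmentation`.
#' @param i,j subject ids present in `seg`.
#' @param n_rep number of replicates (>= 1).
#' @param seed integer seed; same seed gives identical results.
#' @param x_obs observed co-occurrence count; defaults to the count in
#'   `seg`.
#' @return list with `p_hat` (fraction of replicates with overlap
#'   `>= x_obs`), `se` (binomial standard error), `n_rep`, `x_obs`.
#' @export
mc_null_pvalue <- function(seg, i, j, n_rep = 10000L, seed = 1L,
                           x_obs = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  if (!is_count(n_rep) || n_rep < 1) {
    svcn_abort("parameter_error", "n_rep must be a positive integer")
  }
  n_i <- seg$n[[as.character(i)]]
  n_j <- seg$n[[as.character(j)]]
  if (is.null(n_i) || is.null(n_j)) {
    svcn_abort("parameter_error", "subject not present in segmentation")
  }
  if (n_i > seg$K || n_j > seg$K) {
    svcn_abort("parameter_error",
               "subject occupies more segments than exist (infeasible)")
  }
  if (is.null(x_obs)) {
    si <- seg$occ$seg[seg$occ$subject_id == as.character(i)]
    sj <- seg$occ$seg[seg$occ$subject_id == as.character(j)]
    x_obs <- length(intersect(si, sj))
  }
  if (x_obs == 0) {
    return(list(p_hat = 1, se = 0, n_rep = as.integer(n_rep),
                x_obs = 0L))
  }
  w <- seg$segments$L_k
  K <- seg$K
  hits <- withr_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      a <- sample.int(K, n_i, replace = FALSE, prob = w)
      b <- sample.int(K, n_j, replace = FALSE, prob = w)
      sum(a %in% b) >= x_obs
    }, logical(1))
  })
  p_hat <- mean(hits)
  list(p_hat = p_hat,
       se = sqrt(p_hat * (1 - p_hat) / n_rep),
       n_rep = as.integer(n_rep), x_obs = as.integer(x_obs))
}

#' Evaluate an expression under a temporary RNG seed
#' @noRd
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
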