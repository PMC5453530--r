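# Shared fixtures and independent oracles. Oracles are deliberately naive
# (series summation, explicit enumeration) so they stay independent of the
# implementation paths they check.

# Brute-force upper-tail Poisson probability by direct series summation in
# log space: sum_{n >= x} mu^n e^-mu / n!
oracle_poisson_tail <- function(x, mu, rel_tol = 1e-16, max_terms = 100000) {
  if (x == 0) return(1)
  logterms <- c()
  n <- x
  repeat {
    lt <- n * log(mu) - mu - lgamma(n + 1)
    logterms <- c(logterms, lt)
    if (n > mu && lt < max(logterms) + log(rel_tol)) break
    n <- n + 1
    if (n - x > max_terms) break
  }
  m <- max(logterms)
  exp(m) * sum(exp(logterms - m))
}

# Pearson correlation by explicit formula (population moments), used as the
# oracle for edge-end correlations.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Event stream where each element of `segments` (a list of subject-id
# vectors) becomes one segment of the given membership at one location,
# one slot apart, under tau = 300.
stream_from_segments <- function(segments, location = "A", tau = 300) {
  subj <- unlist(segments)
  tsec <- rep(seq_along(segments) - 1, lengths(segments)) * tau + 10
  event_stream(subj, tsec, rep(location, length(subj)))
}

# A segmentation with K equal segments of size L at one location, with two
# focal subjects placed in n_focal segments each (non-overlapping), padded
# with fillers so that every segment has exactly L members.
equal_segment_world <- function(K = 200, L = 500, n_focal = 5) {
  segs <- vector("list", K)
  filler <- 0L
  for (k in seq_len(K)) {
    need <- L
    members <- character()
    if (k <= n_focal) { members <- "focal_i"; need <- need - 1L }
    if (k > n_focal && k <= 2L * n_focal) {
      members <- "focal_j"; need <- need - 1L
    }
    members <- c(members, sprintf("f%07d", filler + seq_len(need)))
    filler <- filler + need
    segs[[k]] <- members
  }
  segment_events(stream_from_segments(segs), tau = 300,
                 t0_policy = "stream_min")
}

# Small attributed random graph for property sweeps.
random_attributed_graph <- function(n = 20, p = 0.2, n_groups = 2,
                                    seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  groups <- setNames(sample(LETTERS[seq_len(n_groups)], n, replace = TRUE),
                     igraph::V(g)$name)
  list(g = g, groups = groups)
}

tmpfile <- function(ext = ".csv") tempfile(fileext = ext)
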