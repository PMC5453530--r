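test_that("segmentation bins, deduplicates, and separates locations", {
  # repeat check-ins inside one slot collapse
  ev <- event_stream("s1", c(0, 100), c("L1", "L1"))
  seg <- segment_events(ev, tau = 300, t0_policy = "stream_min")
  expect_equal(seg$K, 1L)
  expect_equal(seg$M, 1L)
  expect_equal(unname(seg$n["s1"]), 1L)

  # floor((t - t0)/tau) binning
  ev2 <- event_stream(c("s1", "s2", "s3"), c(0, 100, 400),
                      c("L1", "L1", "L1"))
  seg2 <- segment_events(ev2, tau = 300, t0_policy = "stream_min")
  expect_equal(seg2$K, 2L)
  expect_equal(seg2$M, 3L)
  expect_equal(sort(seg2$segments$L_k), c(1L, 2L))

  # same slot, different locations -> separate segments
  ev3 <- event_stream(c("s1", "s2"), c(0, 0), c("L1", "L2"))
  seg3 <- segment_events(ev3, tau = 300, t0_policy = "stream_min")
  expect_equal(seg3$K, 2L)

  expect_error(segment_events(ev, tau = 0), class = "svcn_parameter_error")
})

test_that("segmentation conserves occurrences on random streams", {
  set.seed(11)
  for (rep in 1:5) {
    n_ev <- 500
    ev <- event_stream(sample(sprintf("s%02d", 1:30), n_ev, replace = TRUE),
                       runif(n_ev, 0, 86400 * 3),
                       sample(c("L1", "L2", "L3"), n_ev, replace = TRUE))
    seg <- segment_events(ev, tau = 300)
    expect_equal(sum(seg$n), seg$M)
    expect_equal(sum(seg$segments$L_k), seg$M)
    expect_equal(seg$K, nrow(seg$segments))
    expect_true(all(seg$segments$L_k >= 1))
  }
})

test_that("co-occurrence counts match hand enumeration", {
  seg <- segment_events(stream_from_segments(
    list(c("1", "2"), c("1", "2"), c("2", "3"))), t0_policy = "stream_min")
  x <- count_cooccurrences(seg)
  expect_equal(nrow(x), 2L)
  expect_equal(x$x_obs[x$i == "1" & x$j == "2"], 2L)
  expect_equal(x$x_obs[x$i == "2" & x$j == "3"], 1L)

  # all singleton segments -> no pairs
  seg2 <- segment_events(stream_from_segments(list("a", "b", "c")),
                         t0_policy = "stream_min")
  expect_equal(nrow(count_cooccurrences(seg2)), 0L)

  # one segment of 4 subjects -> choose(4,2) pairs, each once
  seg3 <- segment_events(stream_from_segments(list(c("a", "b", "c", "d"))),
                         t0_policy = "stream_min")
  x3 <- count_cooccurrences(seg3)
  expect_equal(nrow(x3), 6L)
  expect_true(all(x3$x_obs == 1L))

  # conservation: sum over pairs = sum_k choose(L_k, 2)
  seg4 <- segment_events(stream_from_segments(
    list(c("a", "b", "c"), c("a", "b"), c("b", "c", "d", "e"))),
    t0_policy = "stream_min")
  x4 <- count_cooccurrences(seg4)
  expect_equal(sum(x4$x_obs), sum(choose(seg4$segments$L_k, 2)))
})

test_that("expected co-occurrence matches hand evaluation and symmetry", {
  # L = [2, 2], n_i = n_j = 1 -> 1/3
  seg <- segment_events(stream_from_segments(
    list(c("i", "x"), c("j", "y"))), t0_policy = "stream_min")
  expect_equal(expected_cooccurrence(seg, "i", "j"), 1 / 3)
  expect_equal(expected_cooccurrence(seg, "j", "i"),
               expected_cooccurrence(seg, "i", "j"))

  # L = [3], n_i = n_j = 1 -> 1.0
  seg2 <- segment_events(stream_from_segments(list(c("i", "j", "k"))),
                         t0_policy = "stream_min")
  expect_equal(expected_cooccurrence(seg2, "i", "j"), 1.0)

  # all L_k = 1 -> 0
  seg3 <- segment_events(stream_from_segments(list("i", "j")),
                         t0_policy = "stream_min")
  expect_equal(expected_cooccurrence(seg3, "i", "j"), 0)
})

test_that("mean identity holds on small random streams", {
  set.seed(21)
  for (rep in 1:3) {
    ev <- event_stream(sample(sprintf("s%02d", 1:15), 200, replace = TRUE),
                       runif(200, 0, 86400),
                       sample(c("L1", "L2"), 200, replace = TRUE))
    seg <- segment_events(ev, tau = 600)
    subjects <- names(seg$n)
    pairs <- t(combn(subjects, 2))
    lhs <- sum(expected_cooccurrence(seg, pairs[, 1], pairs[, 2]))
    rhs <- seg$S / (seg$M * (seg$M - 1)) *
      sum(combn(seg$n, 2, FUN = prod))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("poisson_upper_tail: exact cases and series oracle", {
  expect_identical(poisson_upper_tail(0, 5), 1)
  expect_equal(poisson_upper_tail(1, 1), 1 - exp(-1), tolerance = 1e-14)
  # deep tail against the brute-force series
  for (case in list(c(10, 0.1), c(30, 0.5), c(50, 2), c(5, 1e-3))) {
    p <- poisson_upper_tail(case[1], case[2])
    expect_equal(p, oracle_poisson_tail(case[1], case[2]),
                 tolerance = 1e-10)
  }
  expect_error(poisson_upper_tail(1, 0), class = "svcn_parameter_error")
})

test_that("poisson_upper_tail is monotone in x_obs and mu", {
  mus <- c(0.01, 0.5, 3, 20)
  for (mu in mus) {
    p <- poisson_upper_tail(0:30, mu)
    expect_true(all(diff(p) <= 0))
  }
  for (x in c(1, 5, 20)) {
    p <- poisson_upper_tail(x, seq(0.01, 30, length.out = 40))
    expect_true(all(diff(p) >= 0))
  }
})

test_that("corrected_threshold implements Bonferroni", {
  expect_equal(corrected_threshold(0.01, 1), 0.01)
  expect_equal(corrected_threshold(0.05, 10), 0.005)
  expect_error(corrected_threshold(0.01, 0), class = "svcn_parameter_error")
})

test_that("build_svcn keeps obvious ties and drops chance ones", {
  # two subjects sharing 20 of 20 segments, diluted by 100 background
  # segments that make the null expectation small
  segs <- c(
    lapply(1:20, function(k) c("u", "v", sprintf("b%03d",
                                                 (k - 1) * 5 + 1:5))),
    lapply(1:100, function(k) sprintf("c%03d", (k - 1) * 5 + 1:5)))
  ev <- stream_from_segments(segs)
  res <- build_svcn(ev, tau = 300)
  expect_true(any(res$edges$i == "u" & res$edges$j == "v"))

  # a single co-occurrence between two active subjects is not significant
  segs2 <- c(lapply(1:30, function(k) c("u", sprintf("x%03d", k))),
             lapply(1:30, function(k) c("v", sprintf("y%03d", k))),
             list(c("u", "v")))
  res2 <- build_svcn(stream_from_segments(segs2))
  expect_false(any(res2$edges$i == "u" & res2$edges$j == "v"))

  # every edge honors the threshold strictly; isolates retained as nodes
  expect_true(all(res$edges$p_value < res$corrected_threshold))
  expect_true(all(c(res$edges$i, res$edges$j) %in% res$nodes))
})

test_that("build_svcn on an empty stream gives an empty result", {
  ev <- event_stream(character(), numeric(), character())
  res <- build_svcn(ev)
  expect_s3_class(res, "svcn_result")
  expect_equal(length(res$nodes), 0L)
  expect_equal(nrow(res$edges), 0L)
})

test_that("n_t_policy changes the threshold, not the statistics", {
  ev <- stream_from_segments(list(c("a", "b"), c("a", "b"), c("a", "c")))
  r1 <- build_svcn(ev, n_t_policy = "candidate_pairs")
  r2 <- build_svcn(ev, n_t_policy = "all_pairs")
  r3 <- build_svcn(ev, n_t_policy = "explicit", n_tests = 1000L)
  expect_equal(r1$pair_stats$p_value, r2$pair_stats$p_value)
  expect_equal(r1$n_tests, nrow(r1$pair_stats))
  expect_equal(r2$n_tests, choose(3, 2))
  expect_equal(r3$corrected_threshold, 0.01 / 1000)
})

test_that("mc_null_pvalue: trivial cases and determinism", {
  seg <- segment_events(stream_from_segments(
    list(c("i", "x"), c("j", "y"), c("x", "y"))), t0_policy = "stream_min")
  expect_equal(mc_null_pvalue(seg, "i", "j", n_rep = 50, seed = 1)$p_hat, 1)
  a <- mc_null_pvalue(seg, "i", "j", n_rep = 200, seed = 9, x_obs = 1)
  b <- mc_null_pvalue(seg, "i", "j", n_rep = 200, seed = 9, x_obs = 1)
  expect_identical(a$p_hat, b$p_hat)
  expect_error(mc_null_pvalue(seg, "i", "j", n_rep = 0),
               class = "svcn_parameter_error")
})

test_that("analytic p-value agrees with the Monte-Carlo null (small case)", {
  seg <- equal_segment_world(K = 100, L = 50, n_focal = 4)
  mu <- expected_cooccurrence(seg, "focal_i", "focal_j")
  p_an <- poisson_upper_tail(1, mu)
  mc <- mc_null_pvalue(seg, "focal_i", "focal_j", n_rep = 4000, seed = 3,
                       x_obs = 1)
  expect_lt(abs(p_an - mc$p_hat), 3 * max(mc$se, 1e-3))
})
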