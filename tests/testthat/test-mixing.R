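star <- function(k) {
  graph_from_edges(rep("hub", k), sprintf("leaf%d", seq_len(k)))
}

test_that("global degree assortativity: star, regular, oracle", {
  # K_{1,3}: ordered edge-end degree pairs (1,3) x3 and (3,1) x3 -> r = -1
  expect_equal(degree_assortativity_global(star(3)), -1)

  # 2-regular cycle: zero variance -> undefined
  expect_error(degree_assortativity_global(igraph::make_ring(5)),
               class = "svcn_undefined_coefficient")

  # random graph equals the brute-force Pearson over ordered pairs
  ra <- random_attributed_graph(20, 0.3, seed = 2)
  el <- igraph::as_edgelist(ra$g)
  deg <- igraph::degree(ra$g)
  x <- c(deg[el[, 1]], deg[el[, 2]])
  y <- c(deg[el[, 2]], deg[el[, 1]])
  expect_equal(degree_assortativity_global(ra$g), oracle_pearson(x, y),
               tolerance = 1e-12)
})

test_that("universal decomposition: trivial grouping and brute force", {
  ra <- random_attributed_graph(15, 0.3, seed = 4)
  r_global <- degree_assortativity_global(ra$g)
  one <- setNames(rep("all", 15), igraph::V(ra$g)$name)
  um1 <- universal_assortativity_matrix(ra$g, one)
  expect_equal(dim(um1), c(1L, 1L))
  expect_equal(um1[1, 1], r_global, tolerance = 1e-12)

  # toy two-group graph vs explicit edge-contribution sums
  g <- graph_from_edges(c("a", "a", "b", "c", "d"),
                        c("b", "c", "c", "d", "e"))
  grp <- setNames(c("G1", "G1", "G1", "G2", "G2"), letters[1:5])
  um <- universal_assortativity_matrix(g, grp)
  el <- igraph::as_edgelist(g)
  deg <- igraph::degree(g)
  q <- c(deg[el[, 1]], deg[el[, 2]]) - 1
  mu <- mean(q); s2 <- mean((q - mu)^2); m <- nrow(el)
  rho <- (deg[el[, 1]] - 1 - mu) * (deg[el[, 2]] - 1 - mu) / (m * s2)
  pair_lab <- apply(cbind(grp[el[, 1]], grp[el[, 2]]), 1,
                    function(z) paste(sort(z), collapse = "|"))
  exp_11 <- sum(rho[pair_lab == "G1|G1"])
  exp_12 <- sum(rho[pair_lab == "G1|G2"])
  exp_22 <- sum(rho[pair_lab == "G2|G2"])
  expect_equal(um["G1", "G1"], exp_11, tolerance = 1e-12)
  expect_equal(um["G1", "G2"], exp_12, tolerance = 1e-12)
  expect_equal(um["G2", "G2"], exp_22, tolerance = 1e-12)
})

test_that("universal decomposition conserves the global coefficient", {
  for (sd in 1:25) {
    ra <- random_attributed_graph(18, 0.3, n_groups = 3, seed = sd)
    if (igraph::ecount(ra$g) < 2) next
    r <- tryCatch(degree_assortativity_global(ra$g),
                  svcn_undefined_coefficient = function(e) NULL)
    if (is.null(r)) next
    um <- universal_assortativity_matrix(ra$g, ra$groups)
    expect_lt(abs(sum(um[upper.tri(um, diag = TRUE)]) - r), 1e-10)
  }
})

test_that("scalar attribute assortativity: perfect, anti, oracle", {
  # two components with constant values 0 / 1 -> perfect assortativity
  g <- graph_from_edges(c("a", "c"), c("b", "d"))
  expect_equal(attribute_assortativity_scalar(
    g, c(a = 0, b = 0, c = 1, d = 1)), 1)

  # K_{2,2} with side-distinct values -> -1
  kb <- graph_from_edges(c("u1", "u1", "u2", "u2"),
                         c("v1", "v2", "v1", "v2"))
  expect_equal(attribute_assortativity_scalar(
    kb, c(u1 = 0, u2 = 0, v1 = 1, v2 = 1)), -1)

  # random values equal the brute-force edge-end Pearson
  ra <- random_attributed_graph(20, 0.3, seed = 6)
  set.seed(61)
  vals <- setNames(rnorm(20), igraph::V(ra$g)$name)
  el <- igraph::as_edgelist(ra$g)
  x <- c(vals[el[, 1]], vals[el[, 2]])
  y <- c(vals[el[, 2]], vals[el[, 1]])
  expect_equal(attribute_assortativity_scalar(ra$g, vals),
               oracle_pearson(x, y), tolerance = 1e-12)

  expect_error(attribute_assortativity_scalar(
    g, c(a = 1, b = 1, c = 1, d = 1)),
    class = "svcn_undefined_coefficient")
})

test_that("categorical assortativity: perfect, K22, permutation invariant", {
  g <- graph_from_edges(c("a", "c"), c("b", "d"))
  lab <- c(a = "X", b = "X", c = "Y", d = "Y")
  expect_equal(attribute_assortativity_categorical(g, lab), 1)

  kb <- graph_from_edges(c("u1", "u1", "u2", "u2"),
                         c("v1", "v2", "v1", "v2"))
  side <- c(u1 = "L", u2 = "L", v1 = "R", v2 = "R")
  expect_equal(attribute_assortativity_categorical(kb, side), -1)

  ra <- random_attributed_graph(20, 0.3, n_groups = 3, seed = 9)
  r1 <- attribute_assortativity_categorical(ra$g, ra$groups)
  relab <- c(A = "Z", B = "Q", C = "W")
  r2 <- attribute_assortativity_categorical(
    ra$g, setNames(relab[ra$groups], names(ra$groups)))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(attribute_assortativity_categorical(
    g, c(a = "X", b = "X", c = "X", d = "X")),
    class = "svcn_undefined_coefficient")
})

test_that("TFPI: homophily toys and the 4-node hand example", {
  # two equal groups, only intra-group edges -> q = +1 on, -1 off diagonal
  g <- graph_from_edges(c("a", "c"), c("b", "d"))
  grp <- c(a = "G1", b = "G1", c = "G2", d = "G2")
  tf <- tfpi_matrix(g, grp)
  expect_equal(unname(diag(tf$q)), c(1, 1))
  expect_equal(tf$q["G1", "G2"], -1)
  expect_equal(tf$q["G2", "G1"], -1)
  expect_equal(unname(rowSums(tf$p)), c(1, 1))

  # hand example: G1 = {a, b}, G2 = {c, d}, edges a-b, a-c
  g2 <- graph_from_edges(c("a", "a"), c("b", "c"), nodes = letters[1:4])
  tf2 <- tfpi_matrix(g2, grp)
  expect_equal(tf2$q["G1", "G1"], 1 / 3)
  expect_equal(tf2$q["G1", "G2"], -1 / 3)
  expect_equal(tf2$q["G2", "G1"], 1)
  expect_equal(tf2$q["G2", "G2"], -1)
  # s_i is the group's mean degree
  expect_equal(unname(tf2$s_i), c(1.5, 0.5))
})

test_that("TFPI vanishes under proportional mixing and flags empty rows", {
  # large bipartite-ish random graph with size-proportional attachment:
  # dyad probability independent of group membership
  set.seed(31)
  n <- 300
  grp <- setNames(sample(c("A", "B", "C"), n, replace = TRUE,
                         prob = c(0.5, 0.3, 0.2)), sprintf("n%03d", 1:n))
  g <- igraph::sample_gnp(n, 0.05)
  igraph::V(g)$name <- names(grp)
  tf <- tfpi_matrix(g, grp)
  expect_true(all(abs(tf$q) < 0.12))  # ~0 within sampling error

  # bounds: q_ij in [-w_j/(1-w_j), 1]
  lower <- -tf$w / (1 - tf$w)
  for (j in seq_along(tf$w)) {
    expect_true(all(tf$q[, j] >= lower[j] - 1e-12))
    expect_true(all(tf$q[, j] <= 1 + 1e-12))
  }

  # a group with no edges is flagged undefined, not zero
  g3 <- graph_from_edges("a", "b", nodes = c("a", "b", "z"))
  tf3 <- tfpi_matrix(g3, c(a = "G1", b = "G1", z = "G2"))
  expect_false(tf3$defined["G2"])
  expect_true(all(is.na(tf3$q["G2", ])))
})

test_that("planted homophily is recovered as positive intra-group TFPI", {
  pop <- gen_population(population_spec(300), seed = 5)
  ties <- gen_tie_graph(pop, tie_model(p_base = 0.01, beta = c(grade = 6)),
                        seed = 6)
  tf <- tfpi_matrix(ties, grouping_scheme(pop, "grade"))
  expect_true(all(diag(tf$q)[tf$defined] > 0))
})

test_that("mixing_summary dispatches on attribute type", {
  pop <- gen_population(population_spec(200), seed = 15)
  ties <- gen_tie_graph(pop, tie_model(p_base = 0.02, beta = c(grade = 5)),
                        seed = 16)
  mx <- mixing_summary(ties, pop, "grade")
  expect_equal(mx$type, "categorical")
  expect_true(mx$attribute_assortativity > 0)  # planted intra-grade bias
  expect_equal(sum(mx$universal_matrix[upper.tri(mx$universal_matrix,
                                                 diag = TRUE)]),
               mx$degree_assortativity, tolerance = 1e-10)
})
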