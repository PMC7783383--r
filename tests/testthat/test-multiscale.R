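test_that("walk operators define a proper stationary random walk", {
  set.seed(23)
  A <- random_adjacency(7)
  ops <- walk_operators(A)
  expect_equal(sum(ops$pi), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(ops$M)), rep(1, 7), tolerance = 1e-12)
  expect_error(walk_operators(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("stability of the one-block partition is zero and the t->0 limit holds", {
  set.seed(24)
  A <- random_adjacency(6)
  ops <- walk_operators(A)
  one <- setNames(rep(1L, 6), ops$nodes)
  for (t in c(0.1, 1, 10)) {
    expect_equal(markov_stability(ops, one, t), 0, tolerance = 1e-10)
  }
  singles <- setNames(1:6, ops$nodes)
  expect_equal(markov_stability(ops, singles, 1e-8),
               1 - sum(ops$pi^2), tolerance = 1e-6)
  expect_error(markov_stability(ops, singles, -1), "t must be")
  expect_error(markov_stability(ops, setNames(1:5, ops$nodes[1:5]), 1),
               "node set")
})

test_that("the spectral propagator matches a dense matrix exponential", {
  set.seed(25)
  A <- random_adjacency(8)
  ops <- walk_operators(A)
  for (t in c(0.3, 2)) {
    B <- surgcomm:::stability_matrix(ops, t)
    M <- ops$M
    E <- as.matrix(Matrix::expm(-t * (diag(8) - M)))
    Bref <- diag(ops$pi) %*% E - outer(ops$pi, ops$pi)
    Bref <- (Bref + t(Bref)) / 2
    expect_equal(unname(B), unname(Bref), tolerance = 1e-10)
  }
})

test_that("full and linearised stability agree to O(t^2) at small t", {
  set.seed(26)
  for (rep in seq_len(5)) {
    A <- random_adjacency(sample(5:9, 1))
    ops <- walk_operators(A)
    m <- setNames(sample(1:3, nrow(A), replace = TRUE), ops$nodes)
    t <- 1e-3
    expect_equal(markov_stability(ops, m, t, "exp"),
                 markov_stability(ops, m, t, "linearised"),
                 tolerance = 1e-4)
  }
})

two_triangles <- function() {
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  }
  dimnames(A) <- list(letters[1:6], letters[1:6])
  A
}

test_that("the clique split maximises stability among all partitions", {
  A <- two_triangles()
  ops <- walk_operators(A)
  cliques <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), letters[1:6])
  pm <- partition_masks(6)
  # below t = ln(2)/1.5 the singleton partition overtakes the cliques, so
  # "small t" here means small but past that crossover
  for (t in c(0.5, 1)) {
    B <- surgcomm:::stability_matrix(ops, t)
    vals <- as.vector(pm$masks %*% as.vector(B))
    best <- max(vals)
    expect_equal(markov_stability(ops, cliques, t), best, tolerance = 1e-12)
    # strictly better than any partition that splits a clique
    splits <- apply(pm$parts, 1, function(p) {
      length(unique(p[1:3])) > 1 || length(unique(p[4:6])) > 1
    })
    expect_true(all(vals[splits] < best - 1e-9))
  }
})

test_that("the optimiser recovers planted cliques and is deterministic", {
  A <- two_triangles()
  p <- optimise_partition(A, t = 1, n_runs = 5, seed = 3)
  expect_equal(p$n_communities, 2)
  expect_equal(unname(p$membership), c(1L, 1L, 1L, 2L, 2L, 2L))
  p2 <- optimise_partition(A, t = 1, n_runs = 5, seed = 3)
  expect_identical(p, p2)
})

test_that("variation of information behaves as an information metric", {
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(variation_of_information(1:4, rep(1, 4)), log(4),
               tolerance = 1e-12)
  set.seed(27)
  for (rep in seq_len(20)) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(variation_of_information(a, b),
                 variation_of_information(b, a), tolerance = 1e-12)
    expect_gte(variation_of_information(a, b), 0)
  }
  expect_error(variation_of_information(setNames(1:3, c("a", "b", "c")),
                                        setNames(1:3, c("a", "b", "d"))),
               "node set")
})

test_that("adjusted Rand index agrees with the mclust implementation", {
  set.seed(28)
  for (rep in seq_len(20)) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2), c(2, 2, 1)), 1)
})

test_that("disconnected components give one plateau spanning the scan", {
  A <- matrix(0, 9, 9)
  for (k in 0:2) {
    ix <- 3 * k + 1:3
    A[ix, ix] <- 1
  }
  diag(A) <- 0
  dimnames(A) <- list(paste0("n", 1:9), paste0("n", 1:9))
  grid <- default_t_grid(12, 0.5, 50)
  sc <- scan_and_select(A, grid, n_runs = 5, seed = 4)
  expect_true(all(sc$table$n_communities == 3))
  expect_equal(nrow(sc$plateaus), 1)
  expect_equal(sc$plateaus$n_points, 12)
  expect_equal(length(sc$robust), 1)
  expect_equal(sc$robust[[1]]$n_communities, 3)
})

test_that("an unsatisfiable plateau criterion yields no robust partition", {
  A <- two_triangles()
  grid <- default_t_grid(6, 0.5, 5)
  sc <- scan_and_select(A, grid, selection_criteria(min_plateau = 10),
                        n_runs = 3, seed = 5)
  expect_equal(length(sc$robust), 0)
  expect_equal(nrow(sc$plateaus), 0)
})

test_that("plateau community counts are non-increasing from fine to coarse", {
  world <- tiny_world(seed = 15, lsoas = 8)
  adm <- generate_admissions(world, 2000, seed = 15)
  net <- build_network_from_admissions(world, adm)
  sc <- scan_and_select(net$graph, default_t_grid(20, 0.05, 1e4),
                        n_runs = 8, seed = 6)
  ks <- vapply(sc$robust, function(p) p$n_communities, integer(1))
  expect_true(all(diff(ks) <= 0))
  expect_gte(length(sc$robust), 1)
})
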