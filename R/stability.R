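# Markov stability: random-walk operators, the quality function, and its
# Louvain-style optimisation.

#' Continuous-time random-walk operators of a weighted graph
#'
#' For an undirected weighted graph with adjacency `A`, degree (strength)
#' vector `d` and total weight `2m = sum(d)`: the stationary distribution is
#' `pi = d / 2m`, the one-step transition operator is `M = D^-1 A`, and the
#' continuous-time propagator at Markov time `t` is `exp(-t (I - M))`. The
#' spectral decomposition of the symmetrised Laplacian
#' `I - D^-1/2 A D^-1/2` is precomputed so propagators at many `t` are cheap.
#'
#' @param graph an [igraph::graph] with edge weights, or a symmetric
#'   non-negative adjacency matrix. Every node must have positive strength.
#' @return A list of class `surgcomm_walk_operators`: `A`, `degree`, `pi`,
#'   `M`, `nodes`, and the spectral pieces used internally.
#' @export
walk_operators <- function(graph) {
  A <- if (igraph::is_igraph(graph)) {
    as.matrix(igraph::as_adjacency_matrix(
      graph, attr = if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
      sparse = TRUE))
  } else {
    as.matrix(graph)
  }
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10))) {
    stop_input("adjacency must be symmetric")
  }
  n <- nrow(A)
  nodes <- rownames(A) %||% as.character(seq_len(n))
  d <- rowSums(A)
  if (any(d <= 0)) stop_input("every node needs positive strength")
  total <- sum(d)
  piv <- d / total
  M <- A / d
  s <- sqrt(d)
  Lsym <- diag(n) - (A / s) / rep(s, each = n)  # I - D^-1/2 A D^-1/2
  Lsym <- (Lsym + t(Lsym)) / 2
  eig <- eigen(Lsym, symmetric = TRUE)
  structure(list(A = A, degree = d, pi = piv, M = M, total = total,
                 nodes = nodes, sqrt_d = s, eig = eig),
            class = "surgcomm_walk_operators")
}

# Symmetric stability matrix B(t) with Q(partition) = sum of within-community
# entries. Full: Pi exp(-t(I-M)) - pi pi^T, computed spectrally as
# (1/2m) D^1/2 V e^{-t L} V^T D^1/2. Linearised (first order in t):
# (1-t) Pi + t A/2m - pi pi^T; equals modularity at t = 1.
stability_matrix <- function(ops, t, variant = c("exp", "linearised")) {
  variant <- match.arg(variant)
  if (t <= 0) stop_input("Markov time t must be > 0")
  n <- length(ops$pi)
  if (variant == "exp") {
    V <- ops$eig$vectors
    E <- V %*% (exp(-t * ops$eig$values) * t(V))
    B <- (ops$sqrt_d * E * rep(ops$sqrt_d, each = n)) / ops$total
    B <- (B + t(B)) / 2
  } else {
    B <- t * ops$A / ops$total
    diag(B) <- diag(B) + (1 - t) * ops$pi
  }
  B - outer(ops$pi, ops$pi)
}

partition_quality <- function(B, membership) {
  agg <- rowsum(B, membership)
  agg2 <- rowsum(t(agg), membership)
  sum(diag(as.matrix(agg2)))
}

normalise_membership <- function(m, nodes = NULL) {
  m <- as.integer(factor(m, levels = unique(m)))
  if (!is.null(nodes)) names(m) <- nodes
  m
}

resolve_membership <- function(partition, nodes) {
  m <- if (inherits(partition, "surgcomm_partition")) partition$membership else partition
  if (!is.null(names(m))) {
    if (!setequal(names(m), nodes)) {
      stop_input("partition node set does not match the graph")
    }
    m <- m[nodes]
  } else if (length(m) != length(nodes)) {
    stop_input("partition must cover every node")
  }
  if (any(is.na(m))) stop_input("partition must cover every node")
  m
}

#' Markov stability of a partition
#'
#' The stability of a hard partition with indicator matrix `H` at Markov
#' time `t` is `trace(H^T (Pi exp(-t(I-M)) - pi pi^T) H)`: the probability
#' that a stationary continuous-time random walk is in the same community at
#' times 0 and `t`, minus the same probability for independent draws. Small
#' `t` rewards fine partitions, large `t` coarse ones. The linearised
#' variant replaces the exponential by its first-order expansion
#' `(1-t) Pi + t Pi M - pi pi^T` (modularity at `t = 1`), and is the
#' documented fallback for graphs too large to exponentiate.
#'
#' @param graph graph or adjacency matrix (see [walk_operators()]), or a
#'   precomputed `surgcomm_walk_operators`.
#' @param partition membership vector (named by node, or in node order), or
#'   a `surgcomm_partition`.
#' @param t Markov time, > 0.
#' @param variant `"exp"` (default) or `"linearised"`.
#' @return The stability value (a real number).
#' @export
markov_stability <- function(graph, partition, t, variant = c("exp", "linearised")) {
  ops <- if (inherits(graph, "surgcomm_walk_operators")) graph else walk_operators(graph)
  m <- resolve_membership(partition, ops$nodes)
  B <- stability_matrix(ops, t, variant)
  partition_quality(B, m)
}

#' Optimise Markov stability at one Markov time
#'
#' Runs the generalised Louvain optimiser `n_runs` times on the stability
#' matrix at time `t`, each run visiting level-0 nodes in a fresh random
#' order drawn from a seed derived from `seed` and the run index, and
#' returns the best-scoring partition. Deterministic for fixed inputs.
#'
#' @inheritParams markov_stability
#' @param n_runs number of optimiser restarts (>= 1).
#' @param seed integer seed for the restart orders.
#' @return A list of class `surgcomm_partition`: `membership` (named integer
#'   vector, labels 1..k by first occurrence), `t`, `stability`,
#'   `n_communities`, `n_runs`, `seed`.
#' @export
optimise_partition <- function(graph, t, n_runs = 50, seed = 1,
                               variant = c("exp", "linearised")) {
  stopifnot(n_runs >= 1)
  ops <- if (inherits(graph, "surgcomm_walk_operators")) graph else walk_operators(graph)
  B <- stability_matrix(ops, t, variant)
  runs <- optimise_runs(B, ops$nodes, n_runs, seed, t)
  best <- runs$best
  structure(list(membership = best$membership, t = t,
                 stability = best$score,
                 n_communities = max(best$membership),
                 n_runs = n_runs, seed = seed),
            class = "surgcomm_partition")
}

#' @export
print.surgcomm_partition <- function(x, ...) {
  cat("<surgcomm_partition> t =", format(x$t), "|", x$n_communities,
      "communities | stability", format(x$stability, digits = 6), "\n")
  invisible(x)
}

# All restarts at one t; returns every membership (for VI diagnostics) plus
# the best. Run r uses node order sample.int(n) under derive_seed(seed, ...).
optimise_runs <- function(B, nodes, n_runs, seed, t) {
  n <- nrow(B)
  members <- vector("list", n_runs)
  scores <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    ord <- with_seed(derive_seed(seed, sprintf("louvain|%.10g|%d", t, r)),
                     sample.int(n))
    m <- louvain_dense_cpp(B, ord - 1L) + 1L
    m <- normalise_membership(m, nodes)
    members[[r]] <- m
    scores[r] <- partition_quality(B, m)
  }
  best_i <- which.max(scores)
  list(members = members, scores = scores,
       best = list(membership = members[[best_i]], score = scores[best_i]))
}
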