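# Scanning Markov times and selecting robust partitions.

#' Default log-spaced Markov-time grid
#'
#' @param n number of grid points (default 40).
#' @param t_min,t_max grid endpoints (defaults 1e-2 and 1e2).
#' @return Strictly increasing numeric vector.
#' @export
default_t_grid <- function(n = 40, t_min = 1e-2, t_max = 1e5) {
  stopifnot(n >= 2, t_min > 0, t_max > t_min)
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Robust-scale selection criteria
#'
#' A robust scale is a maximal run of consecutive grid points whose best
#' partitions have the same number of communities and whose mean pairwise
#' variation of information across optimiser restarts stays at or below
#' `vi_max`, with run length at least `min_plateau`. The two trivial
#' partitions are excluded from the robust list by default: the one-block
#' partition (always maximally stable at large enough times) and the
#' all-singletons partition (the optimum at vanishing Markov time, and also
#' what the optimiser returns once the propagator has numerically converged
#' to stationarity at very large times); neither carries community
#' information.
#'
#' @param min_plateau minimum plateau length in grid points.
#' @param vi_max maximum mean intra-time VI (nats).
#' @param exclude_trivial drop plateaus whose partitions are one block or
#'   all singletons.
#' @return A named list.
#' @export
selection_criteria <- function(min_plateau = 4, vi_max = 0.05,
                               exclude_trivial = TRUE) {
  stopifnot(min_plateau >= 1, vi_max >= 0)
  list(min_plateau = as.integer(min_plateau), vi_max = vi_max,
       exclude_trivial = isTRUE(exclude_trivial))
}

#' Scan Markov times and select robust partitions
#'
#' For each Markov time on the grid the stability objective is optimised
#' from `n_runs` restarts; the scan records the best partition, the mean
#' pairwise VI across restarts (intra-time robustness) and the VI between
#' the best partitions at consecutive times (inter-time persistence).
#' Plateaus meeting the [selection_criteria()] become robust scales, each
#' represented by its best-scoring partition, ordered fine to coarse.
#'
#' @param graph graph or adjacency matrix (see [walk_operators()]).
#' @param t_grid strictly increasing Markov times, length >= 10 recommended.
#' @param criteria a [selection_criteria()].
#' @param n_runs optimiser restarts per time.
#' @param seed integer seed.
#' @param variant stability variant, see [markov_stability()].
#' @return A list of class `surgcomm_scan`: `table` (tibble `t`,
#'   `n_communities`, `stability`, `vi_intra`, `vi_inter`), `robust` (list
#'   of `surgcomm_partition`, fine to coarse), `plateaus` (tibble
#'   `t_start`, `t_end`, `n_points`, `n_communities`, `t_representative`),
#'   `criteria`, `seed`.
#' @export
scan_and_select <- function(graph, t_grid = default_t_grid(),
                            criteria = selection_criteria(),
                            n_runs = 50, seed = 1,
                            variant = c("exp", "linearised")) {
  if (length(t_grid) == 0) stop_input("t_grid must not be empty")
  if (any(diff(t_grid) <= 0)) stop_input("t_grid must be strictly increasing")
  ops <- if (inherits(graph, "surgcomm_walk_operators")) graph else walk_operators(graph)
  nt <- length(t_grid)
  best <- vector("list", nt)
  n_comm <- integer(nt)
  stab <- numeric(nt)
  vi_intra <- numeric(nt)
  vi_inter <- rep(NA_real_, nt)
  for (ti in seq_len(nt)) {
    t <- t_grid[ti]
    B <- stability_matrix(ops, t, variant)
    runs <- optimise_runs(B, ops$nodes, n_runs, seed, t)
    best[[ti]] <- structure(
      list(membership = runs$best$membership, t = t,
           stability = runs$best$score,
           n_communities = max(runs$best$membership),
           n_runs = n_runs, seed = seed),
      class = "surgcomm_partition")
    n_comm[ti] <- best[[ti]]$n_communities
    stab[ti] <- runs$best$score
    vi_intra[ti] <- mean_pairwise_vi(runs$members)
    if (ti > 1) {
      vi_inter[ti] <- variation_of_information(best[[ti - 1]], best[[ti]])
    }
  }
  tab <- tibble::tibble(t = t_grid, n_communities = n_comm, stability = stab,
                        vi_intra = vi_intra, vi_inter = vi_inter)
  plateaus <- find_plateaus(tab, criteria, n_nodes = length(ops$nodes))
  robust <- lapply(seq_len(nrow(plateaus)), function(i) {
    ix <- seq(plateaus$i_start[i], plateaus$i_end[i])
    rep_i <- ix[which.max(stab[ix])]
    best[[rep_i]]
  })
  plateaus$t_representative <- vapply(robust, function(p) p$t, numeric(1))
  structure(list(table = tab, robust = robust,
                 plateaus = plateaus[, c("t_start", "t_end", "n_points",
                                         "n_communities", "t_representative")],
                 criteria = criteria, seed = seed),
            class = "surgcomm_scan")
}

mean_pairwise_vi <- function(members) {
  k <- length(members)
  if (k < 2) return(0)
  tot <- 0
  np <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      tot <- tot + variation_of_information(members[[i]], members[[j]])
      np <- np + 1
    }
  }
  tot / np
}

# Maximal runs of consecutive eligible points with constant community count.
find_plateaus <- function(tab, criteria, n_nodes = Inf) {
  ok <- tab$vi_intra <= criteria$vi_max
  grp <- cumsum(c(TRUE, diff(tab$n_communities) != 0 | diff(ok) != 0))
  grp[!ok] <- NA
  out <- list()
  for (g in unique(grp[!is.na(grp)])) {
    ix <- which(!is.na(grp) & grp == g)
    if (length(ix) < criteria$min_plateau) next
    k <- tab$n_communities[ix[1]]
    if (criteria$exclude_trivial && (k == 1 || k == n_nodes)) next
    out[[length(out) + 1]] <- tibble::tibble(
      i_start = ix[1], i_end = ix[length(ix)],
      t_start = tab$t[ix[1]], t_end = tab$t[ix[length(ix)]],
      n_points = length(ix), n_communities = k)
  }
  if (!length(out)) {
    return(tibble::tibble(i_start = integer(), i_end = integer(),
                          t_start = numeric(), t_end = numeric(),
                          n_points = integer(), n_communities = integer()))
  }
  dplyr::bind_rows(out)
}

#' @export
print.surgcomm_scan <- function(x, ...) {
  cat("<surgcomm_scan> ", nrow(x$table), " Markov times, ",
      length(x$robust), " robust partition(s): ",
      paste(vapply(x$robust, function(p) p$n_communities, integer(1)),
            collapse = ", "),
      " communities\n", sep = "")
  invisible(x)
}
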