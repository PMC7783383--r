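# Presentation-proportion matrix, cosine similarity and RMST sparsification.

#' Build the LSOA-by-provider presentation-proportion matrix
#'
#' Restricts events to high-volume procedures performed at their regular
#' provider sites, pools counts over all HVPs into a single LSOA-by-site
#' table, and row-normalises so each row gives the proportion of that LSOA's
#' HVP events presenting to each site. An alternative per-HVP mode computes
#' one matrix per procedure (see [cosine_similarity()]'s `flow_list` input).
#'
#' @param events events table (merged site codes) with `lsoa_code`,
#'   `site_code`, `opcs3`.
#' @param hvps an [identify_hvps()] result.
#' @param providers a [regular_providers()] result.
#' @param lsoa_codes optional full LSOA universe, used to record LSOAs with
#'   zero eligible events (excluded from the matrix, listed in the
#'   `excluded_lsoas` attribute).
#' @param per_hvp if `TRUE`, return a named list of one matrix per HVP
#'   instead of the pooled matrix.
#' @return A row-stochastic matrix of class `surgcomm_flow_matrix` (rows =
#'   LSOAs with events, columns = regular provider sites), with attributes
#'   `excluded_lsoas` and `counts` (the unnormalised count matrix); or a
#'   list of such matrices when `per_hvp = TRUE`.
#' @export
build_flow_matrix <- function(events, hvps, providers, lsoa_codes = NULL,
                              per_hvp = FALSE) {
  eligible <- lapply(names(providers$providers), function(code) {
    ev <- events[events$opcs3 == code &
                   events$site_code %in% providers$providers[[code]], ,
                 drop = FALSE]
    ev
  })
  names(eligible) <- names(providers$providers)
  all_ev <- dplyr::bind_rows(eligible)
  if (nrow(all_ev) == 0) stop_input("no eligible HVP events at regular providers")
  site_universe <- sort(unique(unlist(providers$providers)))
  make_matrix <- function(ev) {
    lsoas <- sort(unique(ev$lsoa_code))
    counts <- table(factor(ev$lsoa_code, levels = lsoas),
                    factor(ev$site_code, levels = site_universe))
    counts <- matrix(as.integer(counts), nrow = length(lsoas),
                     dimnames = list(lsoas, site_universe))
    fm <- counts / rowSums(counts)
    excluded <- if (is.null(lsoa_codes)) character() else
      setdiff(lsoa_codes, lsoas)
    structure(fm, counts = counts, excluded_lsoas = excluded,
              class = c("surgcomm_flow_matrix", class(fm)))
  }
  if (per_hvp) lapply(eligible, make_matrix) else make_matrix(all_ev)
}

#' Cosine similarity between LSOA presentation patterns
#'
#' For LSOAs A and B with presentation proportions `A_i`, `B_i` over the `n`
#' provider sites, the similarity is
#' `sum(A_i B_i) / sqrt(sum(A_i^2) sum(B_i^2))`. With a list of per-HVP flow
#' matrices, per-HVP similarities are averaged over the procedures for which
#' both LSOAs have events.
#'
#' @param flow a [build_flow_matrix()] matrix, or a named list of them.
#' @return A symmetric matrix in `[0, 1]` with unit diagonal over the
#'   included LSOAs.
#' @export
cosine_similarity <- function(flow) {
  if (is.list(flow) && !is.matrix(flow)) {
    lsoas <- sort(unique(unlist(lapply(flow, rownames))))
    acc <- matrix(0, length(lsoas), length(lsoas), dimnames = list(lsoas, lsoas))
    cnt <- acc
    for (fm in flow) {
      s <- cosine_similarity(fm)
      ix <- match(rownames(s), lsoas)
      acc[ix, ix] <- acc[ix, ix] + s
      cnt[ix, ix] <- cnt[ix, ix] + 1
    }
    if (any(cnt == 0)) {
      stop_input("some LSOA pairs share no HVP; use the pooled matrix")
    }
    out <- acc / cnt
    diag(out) <- 1
    return(out)
  }
  if (nrow(flow) < 2) stop_input("need at least 2 LSOAs")
  norms <- sqrt(rowSums(flow^2))
  if (any(norms == 0)) stop_input("zero-norm row reached cosine_similarity")
  rn <- flow / norms
  s <- tcrossprod(rn)
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 1
  s
}

#' Sparsify a similarity network with a relaxed minimum spanning tree
#'
#' Converts similarities to distances `d = 1 - s`, builds the minimum
#' spanning tree (MST) on `d`, and additionally retains any direct edge
#' `(i, j)` whose distance beats its relaxed MST-path bottleneck:
#' `d_ij < maxlink_ij + min(d_i^(k), d_j^(k))`, where `maxlink_ij` is the
#' largest single-step distance on the MST path between `i` and `j` and
#' `d_i^(k)` is `i`'s distance to its `k_local`-th nearest neighbour. This
#' preserves global connectivity (the MST) while re-admitting locally
#' consistent short-range edges.
#'
#' @param sim symmetric similarity matrix with dimnames (see
#'   [cosine_similarity()]).
#' @param k_local local-scale neighbour index, default 1.
#' @return An undirected connected [igraph::graph] whose vertices are the
#'   LSOAs; edge attribute `weight` holds the similarity and `provenance` is
#'   `"MST"` or `"relaxation"`.
#' @export
rmst_sparsify <- function(sim, k_local = 1) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim), k_local >= 1)
  n <- nrow(sim)
  nodes <- rownames(sim) %||% as.character(seq_len(n))
  off <- sim
  diag(off) <- 0
  dead <- rowSums(off > 0) == 0
  if (any(dead)) {
    stop_input("LSOAs with zero similarity to every other node: ",
               paste(nodes[dead], collapse = ", "))
  }
  gpos <- igraph::graph_from_adjacency_matrix(off > 0, mode = "undirected")
  comp <- igraph::components(gpos)
  if (comp$no > 1) {
    small <- which(comp$membership != which.max(comp$csize))
    stop_input("similarity graph is disconnected; isolated nodes include: ",
               paste(head(nodes[small], 10), collapse = ", "))
  }
  d <- 1 - sim
  diag(d) <- 0
  gd <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(gd, weights = igraph::E(gd)$weight)
  mst_el <- igraph::as_edgelist(mst, names = FALSE)
  mst_adj <- lapply(seq_len(n), function(i) integer())
  for (e in seq_len(nrow(mst_el))) {
    i <- mst_el[e, 1]; j <- mst_el[e, 2]
    mst_adj[[i]] <- c(mst_adj[[i]], j)
    mst_adj[[j]] <- c(mst_adj[[j]], i)
  }
  # max single-step distance along the MST path, from each root by DFS
  maxlink <- matrix(0, n, n)
  for (root in seq_len(n)) {
    stack <- root
    seen <- logical(n)
    seen[root] <- TRUE
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (v in mst_adj[[u]]) {
        if (!seen[v]) {
          seen[v] <- TRUE
          maxlink[root, v] <- max(maxlink[root, u], d[u, v])
          stack <- c(stack, v)
        }
      }
    }
  }
  dk <- apply(d + diag(Inf, n), 1, function(r) sort(r)[k_local])
  relax <- outer(dk, dk, pmin)
  keep <- d < maxlink + relax & sim > 0
  in_mst <- matrix(FALSE, n, n)
  in_mst[mst_el] <- TRUE
  in_mst <- in_mst | t(in_mst)
  keep <- (keep | in_mst)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  ij <- which(keep, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[ij[, 1]], to = nodes[ij[, 2]],
               weight = sim[ij],
               provenance = ifelse(in_mst[ij], "MST", "relaxation"),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  g
}

#' Edge list of a sparse graph as a tibble
#'
#' @param graph an [rmst_sparsify()] graph.
#' @return Tibble `node_a`, `node_b`, `weight`, `provenance`.
#' @export
graph_edge_table <- function(graph) {
  el <- igraph::as_edgelist(graph)
  tibble::tibble(node_a = el[, 1], node_b = el[, 2],
                 weight = igraph::E(graph)$weight,
                 provenance = igraph::E(graph)$provenance)
}
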