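# Independent oracles used across tests. These reimplement the checked
# quantities by the most transparent route available (enumeration, double
# loops, per-admission scanning) and never call the code paths they verify.

# --- set partitions ---------------------------------------------------------

# All set partitions of n items as a matrix (one row per partition,
# membership labels 1..k), via restricted growth strings.
all_set_partitions <- function(n) {
  res <- list()
  rec <- function(i, labels, maxl) {
    if (i > n) {
      res[[length(res) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (l in seq_len(maxl + 1L)) {
      labels[i] <- l
      rec(i + 1L, labels, max(maxl, l))
    }
  }
  rec(1L, integer(n), 0L)
  do.call(rbind, res)
}

# Cache of same-community masks per n: one row per partition, n^2 columns of
# vec(outer(p, p, "==")). Stability of every partition for a matrix B is then
# the single product masks %*% as.vector(B).
partition_mask_cache <- new.env(parent = emptyenv())
partition_masks <- function(n) {
  key <- as.character(n)
  if (is.null(partition_mask_cache[[key]])) {
    parts <- all_set_partitions(n)
    masks <- t(apply(parts, 1, function(p) as.numeric(outer(p, p, "=="))))
    partition_mask_cache[[key]] <- list(parts = parts, masks = masks)
  }
  partition_mask_cache[[key]]
}

# Exhaustive optimum of sum_{same community} B_ij over all partitions.
brute_best_partition <- function(B) {
  n <- nrow(B)
  pm <- partition_masks(n)
  vals <- as.vector(pm$masks %*% as.vector(B))
  i <- which.max(vals)
  list(value = vals[i], membership = pm$parts[i, ])
}

# --- preprocessing reference ------------------------------------------------

# Per-admission reference for first-operative-day extraction: scans day
# offsets in increasing order and returns the countable codes of the first
# day that has any, applying the code rules with plain scalar logic.
reference_day_codes <- function(codes, rules) {
  codes <- codes[!substr(codes, 1, 1) %in% rules$excluded_prefixes]
  if (rules$lens_pair[1] %in% codes && rules$lens_pair[2] %in% codes) {
    codes <- c(setdiff(codes, rules$lens_pair), rules$lens_code)
  }
  codes[codes %in% rules$lower_gi] <- rules$lower_gi_code
  if (isTRUE(rules$dedup_same_day)) codes <- unique(codes)
  codes
}

reference_extract <- function(admissions, rules) {
  out <- list()
  for (aid in unique(admissions$admission_id)) {
    adm <- admissions[admissions$admission_id == aid, ]
    for (d in sort(unique(adm$day_offset))) {
      codes <- reference_day_codes(adm$opcs3[adm$day_offset == d], rules)
      if (length(codes)) {
        out[[length(out) + 1L]] <- data.frame(
          admission_id = aid, day_offset = d, opcs3 = sort(codes),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(out)) {
    return(data.frame(admission_id = character(), day_offset = integer(),
                      opcs3 = character()))
  }
  do.call(rbind, out)
}

# --- misc -------------------------------------------------------------------

# Random row-stochastic flow matrix with optional sparsity.
random_flow_matrix <- function(n_rows, n_cols, zero_prob = 0.3) {
  m <- matrix(runif(n_rows * n_cols), n_rows, n_cols)
  m[runif(n_rows * n_cols) < zero_prob] <- 0
  # guarantee a nonzero entry per row
  m[cbind(seq_len(n_rows), sample.int(n_cols, n_rows, replace = TRUE))] <-
    runif(n_rows, 0.5, 1)
  m <- m / rowSums(m)
  rownames(m) <- sprintf("L%02d", seq_len(n_rows))
  colnames(m) <- sprintf("S%02d", seq_len(n_cols))
  m
}

# Random connected-ish weighted adjacency with positive degrees.
random_adjacency <- function(n, edge_prob = 0.6) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  w <- ifelse(runif(sum(up)) < edge_prob, runif(sum(up), 0.2, 1), 0)
  A[up] <- w
  A <- A + t(A)
  for (i in seq_len(n)) {
    if (sum(A[i, ]) == 0) {
      j <- if (i == n) 1L else i + 1L
      A[i, j] <- A[j, i] <- runif(1, 0.2, 1)
    }
  }
  dimnames(A) <- list(sprintf("v%d", seq_len(n)), sprintf("v%d", seq_len(n)))
  A
}

# Small world + admissions fixture used by several module tests.
tiny_world <- function(seed = 1, lsoas = 5, sites = 2, ...) {
  generate_world(world_config(lsoas_per_subregion = lsoas,
                              sites_per_subregion = sites, ...),
                 seed = seed)
}

# Run the analysis chain (no risk stage) from admissions to scan input.
build_network_from_admissions <- function(world, admissions,
                                          rules = code_rules(),
                                          build_graph = TRUE) {
  ev0 <- extract_first_day_events(admissions, rules)
  vol <- table(ev0$site_code)
  registry <- merge_nearby_sites(world$sites,
                                 setNames(as.numeric(vol), names(vol)))
  ev <- apply_site_registry(ev0, registry)
  hvps <- identify_hvps(ev)
  providers <- regular_providers(ev, hvps)
  allowed <- unlist(lapply(names(providers$providers), function(cd) {
    paste(cd, providers$providers[[cd]])
  }))
  hvp_events <- ev[paste(ev$opcs3, ev$site_code) %in% allowed, ]
  flow <- build_flow_matrix(hvp_events, hvps, providers,
                            lsoa_codes = world$lsoas$lsoa_code)
  sim <- cosine_similarity(flow)
  graph <- if (build_graph) rmst_sparsify(sim) else NULL
  list(events = ev, hvp_events = hvp_events, registry = registry,
       hvps = hvps, providers = providers, flow = flow, sim = sim,
       graph = graph)
}

truth_vector <- function(world, level = c("subregion", "region")) {
  level <- match.arg(level)
  col <- paste0("truth_", level)
  setNames(as.integer(factor(world$lsoas[[col]])), world$lsoas$lsoa_code)
}
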