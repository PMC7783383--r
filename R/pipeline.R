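# End-to-end pipeline: configuration, file-based stages, orchestration.
#
# Every stage reads its inputs from and writes its outputs to the run
# directory, so running stages individually composes byte-for-byte into the
# monolithic run_pipeline(). Stage seeds are derived from the global seed by
# stage-name hashing; adding a stage never perturbs earlier streams.

#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full pipeline run. Every
#' parameter of every stage lives here; [read_pipeline_config()] builds the
#' same structure from a YAML file and rejects unknown keys.
#'
#' @param world a [world_config()].
#' @param n_patients number of synthetic patients.
#' @param rules a [code_rules()].
#' @param risk list: `charlson_map` (`"weighted17"`, `"unit14"` or a CSV
#'   path) and `lookback_days`.
#' @param network list: `k_local` (RMST relaxation neighbour) and `per_hvp`
#'   (per-procedure similarity averaging instead of the pooled matrix).
#' @param scan list: `n_grid`, `t_min`, `t_max`, `n_runs`, `min_plateau`,
#'   `vi_max`, `exclude_trivial`, `variant`.
#' @param analysis list: `denominator` (`"demand"` or `"mean"`) and
#'   `population_weighted_ems`.
#' @param seed global integer seed.
#' @return A named list of class `surgcomm_pipeline_config`.
#' @export
pipeline_config <- function(world = world_config(),
                            n_patients = 50000,
                            rules = code_rules(),
                            risk = list(),
                            network = list(),
                            scan = list(),
                            analysis = list(),
                            seed = 1) {
  defaults <- list(
    risk = list(charlson_map = "weighted17", lookback_days = 183),
    network = list(k_local = 1, per_hvp = FALSE),
    scan = list(n_grid = 40, t_min = 1e-2, t_max = 1e5, n_runs = 50,
                min_plateau = 4, vi_max = 0.05, exclude_trivial = TRUE,
                variant = "exp"),
    analysis = list(denominator = "demand", population_weighted_ems = FALSE))
  merge_section <- function(given, section) {
    bad <- setdiff(names(given), names(defaults[[section]]))
    if (length(bad)) {
      stop_input("unknown ", section, " config keys: ", paste(bad, collapse = ", "))
    }
    utils::modifyList(defaults[[section]], given)
  }
  if (!inherits(world, "surgcomm_world_config")) world <- do.call(world_config, world)
  if (!inherits(rules, "surgcomm_code_rules")) rules <- do.call(code_rules, rules)
  cfg <- list(world = world,
              n_patients = assert_positive_count(n_patients, "n_patients"),
              rules = rules,
              risk = merge_section(risk, "risk"),
              network = merge_section(network, "network"),
              scan = merge_section(scan, "scan"),
              analysis = merge_section(analysis, "analysis"),
              seed = as.integer(seed))
  stopifnot(cfg$scan$n_grid >= 2, cfg$scan$n_runs >= 1,
            cfg$network$k_local >= 1,
            cfg$analysis$denominator %in% c("demand", "mean"),
            cfg$scan$variant %in% c("exp", "linearised"))
  structure(cfg, class = "surgcomm_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain any subset of the sections accepted by
#' [pipeline_config()] (`world`, `n_patients`, `rules`, `risk`, `network`,
#' `scan`, `analysis`, `seed`); unknown keys anywhere raise an error.
#'
#' @param path path to a YAML file.
#' @return A `surgcomm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("world", "n_patients", "rules", "risk", "network", "scan",
               "analysis", "seed")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop_input("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$world)) {
    bad_w <- setdiff(names(raw$world), names(formals(world_config)))
    if (length(bad_w)) {
      stop_input("unknown world config keys: ", paste(bad_w, collapse = ", "))
    }
    if (!is.null(raw$world$comorbidity_prevalence)) {
      raw$world$comorbidity_prevalence <- unlist(raw$world$comorbidity_prevalence)
    }
  }
  if (!is.null(raw$rules)) {
    bad_r <- setdiff(names(raw$rules), names(formals(code_rules)))
    if (length(bad_r)) {
      stop_input("unknown rules config keys: ", paste(bad_r, collapse = ", "))
    }
  }
  do.call(pipeline_config, raw)
}

read_run_csv <- function(outdir, name, col_types = NULL) {
  path <- file.path(outdir, name)
  if (!file.exists(path)) {
    stop_input("missing pipeline file ", name, "; run the earlier stages first")
  }
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

write_run_csv <- function(x, outdir, name) {
  readr::write_csv(x, file.path(outdir, name), na = "")
  invisible(name)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from `outdir` (as written by the preceding
#' stages) and writes its outputs there, so stages can be run one at a time
#' or all at once via [run_pipeline()]. Stage seeds derive from `seed` and
#' the stage name.
#'
#' \describe{
#'   \item{simulate}{world + admissions -> `lsoas.csv`, `sites.csv`,
#'     `truth_labels.csv`, `catalog.csv`, `admissions.csv`}
#'   \item{preprocess}{first-day events, site merging, HVPs, providers ->
#'     `events.csv`, `site_registry.csv`, `merged_sites.csv`,
#'     `hvp_table.csv`, `provider_sets.csv`}
#'   \item{risk}{Charlson + risk class -> `events_risk.csv`}
#'   \item{network}{flow matrix, distances, similarity, RMST ->
#'     `hvp_events.csv`, `distance_summary.csv`, `network_edges.csv`,
#'     `excluded_lsoas.csv`}
#'   \item{detect}{Markov-stability scan -> `scan.csv`,
#'     `partition_<i>_k<k>.csv`, `selection.json`}
#'   \item{report}{community reports, EMS, GeoJSON ->
#'     `community_report_<i>.csv`, `ems_<i>.csv`, `summary.json`,
#'     `lsoa_communities.geojson`}
#' }
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if missing).
#' @param seed global seed; defaults to the configured one.
#' @return Invisibly, the character vector of files written.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(config, outdir, seed = config$seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  world <- generate_world(config$world, seed = derive_seed(seed, "simulate"))
  admissions <- generate_admissions(world, config$n_patients,
                                    seed = derive_seed(seed, "simulate"))
  files <- c(
    write_run_csv(world$lsoas[, c("lsoa_code", "lat", "lon", "population",
                                  "admin_region")], outdir, "lsoas.csv"),
    write_run_csv(world$lsoas[, c("lsoa_code", "truth_subregion",
                                  "truth_region")], outdir, "truth_labels.csv"),
    write_run_csv(world$sites, outdir, "sites.csv"),
    write_run_csv(world$catalog, outdir, "catalog.csv"),
    write_run_csv(admissions, outdir, "admissions.csv"))
  invisible(files)
}

admissions_col_types <- readr::cols(
  admission_id = "c", patient_id = "c", lsoa_code = "c", site_code = "c",
  age = "i", admission_date = readr::col_date(), day_offset = "i",
  opcs3 = "c", comorbidities = "c")

#' @rdname pipeline-stages
#' @export
stage_preprocess <- function(config, outdir, seed = config$seed) {
  admissions <- read_run_csv(outdir, "admissions.csv", admissions_col_types)
  sites <- read_run_csv(outdir, "sites.csv")
  events0 <- extract_first_day_events(admissions, config$rules)
  volumes <- table(events0$site_code)
  registry <- merge_nearby_sites(sites, setNames(as.numeric(volumes),
                                                 names(volumes)))
  events <- apply_site_registry(events0, registry)
  hvps <- identify_hvps(events)
  providers <- regular_providers(events, hvps)
  hvp_tab <- hvps$table
  hvp_tab$selected <- hvp_tab$opcs3 %in% hvps$codes
  files <- c(
    write_run_csv(events, outdir, "events.csv"),
    write_run_csv(tibble::tibble(raw_site_code = names(registry$map),
                                 merged_site_code = unname(registry$map)),
                  outdir, "site_registry.csv"),
    write_run_csv(registry$sites, outdir, "merged_sites.csv"),
    write_run_csv(hvp_tab, outdir, "hvp_table.csv"),
    write_run_csv(providers$table, outdir, "provider_sets.csv"))
  invisible(files)
}

events_col_types <- readr::cols(
  patient_id = "c", admission_id = "c", opcs3 = "c", lsoa_code = "c",
  site_code = "c", age = "i", operative_date = readr::col_date(),
  .default = readr::col_guess())

read_provider_set <- function(outdir) {
  tab <- read_run_csv(outdir, "provider_sets.csv")
  hvp_tab <- read_run_csv(outdir, "hvp_table.csv")
  codes <- hvp_tab$opcs3[hvp_tab$selected]
  sel <- tab[tab$selected, ]
  providers <- lapply(split(sel$site_code, sel$opcs3), identity)
  structure(list(providers = providers[codes[codes %in% names(providers)]],
                 table = tab, share = 0.99),
            class = "surgcomm_provider_set")
}

read_hvp_set <- function(outdir) {
  tab <- read_run_csv(outdir, "hvp_table.csv")
  codes <- tab$opcs3[tab$selected]
  structure(list(codes = codes, cut_share = max(tab$cum_share[tab$selected]),
                 table = tab[, c("opcs3", "volume", "cum_share")]),
            class = "surgcomm_hvp_set")
}

#' @rdname pipeline-stages
#' @export
stage_risk <- function(config, outdir, seed = config$seed) {
  events <- read_run_csv(outdir, "events.csv", events_col_types)
  admissions <- read_run_csv(outdir, "admissions.csv", admissions_col_types)
  map <- load_charlson_map(config$risk$charlson_map)
  events <- add_risk(events, admissions, map,
                     lookback_days = config$risk$lookback_days)
  invisible(write_run_csv(events, outdir, "events_risk.csv"))
}

#' @rdname pipeline-stages
#' @export
stage_network <- function(config, outdir, seed = config$seed) {
  events <- read_run_csv(outdir, "events_risk.csv", events_col_types)
  lsoas <- read_run_csv(outdir, "lsoas.csv")
  merged_sites <- read_run_csv(outdir, "merged_sites.csv")
  hvps <- read_hvp_set(outdir)
  providers <- read_provider_set(outdir)
  allowed <- unlist(lapply(names(providers$providers), function(code) {
    paste(code, providers$providers[[code]])
  }))
  hvp_events <- events[paste(events$opcs3, events$site_code) %in% allowed, ,
                       drop = FALSE]
  dist_sum <- distance_travelled_summary(hvp_events, lsoas, merged_sites)
  flow <- build_flow_matrix(hvp_events, hvps, providers,
                            lsoa_codes = lsoas$lsoa_code,
                            per_hvp = isTRUE(config$network$per_hvp))
  sim <- cosine_similarity(flow)
  graph <- rmst_sparsify(sim, k_local = config$network$k_local)
  excl <- if (is.list(flow) && !is.matrix(flow)) {
    setdiff(lsoas$lsoa_code, rownames(sim))
  } else {
    attr(flow, "excluded_lsoas")
  }
  files <- c(
    write_run_csv(hvp_events, outdir, "hvp_events.csv"),
    write_run_csv(dist_sum$per_procedure, outdir, "distance_summary.csv"),
    write_run_csv(graph_edge_table(graph), outdir, "network_edges.csv"),
    write_run_csv(tibble::tibble(lsoa_code = excl), outdir,
                  "excluded_lsoas.csv"))
  invisible(files)
}

read_network_graph <- function(outdir) {
  edges <- read_run_csv(outdir, "network_edges.csv")
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  igraph::graph_from_data_frame(
    data.frame(from = edges$node_a, to = edges$node_b,
               weight = edges$weight, provenance = edges$provenance),
    directed = FALSE, vertices = data.frame(name = nodes))
}

#' @rdname pipeline-stages
#' @export
stage_detect <- function(config, outdir, seed = config$seed) {
  graph <- read_network_graph(outdir)
  sc <- config$scan
  scan <- scan_and_select(
    graph,
    t_grid = default_t_grid(sc$n_grid, sc$t_min, sc$t_max),
    criteria = selection_criteria(sc$min_plateau, sc$vi_max,
                                  sc$exclude_trivial),
    n_runs = sc$n_runs, seed = derive_seed(seed, "detect"),
    variant = sc$variant)
  if (!length(scan$robust)) {
    warning("no robust partition found under the selection criteria",
            call. = FALSE)
  }
  files <- write_run_csv(scan$table, outdir, "scan.csv")
  for (i in seq_along(scan$robust)) {
    p <- scan$robust[[i]]
    files <- c(files, write_run_csv(
      tibble::tibble(lsoa_code = names(p$membership),
                     community = unname(p$membership)),
      outdir, sprintf("partition_%d_k%d.csv", i, p$n_communities)))
  }
  jsonlite::write_json(
    list(plateaus = scan$plateaus,
         robust = lapply(scan$robust, function(p) {
           list(t = p$t, n_communities = p$n_communities,
                stability = p$stability)
         })),
    file.path(outdir, "selection.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, "selection.json"))
}

#' @rdname pipeline-stages
#' @export
stage_report <- function(config, outdir, seed = config$seed) {
  lsoas <- read_run_csv(outdir, "lsoas.csv")
  merged_sites <- read_run_csv(outdir, "merged_sites.csv")
  hvp_events <- read_run_csv(outdir, "hvp_events.csv", events_col_types)
  part_files <- sort(list.files(outdir, pattern = "^partition_\\d+_k\\d+\\.csv$"))
  files <- character()
  summaries <- list()
  geo_props <- tibble::tibble(lsoa_code = lsoas$lsoa_code)
  for (pf in part_files) {
    i <- as.integer(sub("^partition_(\\d+)_k\\d+\\.csv$", "\\1", pf))
    ptab <- read_run_csv(outdir, pf)
    membership <- setNames(ptab$community, ptab$lsoa_code)
    full <- attach_missing_lsoas(membership, lsoas)
    site_comm <- assign_sites_to_communities(full, lsoas, merged_sites)
    rep_ <- community_summary(full, hvp_events, site_comm,
                              denominator = config$analysis$denominator)
    ems <- equivalent_market_size(lsoas, full,
                                  config$analysis$population_weighted_ems)
    files <- c(files,
               write_run_csv(rep_$table, outdir,
                             sprintf("community_report_%d.csv", i)),
               write_run_csv(ems, outdir, sprintf("ems_%d.csv", i)))
    summaries[[sprintf("partition_%d", i)]] <- c(
      rep_$summary, list(median_ems = median(ems$ems)))
    geo_props[[sprintf("community_%d", i)]] <-
      unname(full[lsoas$lsoa_code])
  }
  jsonlite::write_json(summaries, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_lsoa_geojson(lsoas, geo_props,
                     file.path(outdir, "lsoa_communities.geojson"))
  invisible(c(files, "summary.json", "lsoa_communities.geojson"))
}

# GeoJSON point collection of LSOA centroids tagged with community labels.
write_lsoa_geojson <- function(lsoas, props, path) {
  features <- lapply(seq_len(nrow(lsoas)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(lsoas$lon[i], lsoas$lat[i])),
         properties = as.list(props[i, ]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 8)
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, risk, network, detect and report in order
#' on one run directory, then writes `manifest.json` recording the
#' configuration, the seeds and an MD5 digest of every output file. The run
#' is a pure function of `(config, seed)`: repeating it reproduces every
#' file byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if missing).
#' @param seed global seed; defaults to the configured one.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, outdir, seed = config$seed) {
  stopifnot(inherits(config, "surgcomm_pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop_input("cannot create output directory ", outdir)
  stages <- list(simulate = stage_simulate, preprocess = stage_preprocess,
                 risk = stage_risk, network = stage_network,
                 detect = stage_detect, report = stage_report)
  for (nm in names(stages)) {
    message("[", nm, "] running")
    tryCatch(stages[[nm]](config, outdir, seed = seed),
             error = function(e) {
               stop_input("stage `", nm, "` failed: ", conditionMessage(e))
             })
  }
  out_files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    package = "surgcomm",
    seed = seed,
    stage_seeds = lapply(setNames(nm = names(stages)),
                         function(nm) derive_seed(seed, nm)),
    config = unclass_config(config),
    files = as.list(tools::md5sum(file.path(outdir, sort(out_files)))))
  names(manifest$files) <- sort(out_files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$world <- unclass(cfg$world)
  cfg$rules <- unclass(cfg$rules)
  cfg$world$comorbidity_prevalence <- as.list(cfg$world$comorbidity_prevalence)
  cfg
}
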