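# Synthetic HES-like world: hierarchical geography, sites and a procedure
# catalog with planted community structure.

#' Configuration for the synthetic world generator
#'
#' Returns the full generation configuration as a named list; any argument can
#' be overridden. Defaults define the package's reference study conditions:
#' two coarse regions of three subregions each, 25 LSOAs and 2 hospital sites
#' per subregion, gravity-model site choice with a 20 km decay length, a
#' within-subregion preference boost of 5 and a cross-region leakage mass of
#' 0.05.
#'
#' Geography is a planar grid: subregions are square blocks of
#' `subregion_size_deg` degrees, stacked vertically within a region, regions
#' placed side by side. LSOA centroids are uniform within their block. This
#' gives controllable contiguity without shapefiles. Administrative regions
#' (STP analogues) re-tile the map with the blocks shifted by
#' `admin_offset_frac` of a block in both axes, so they deliberately
#' misalign with the planted truth regions.
#'
#' @param n_regions,subregions_per_region,lsoas_per_subregion,sites_per_subregion
#'   positive integer counts defining the hierarchy.
#' @param lat_min,lon_min south-west corner of the bounding box (degrees).
#' @param subregion_size_deg side length of one subregion block (degrees).
#' @param duplicate_site_fraction fraction of base sites that receive a twin
#'   site placed under 1 km away (exercises site merging), in `[0, 1]`.
#' @param private_site_fraction fraction of sites flagged as private.
#' @param decay_lambda_km gravity decay length in km. The default (20) is
#'   commensurate with the subregion block spacing, so that a patient's
#'   choice mass on neighbouring same-region subregions (about 10 per cent)
#'   exceeds the cross-region leakage mass: that ordering is what makes the
#'   planted two-level hierarchy real rather than nominal.
#' @param within_subregion_boost multiplicative preference (> 1 means
#'   patients favour sites homed in their own subregion).
#' @param leakage total choice mass routed to sites outside the patient's
#'   coarse region; `NULL` disables the rescaling (pure gravity choice).
#' @param admin_offset_frac offset of the administrative tiling, as a
#'   fraction of a block.
#' @param n_countable_codes,zipf_s size and Zipf exponent of the countable
#'   procedure catalog; with the defaults (40 codes, s = 1.2) a handful of
#'   top codes cover about half of all volume, as in real elective activity.
#' @param age_mean,age_sd,age_min age distribution of patients (normal,
#'   truncated below at `age_min`).
#' @param comorbidity_prevalence named numeric vector of per-condition
#'   prevalences; names must be flags of the selected Charlson map.
#' @param age_comorbidity_correlation if `TRUE`, condition prevalence rises
#'   with age on the logit scale (slope `corr_strength` per age SD).
#' @param corr_strength logit slope used when the correlation switch is on.
#' @param multiday_fraction fraction of admissions that carry an extra
#'   countable procedure on day offset 1.
#' @param second_code_fraction fraction of admissions with a second countable
#'   code on the first operative day.
#' @param excluded_day0_fraction fraction of admissions with an
#'   excluded-family (U/Y/Z/X) code added on day 0.
#' @param lens_pair_prob probability that a lens-extraction (C71) admission
#'   also records a prosthetic-lens insertion (C75) the same day.
#' @param prior_admission_fraction fraction of patients with one extra
#'   non-index admission in the six months before surgery (exercises the
#'   Charlson lookback).
#' @param study_start,study_end ISO dates bounding admission dates.
#' @return A named list of class `surgcomm_world_config`.
#' @export
world_config <- function(n_regions = 2,
                         subregions_per_region = 3,
                         lsoas_per_subregion = 25,
                         sites_per_subregion = 2,
                         lat_min = 51.0,
                         lon_min = -2.0,
                         subregion_size_deg = 0.25,
                         duplicate_site_fraction = 0.25,
                         private_site_fraction = 0.1,
                         decay_lambda_km = 20,
                         within_subregion_boost = 5,
                         leakage = 0.05,
                         admin_offset_frac = 0.5,
                         n_countable_codes = 40,
                         zipf_s = 1.2,
                         age_mean = 61.4,
                         age_sd = 16.7,
                         age_min = 18,
                         comorbidity_prevalence = c(
                           diabetes = 0.12,
                           chronic_pulmonary_disease = 0.08,
                           congestive_heart_failure = 0.05,
                           malignancy = 0.05,
                           renal_disease = 0.04,
                           myocardial_infarction = 0.04,
                           cerebrovascular_disease = 0.03,
                           dementia = 0.02,
                           metastatic_solid_tumour = 0.01),
                         age_comorbidity_correlation = FALSE,
                         corr_strength = 1.0,
                         multiday_fraction = 0.10,
                         second_code_fraction = 0.15,
                         excluded_day0_fraction = 0.15,
                         lens_pair_prob = 0.8,
                         prior_admission_fraction = 0.2,
                         study_start = "2017-04-01",
                         study_end = "2018-03-31") {
  cfg <- as.list(environment())
  for (nm in c("n_regions", "subregions_per_region", "lsoas_per_subregion",
               "sites_per_subregion", "n_countable_codes")) {
    assert_positive_count(cfg[[nm]], nm)
  }
  for (nm in c("duplicate_site_fraction", "private_site_fraction",
               "multiday_fraction", "second_code_fraction",
               "excluded_day0_fraction", "lens_pair_prob",
               "prior_admission_fraction")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop_input("configuration error: `", nm, "` must lie in [0, 1]")
    }
  }
  if (!is.null(cfg$leakage) && (cfg$leakage < 0 || cfg$leakage >= 1)) {
    stop_input("configuration error: `leakage` must lie in [0, 1) or be NULL")
  }
  if (cfg$decay_lambda_km <= 0) stop_input("configuration error: `decay_lambda_km` must be > 0")
  if (cfg$within_subregion_boost < 1) {
    stop_input("configuration error: `within_subregion_boost` must be >= 1")
  }
  structure(cfg, class = "surgcomm_world_config")
}

# Default procedure catalog: countable Zipf-weighted codes plus the special
# families needed to exercise every preprocessing rule.
build_catalog <- function(config) {
  n <- config$n_countable_codes
  countable <- sprintf("P%02d", seq_len(n))
  special <- c("C71", "C75", "H20", "H22", "H23", "H25")
  family <- c(rep("countable", n),
              "lens_C71", "lens_C75", rep("lower_GI", 4))
  codes <- c(countable, special)
  # interleave the special codes among the top ranks so that lens and
  # lower-GI procedures are high-volume, echoing real elective case mix
  rank_order <- c("H20", "P01", "C71", "H22", "P02", "P03", "H23", "P04",
                  "C75", "H25")
  rest <- setdiff(codes, rank_order)
  ranked <- c(rank_order, rest)
  w <- 1 / seq_along(ranked)^config$zipf_s
  weights <- w[match(codes, ranked)]
  excluded <- c("U01", "U02", "Y01", "Y02", "Z01", "Z02", "X01", "X02")
  tibble::tibble(
    opcs3 = c(codes, excluded),
    family = c(family, paste0("excluded_", substr(excluded, 1, 1))),
    relative_volume = c(weights, rep(0.02, length(excluded))))
}

#' Generate a synthetic world of LSOAs, sites and truth labels
#'
#' Lays out the planted hierarchical geography described in [world_config()]:
#' LSOAs with population-weighted-centroid coordinates and populations,
#' hospital sites (a configurable fraction with a twin placed under 1 km
#' away), nested truth labels (subregion within coarse region), deliberately
#' offset administrative-region labels, and the procedure catalog. The output
#' is a pure function of `(config, seed)`.
#'
#' @param config a [world_config()].
#' @param seed integer seed.
#' @return A list of class `surgcomm_world`: `lsoas` (tibble `lsoa_code`,
#'   `lat`, `lon`, `population`, `admin_region`, `truth_subregion`,
#'   `truth_region`), `sites` (tibble `site_code`, `lat`, `lon`,
#'   `is_private`, `home_subregion`, `home_region`, `twin_of`), `catalog`,
#'   `config`, `seed`.
#' @export
generate_world <- function(config = world_config(), seed = 1) {
  if (!inherits(config, "surgcomm_world_config")) {
    config <- do.call(world_config, config)
  }
  with_seed(derive_seed(seed, "world"), {
    R <- config$n_regions
    S <- config$subregions_per_region
    sz <- config$subregion_size_deg
    blocks <- expand.grid(sub = seq_len(S), region = seq_len(R))
    blocks$truth_region <- sprintf("R%02d", blocks$region)
    blocks$truth_subregion <- sprintf("R%02d_S%02d", blocks$region, blocks$sub)
    blocks$lat0 <- config$lat_min + (blocks$sub - 1) * sz
    blocks$lon0 <- config$lon_min + (blocks$region - 1) * sz

    nl <- config$lsoas_per_subregion
    n_lsoa <- nrow(blocks) * nl
    bi <- rep(seq_len(nrow(blocks)), each = nl)
    margin <- 0.05 * sz
    lsoas <- tibble::tibble(
      lsoa_code = sprintf("E%07d", seq_len(n_lsoa)),
      lat = blocks$lat0[bi] + runif(n_lsoa, margin, sz - margin),
      lon = blocks$lon0[bi] + runif(n_lsoa, margin, sz - margin),
      population = pmax(300L, as.integer(round(rnorm(n_lsoa, 1704, 450)))),
      truth_subregion = blocks$truth_subregion[bi],
      truth_region = blocks$truth_region[bi])
    off <- config$admin_offset_frac * sz
    lsoas$admin_region <- sprintf(
      "STP%02d_%02d",
      floor((lsoas$lon - config$lon_min + off) / sz),
      floor((lsoas$lat - config$lat_min + off) / sz))

    ns <- config$sites_per_subregion
    n_site <- nrow(blocks) * ns
    si <- rep(seq_len(nrow(blocks)), each = ns)
    sites <- tibble::tibble(
      site_code = sprintf("S%03d", seq_len(n_site)),
      lat = blocks$lat0[si] + runif(n_site, 0.3 * sz, 0.7 * sz),
      lon = blocks$lon0[si] + runif(n_site, 0.3 * sz, 0.7 * sz),
      is_private = runif(n_site) < config$private_site_fraction,
      home_subregion = blocks$truth_subregion[si],
      home_region = blocks$truth_region[si],
      twin_of = NA_character_)

    n_twin <- round(config$duplicate_site_fraction * n_site)
    if (n_twin > 0) {
      base_idx <- sort(sample.int(n_site, n_twin))
      d_km <- runif(n_twin, 0.1, 0.9)
      bearing <- runif(n_twin, 0, 2 * pi)
      twin <- sites[base_idx, ]
      twin$twin_of <- twin$site_code
      twin$site_code <- paste0(twin$site_code, "B")
      twin$lat <- twin$lat + d_km * cos(bearing) / 110.574
      twin$lon <- twin$lon + d_km * sin(bearing) /
        (111.320 * cos(twin$lat * pi / 180))
      sites <- rbind(sites, twin)
    }

    structure(list(lsoas = lsoas, sites = sites,
                   catalog = build_catalog(config),
                   config = config, seed = seed),
              class = "surgcomm_world")
  })
}

#' @export
print.surgcomm_world <- function(x, ...) {
  cat("<surgcomm_world> ", nrow(x$lsoas), " LSOAs, ", nrow(x$sites),
      " sites (", sum(!is.na(x$sites$twin_of)), " twins), ",
      length(unique(x$lsoas$truth_region)), " regions x ",
      length(unique(x$lsoas$truth_subregion)), " subregions, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Site-choice probabilities for every LSOA
#'
#' Gravity-model choice: the probability that a patient resident in an LSOA
#' presents to a site is proportional to `exp(-d / lambda)` of the haversine
#' distance `d`, multiplied by `within_subregion_boost` when the site is
#' homed in the patient's subregion. When `leakage` is set, mass is rescaled
#' so that sites outside the LSOA's coarse region receive exactly that total
#' probability.
#'
#' @param world a [generate_world()] result.
#' @return Row-stochastic matrix, LSOAs by sites, with dimnames.
#' @export
site_choice_probs <- function(world) {
  cfg <- world$config
  d <- haversine_matrix(world$lsoas$lat, world$lsoas$lon,
                        world$sites$lat, world$sites$lon)
  w <- exp(-d / cfg$decay_lambda_km)
  same_sub <- outer(world$lsoas$truth_subregion, world$sites$home_subregion, "==")
  w <- w * ifelse(same_sub, cfg$within_subregion_boost, 1)
  if (!is.null(cfg$leakage)) {
    same_reg <- outer(world$lsoas$truth_region, world$sites$home_region, "==")
    w_in <- w * same_reg
    w_out <- w * !same_reg
    s_in <- rowSums(w_in)
    s_out <- rowSums(w_out)
    both <- s_in > 0 & s_out > 0
    w[both, ] <- (1 - cfg$leakage) * w_in[both, , drop = FALSE] / s_in[both] +
      cfg$leakage * w_out[both, , drop = FALSE] / s_out[both]
  }
  p <- w / rowSums(w)
  dimnames(p) <- list(world$lsoas$lsoa_code, world$sites$site_code)
  p
}

#' Sample treatment sites for residents of one LSOA
#'
#' Draws from the gravity-model choice distribution of [site_choice_probs()].
#' Uses the current RNG state; seed the caller for reproducibility.
#'
#' @param world a [generate_world()] result (must have at least one site).
#' @param lsoa_code LSOA of residence.
#' @param n number of draws.
#' @return Character vector of site codes.
#' @export
sample_site <- function(world, lsoa_code, n = 1) {
  p <- site_choice_probs(world)
  if (!lsoa_code %in% rownames(p)) stop_input("unknown LSOA ", lsoa_code)
  colnames(p)[sample.int(ncol(p), n, replace = TRUE, prob = p[lsoa_code, ])]
}
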