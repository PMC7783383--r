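# Describing partitions: site assignment, supply-demand balance, and the
# equivalent market size of administrative regions.

#' Attach LSOAs absent from the network to their nearest community
#'
#' LSOAs with no eligible events are excluded from the similarity network;
#' for complete reporting each is given the community of the nearest
#' included LSOA centroid (haversine; ties to the smaller LSOA code).
#'
#' @param membership named membership vector over included LSOAs.
#' @param lsoas LSOA table with `lsoa_code`, `lat`, `lon`.
#' @return Membership vector covering every LSOA in `lsoas`.
#' @export
attach_missing_lsoas <- function(membership, lsoas) {
  missing <- setdiff(lsoas$lsoa_code, names(membership))
  if (!length(missing)) return(membership)
  inc <- lsoas[lsoas$lsoa_code %in% names(membership), ]
  inc <- inc[order(inc$lsoa_code), ]
  mis <- lsoas[lsoas$lsoa_code %in% missing, ]
  d <- haversine_matrix(mis$lat, mis$lon, inc$lat, inc$lon)
  nearest <- apply(d, 1, which.min)  # ties: first index = smaller code
  extra <- setNames(membership[inc$lsoa_code[nearest]], mis$lsoa_code)
  c(membership, extra)
}

#' Assign merged sites to communities
#'
#' Communities are sets of LSOAs, so a site's community is proxied by the
#' community of the LSOA whose population-weighted centroid lies nearest to
#' the site (haversine; ties broken by the smaller LSOA code).
#'
#' @param membership membership vector covering every LSOA (see
#'   [attach_missing_lsoas()]).
#' @param lsoas LSOA table with `lsoa_code`, `lat`, `lon`.
#' @param registry a [merge_nearby_sites()] registry, or a data frame of
#'   merged sites with `site_code`, `lat`, `lon`.
#' @return Named vector, merged site code -> community label.
#' @export
assign_sites_to_communities <- function(membership, lsoas, registry) {
  sites <- if (is.data.frame(registry)) registry else registry$sites
  lsoas <- lsoas[lsoas$lsoa_code %in% names(membership), ]
  if (!nrow(lsoas)) stop_input("no LSOA with a community available")
  lsoas <- lsoas[order(lsoas$lsoa_code), ]
  d <- haversine_matrix(sites$lat, sites$lon, lsoas$lat, lsoas$lon)
  nearest <- apply(d, 1, which.min)
  setNames(unname(membership[lsoas$lsoa_code[nearest]]), sites$site_code)
}

#' Supply-demand summary of one partition
#'
#' Treats each community as a self-contained subdivision: demand is the
#' number of HVP events for residents of the community's LSOAs; supply is
#' the number of HVP events performed at sites assigned to the community.
#' The mismatch is the percentage difference between the two,
#' `100 * (supply - demand) / demand` by default (the denominator is
#' configurable to the supply-demand mean).
#'
#' @param membership full LSOA membership vector.
#' @param events HVP events at regular providers, with `lsoa_code` and
#'   merged `site_code`.
#' @param site_assignment [assign_sites_to_communities()] result.
#' @param denominator `"demand"` (default) or `"mean"`.
#' @return A list of class `surgcomm_community_report`: `table` (tibble
#'   `community`, `n_cases`, `n_sites`, `supply`, `demand`,
#'   `mismatch_pct`) and `summary` (medians and IQRs of cases and sites per
#'   community, and the median absolute mismatch).
#' @export
community_summary <- function(membership, events, site_assignment,
                              denominator = c("demand", "mean")) {
  denominator <- match.arg(denominator)
  ev_comm_res <- membership[events$lsoa_code]
  ev_comm_sup <- site_assignment[events$site_code]
  if (any(is.na(ev_comm_res))) stop_input("events reference LSOAs without a community")
  if (any(is.na(ev_comm_sup))) stop_input("events reference sites without a community")
  comms <- sort(unique(c(membership, site_assignment)))
  demand <- tabulate(match(ev_comm_res, comms), length(comms))
  supply <- tabulate(match(ev_comm_sup, comms), length(comms))
  n_sites <- tabulate(match(site_assignment, comms), length(comms))
  den <- switch(denominator, demand = demand, mean = (supply + demand) / 2)
  mismatch <- ifelse(den > 0, 100 * (supply - demand) / den, NA_real_)
  if (any(is.na(mismatch))) {
    warning("communities with zero demand: mismatch undefined", call. = FALSE)
  }
  tab <- tibble::tibble(community = comms, n_cases = demand,
                        n_sites = n_sites, supply = supply, demand = demand,
                        mismatch_pct = mismatch)
  iqr3 <- function(x) unname(quantile(x, c(0.25, 0.75), type = 7))
  structure(list(
    table = tab,
    summary = list(
      n_communities = length(comms),
      median_cases = median(tab$n_cases),
      iqr_cases = iqr3(tab$n_cases),
      median_sites = median(tab$n_sites),
      iqr_sites = iqr3(tab$n_sites),
      median_abs_mismatch = median(abs(tab$mismatch_pct), na.rm = TRUE)),
    denominator = denominator),
    class = "surgcomm_community_report")
}

#' Equivalent market size of administrative regions
#'
#' For administrative region `i`, with `s_ij` the proportion of its LSOAs in
#' community `j`, the equivalent market size is `EMS_i = 1 / sum_j s_ij^2`
#' -- the reciprocal Herfindahl-Hirschman index, interpretable as the
#' effective number of communities active in the region (1 when the region
#' sits wholly inside one community, up to the number of communities `N`).
#' A population-weighted variant uses resident population shares instead of
#' LSOA counts.
#'
#' @param lsoas LSOA table with `lsoa_code`, `admin_region` (and
#'   `population` if weighting).
#' @param membership full LSOA membership vector.
#' @param population_weighted weight shares by population instead of LSOA
#'   counts.
#' @return A tibble `admin_region`, `n_lsoas`, `ems`, with the share matrix
#'   in attribute `shares`.
#' @export
equivalent_market_size <- function(lsoas, membership,
                                   population_weighted = FALSE) {
  comm <- membership[lsoas$lsoa_code]
  if (any(is.na(comm))) stop_input("every LSOA needs a community label")
  w <- if (population_weighted) lsoas$population else rep(1, nrow(lsoas))
  regions <- sort(unique(lsoas$admin_region))
  comms <- sort(unique(comm))
  shares <- matrix(0, length(regions), length(comms),
                   dimnames = list(regions, as.character(comms)))
  totals <- rowsum(w, lsoas$admin_region)
  cross <- rowsum(
    matrix(w * outer(comm, comms, "=="), nrow = length(comm)),
    lsoas$admin_region)
  shares[rownames(cross), ] <- cross / as.vector(totals[rownames(cross), ])
  ems <- 1 / rowSums(shares^2)
  out <- tibble::tibble(admin_region = regions,
                        n_lsoas = as.integer(table(lsoas$admin_region)[regions]),
                        ems = unname(ems[regions]))
  attr(out, "shares") <- shares
  out
}
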