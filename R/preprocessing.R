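# Preprocessing: code rules, first-operative-day extraction, site merging,
# high-volume procedures and regular providers.

#' Procedure-code rules
#'
#' Bundles the filtering and grouping rules applied to each admission-day's
#' codes: removal of excluded code families (diagnostic imaging/testing `U`,
#' method `Y`, site `Z`, miscellaneous `X`), merging of a concurrent lens
#' extraction (C71) with prosthetic lens insertion (C75) into one procedure,
#' grouping of lower-GI endoscopy codes under a single code, and optional
#' collapsing of duplicate identical same-day codes (on by default, so that a
#' grouped endoscopy family cannot double-count one endoscopy).
#'
#' @param excluded_prefixes code-initial letters removed outright.
#' @param lens_pair the two codes merged when concurrent.
#' @param lens_code the merged code emitted for the pair.
#' @param lower_gi codes grouped into the lower-GI endoscopy family. Note
#'   that diagnostic upper-GI endoscopy is deliberately *not* in this family
#'   and passes through unchanged.
#' @param lower_gi_code the group code.
#' @param dedup_same_day collapse duplicate identical codes within one day
#'   (after grouping) to a single event.
#' @return A named list of class `surgcomm_code_rules`.
#' @export
code_rules <- function(excluded_prefixes = c("U", "Y", "Z", "X"),
                       lens_pair = c("C71", "C75"),
                       lens_code = "LENSX",
                       lower_gi = c("H20", "H22", "H23", "H25"),
                       lower_gi_code = "LGIEN",
                       dedup_same_day = TRUE) {
  stopifnot(length(lens_pair) == 2L, is.logical(dedup_same_day))
  structure(as.list(environment()), class = "surgcomm_code_rules")
}

#' Apply code rules to the codes of one admission-day
#'
#' Removes excluded-family codes, merges a concurrent C71+C75 pair into the
#' single merged code (the merge fires only when *both* appear; a lone member
#' passes through unchanged), and maps lower-GI family members to the group
#' code. No de-duplication happens here; see
#' [extract_first_day_events()].
#'
#' @param codes character vector of codes recorded on one day.
#' @param rules a [code_rules()].
#' @return Character vector of countable codes (possibly empty).
#' @export
#' @examples
#' apply_code_rules(c("C71", "C75", "Y01")) # one merged lens procedure
apply_code_rules <- function(codes, rules = code_rules()) {
  keep <- !substr(codes, 1, 1) %in% rules$excluded_prefixes
  codes <- codes[keep]
  if (all(rules$lens_pair %in% codes)) {
    codes <- c(codes[!codes %in% rules$lens_pair], rules$lens_code)
  }
  codes[codes %in% rules$lower_gi] <- rules$lower_gi_code
  codes
}

#' Extract countable procedure events on the first operative day
#'
#' For each admission, the first operative day is the smallest day offset
#' that carries at least one countable code once the code rules are applied
#' (excluded families are removed, so an excluded-only day cannot anchor the
#' operative day). Every countable code on that day becomes an event; all
#' later-day codes are dropped; admissions with no countable code anywhere
#' contribute nothing.
#'
#' @param admissions long table as produced by [generate_admissions()]: one
#'   row per admission-day-code with `admission_id`, `patient_id`,
#'   `lsoa_code`, `site_code`, `age`, `admission_date`, `day_offset`,
#'   `opcs3`.
#' @param rules a [code_rules()].
#' @return A tibble of events: `patient_id`, `admission_id`, `opcs3` (post
#'   merge/grouping), `lsoa_code`, `site_code` (raw; see
#'   [apply_site_registry()]), `age`, `operative_date`.
#' @export
extract_first_day_events <- function(admissions, rules = code_rules()) {
  if (nrow(admissions) == 0) {
    return(tibble::tibble(patient_id = character(), admission_id = character(),
                          opcs3 = character(), lsoa_code = character(),
                          site_code = character(), age = integer(),
                          operative_date = as.Date(character())))
  }
  if (any(is.na(admissions$day_offset)) || any(admissions$day_offset < 0)) {
    stop_input("day offsets must be non-negative integers")
  }
  a <- admissions
  a <- a[!substr(a$opcs3, 1, 1) %in% rules$excluded_prefixes, , drop = FALSE]
  if (nrow(a) == 0) return(extract_first_day_events(a[0, ], rules))

  day_key <- paste(a$admission_id, a$day_offset, sep = "\r")
  is_lens1 <- a$opcs3 == rules$lens_pair[1]
  is_lens2 <- a$opcs3 == rules$lens_pair[2]
  both <- (day_key %in% day_key[is_lens1]) & (day_key %in% day_key[is_lens2])
  lens_rows <- both & (is_lens1 | is_lens2)
  # within each day carrying both pair members, the first pair row becomes
  # the merged code and the remaining pair rows are dropped
  if (any(lens_rows)) {
    idx <- which(lens_rows)
    first_idx <- idx[!duplicated(day_key[idx])]
    a$opcs3[first_idx] <- rules$lens_code
    drop <- setdiff(idx, first_idx)
    if (length(drop)) {
      a <- a[-drop, , drop = FALSE]
      day_key <- paste(a$admission_id, a$day_offset, sep = "\r")
    }
  }
  a$opcs3[a$opcs3 %in% rules$lower_gi] <- rules$lower_gi_code
  if (isTRUE(rules$dedup_same_day)) {
    a <- a[!duplicated(paste(a$admission_id, a$day_offset, a$opcs3, sep = "\r")), ,
           drop = FALSE]
  }
  first_day <- tapply(a$day_offset, a$admission_id, min)
  a <- a[a$day_offset == unname(first_day[a$admission_id]), , drop = FALSE]
  tibble::tibble(
    patient_id = a$patient_id,
    admission_id = a$admission_id,
    opcs3 = a$opcs3,
    lsoa_code = a$lsoa_code,
    site_code = a$site_code,
    age = a$age,
    operative_date = as.Date(a$admission_date) + a$day_offset)
}

#' Merge hospital sites within a distance threshold
#'
#' Sites closer than `threshold_km` (haversine) are treated as one merged
#' site. Clusters are the single-linkage connected components of the
#' "closer than threshold" relation, so chains A-B-C merge even when A and C
#' are farther apart. Each cluster is represented by its highest-volume
#' member (ties broken by lexicographically smallest code), whose code and
#' coordinates stand for the merged site.
#'
#' @param sites data frame with `site_code`, `lat`, `lon`.
#' @param volumes named numeric vector of per-site volumes (sites absent from
#'   it count as volume 0).
#' @param threshold_km merging radius, default 1 km.
#' @return A list of class `surgcomm_site_registry`: `map` (named character,
#'   raw code -> merged code) and `sites` (tibble of merged representatives:
#'   `site_code`, `lat`, `lon`, `n_members`, `members`).
#' @export
merge_nearby_sites <- function(sites, volumes = NULL, threshold_km = 1.0) {
  stopifnot(threshold_km > 0)
  if (any(is.na(sites$lat)) || any(is.na(sites$lon))) {
    stop_input("site coordinates must not be missing")
  }
  n <- nrow(sites)
  vol <- setNames(rep(0, n), sites$site_code)
  if (!is.null(volumes)) vol[names(volumes)] <- volumes
  d <- haversine_matrix(sites$lat, sites$lon, sites$lat, sites$lon)
  adj <- d < threshold_km
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  rep_code <- vapply(split(seq_len(n), comp), function(ix) {
    codes <- sites$site_code[ix]
    codes[order(-vol[codes], codes)][1]
  }, character(1))
  map <- setNames(rep_code[as.character(comp)], sites$site_code)
  reps <- match(unname(map[!duplicated(map)]), sites$site_code)
  merged <- tibble::tibble(
    site_code = sites$site_code[reps],
    lat = sites$lat[reps],
    lon = sites$lon[reps],
    n_members = as.integer(table(map)[sites$site_code[reps]]),
    members = vapply(sites$site_code[reps], function(rc) {
      paste(sort(names(map)[map == rc]), collapse = ";")
    }, character(1)))
  merged <- merged[order(merged$site_code), ]
  structure(list(map = map, sites = merged), class = "surgcomm_site_registry")
}

#' Replace raw site codes with merged-site codes
#'
#' @param events events table with a `site_code` column of raw codes.
#' @param registry a [merge_nearby_sites()] registry.
#' @return `events` with `site_code` mapped through the registry.
#' @export
apply_site_registry <- function(events, registry) {
  unknown <- setdiff(unique(events$site_code), names(registry$map))
  if (length(unknown)) {
    stop_input("sites missing from registry: ", paste(unknown, collapse = ", "))
  }
  events$site_code <- unname(registry$map[events$site_code])
  events
}

#' Identify high-volume procedures
#'
#' Sorts procedure codes by descending event volume and selects the minimal
#' prefix whose cumulative share *strictly* exceeds half of all events.
#'
#' @param events events table with an `opcs3` column.
#' @return A list of class `surgcomm_hvp_set`: `codes` (the selected HVPs, in
#'   volume order), `cut_share` (their cumulative share) and `table` (tibble
#'   `opcs3`, `volume`, `cum_share` over all codes).
#' @export
identify_hvps <- function(events) {
  if (nrow(events) == 0) stop_input("no events: cannot identify HVPs")
  counts <- sort(table(events$opcs3), decreasing = TRUE)
  tab <- tibble::tibble(opcs3 = names(counts), volume = as.integer(counts))
  tab <- tab[order(-tab$volume, tab$opcs3), ]
  tab$cum_share <- cumsum(tab$volume) / sum(tab$volume)
  k <- which(tab$cum_share > 0.5)[1]
  structure(list(codes = tab$opcs3[seq_len(k)],
                 cut_share = tab$cum_share[k],
                 table = tab),
            class = "surgcomm_hvp_set")
}

#' Identify the regular providers of each high-volume procedure
#'
#' For each HVP, sites are ordered by descending volume of that procedure
#' (ties by site code) and the minimal prefix whose cumulative share reaches
#' 99% is selected; rarer providers are excluded.
#'
#' @param events events table (merged site codes) with `opcs3`, `site_code`.
#' @param hvps an [identify_hvps()] result.
#' @param share required cumulative provider share, default 0.99.
#' @return A list of class `surgcomm_provider_set`: `providers` (named list,
#'   HVP code -> character vector of provider site codes) and `table`
#'   (tibble `opcs3`, `site_code`, `volume`, `cum_share`, `selected`).
#' @export
regular_providers <- function(events, hvps, share = 0.99) {
  stopifnot(inherits(hvps, "surgcomm_hvp_set"), length(hvps$codes) > 0)
  tabs <- lapply(hvps$codes, function(code) {
    ev <- events[events$opcs3 == code, , drop = FALSE]
    if (nrow(ev) == 0) {
      warning("HVP ", code, " has zero events; excluded", call. = FALSE)
      return(NULL)
    }
    counts <- table(ev$site_code)
    t <- tibble::tibble(opcs3 = code, site_code = names(counts),
                        volume = as.integer(counts))
    t <- t[order(-t$volume, t$site_code), ]
    t$cum_share <- cumsum(t$volume) / sum(t$volume)
    k <- which(t$cum_share >= share - 1e-9)[1]
    t$selected <- seq_len(nrow(t)) <= k
    t
  })
  tab <- dplyr::bind_rows(tabs)
  providers <- lapply(split(tab[tab$selected, ], tab$opcs3[tab$selected]),
                      function(t) t$site_code)
  structure(list(providers = providers[hvps$codes[hvps$codes %in% names(providers)]],
                 table = tab, share = share),
            class = "surgcomm_provider_set")
}
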