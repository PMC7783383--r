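# Synthetic admissions: one long table, one row per admission-day-code.

#' Generate synthetic elective admissions
#'
#' Draws `n_patients` adult patients (age truncated-normal, mean/sd from the
#' configuration), assigns each a residence LSOA proportional to population
#' and a treatment site from the gravity-choice model, samples procedure
#' codes from the catalog weights, and layers on the structural quirks the
#' preprocessing stage must handle: extra countable codes on the first
#' operative day, procedures on later day offsets, excluded-family (U/Y/Z/X)
#' codes, same-day C71+C75 lens pairs, and prior admissions inside the
#' Charlson lookback window. Deterministic for fixed `(world, n_patients,
#' seed)`.
#'
#' @param world a [generate_world()] result.
#' @param n_patients number of patients; 0 returns an empty table.
#' @param seed integer seed.
#' @return A tibble with one row per admission-day-code: `admission_id`,
#'   `patient_id`, `lsoa_code`, `site_code`, `age`, `admission_date`,
#'   `day_offset`, `opcs3`, `comorbidities` (";"-joined flags, repeated on
#'   every row of the admission).
#' @export
generate_admissions <- function(world, n_patients, seed = 1) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || is.na(n_patients) ||
      n_patients < 0 || n_patients != round(n_patients)) {
    stop_input("configuration error: `n_patients` must be a non-negative integer")
  }
  cfg <- world$config
  empty <- tibble::tibble(
    admission_id = character(), patient_id = character(),
    lsoa_code = character(), site_code = character(), age = integer(),
    admission_date = as.Date(character()), day_offset = integer(),
    opcs3 = character(), comorbidities = character())
  if (n_patients == 0) return(empty)

  with_seed(derive_seed(seed, "admissions"), {
    np <- as.integer(n_patients)
    patients <- tibble::tibble(
      patient_id = sprintf("PT%07d", seq_len(np)),
      age = as.integer(round(qnorm(
        runif(np, pnorm(cfg$age_min, cfg$age_mean, cfg$age_sd), 1),
        cfg$age_mean, cfg$age_sd))),
      lsoa_code = sample(world$lsoas$lsoa_code, np, replace = TRUE,
                         prob = world$lsoas$population))
    # patient-level condition sets, optionally age-correlated on logit scale
    prev <- cfg$comorbidity_prevalence
    cond_mat <- vapply(names(prev), function(cn) {
      p <- prev[[cn]]
      if (isTRUE(cfg$age_comorbidity_correlation)) {
        z <- (patients$age - cfg$age_mean) / cfg$age_sd
        p <- plogis(qlogis(p) + cfg$corr_strength * z)
      }
      runif(np) < p
    }, logical(np))
    if (np == 1L) cond_mat <- matrix(cond_mat, nrow = 1,
                                     dimnames = list(NULL, names(prev)))
    patient_conditions <- apply(cond_mat, 1L, function(z) names(prev)[z],
                                simplify = FALSE)

    start <- as.Date(cfg$study_start)
    span <- as.integer(as.Date(cfg$study_end) - start)
    index <- tibble::tibble(
      patient_id = patients$patient_id,
      admission_date = start + sample.int(span + 1L, np, replace = TRUE) - 1L)
    has_prior <- runif(np) < cfg$prior_admission_fraction
    prior <- tibble::tibble(
      patient_id = patients$patient_id[has_prior],
      admission_date = index$admission_date[has_prior] -
        sample(10:170, sum(has_prior), replace = TRUE))
    index$is_index <- TRUE
    prior$is_index <- rep(FALSE, nrow(prior))
    adm <- rbind(index, prior)
    adm <- adm[order(adm$patient_id, adm$admission_date, !adm$is_index), ]
    na <- nrow(adm)
    adm$admission_id <- sprintf("ADM%07d", seq_len(na))
    pi_ <- match(adm$patient_id, patients$patient_id)
    adm$age <- patients$age[pi_]
    adm$lsoa_code <- patients$lsoa_code[pi_]
    # each admission records each of the patient's conditions with prob 0.7,
    # so the six-month union genuinely adds information
    adm$comorbidities <- vapply(seq_len(na), function(i) {
      cset <- patient_conditions[[pi_[i]]]
      paste(cset[runif(length(cset)) < 0.7], collapse = ";")
    }, character(1))

    # treatment site via gravity choice, grouped by LSOA for speed
    p <- site_choice_probs(world)
    adm$site_code <- NA_character_
    for (lc in unique(adm$lsoa_code)) {
      rows <- which(adm$lsoa_code == lc)
      adm$site_code[rows] <- colnames(p)[
        sample.int(ncol(p), length(rows), replace = TRUE, prob = p[lc, ])]
    }

    # procedure codes
    cat_main <- world$catalog[!startsWith(world$catalog$family, "excluded"), ]
    cat_excl <- world$catalog[startsWith(world$catalog$family, "excluded"), ]
    draw_main <- function(k) sample(cat_main$opcs3, k, replace = TRUE,
                                    prob = cat_main$relative_volume)
    rows <- list(tibble::tibble(admission_id = adm$admission_id,
                                day_offset = 0L, opcs3 = draw_main(na)))
    primary <- rows[[1]]$opcs3
    pair <- primary == "C71" & runif(na) < cfg$lens_pair_prob
    if (any(pair)) {
      rows <- c(rows, list(tibble::tibble(
        admission_id = adm$admission_id[pair], day_offset = 0L, opcs3 = "C75")))
    }
    second <- runif(na) < cfg$second_code_fraction
    if (any(second)) {
      rows <- c(rows, list(tibble::tibble(
        admission_id = adm$admission_id[second], day_offset = 0L,
        opcs3 = draw_main(sum(second)))))
    }
    excl <- runif(na) < cfg$excluded_day0_fraction
    if (any(excl)) {
      rows <- c(rows, list(tibble::tibble(
        admission_id = adm$admission_id[excl], day_offset = 0L,
        opcs3 = sample(cat_excl$opcs3, sum(excl), replace = TRUE))))
    }
    later <- runif(na) < cfg$multiday_fraction
    if (any(later)) {
      rows <- c(rows, list(tibble::tibble(
        admission_id = adm$admission_id[later], day_offset = 1L,
        opcs3 = draw_main(sum(later)))))
    }
    proc <- dplyr::bind_rows(rows)
    out <- dplyr::inner_join(
      proc,
      adm[, c("admission_id", "patient_id", "lsoa_code", "site_code", "age",
              "admission_date", "comorbidities")],
      by = "admission_id")
    out <- out[, c("admission_id", "patient_id", "lsoa_code", "site_code",
                   "age", "admission_date", "day_offset", "opcs3",
                   "comorbidities")]
    out <- out[order(out$admission_id, out$day_offset, out$opcs3), ]
    tibble::as_tibble(out)
  })
}
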