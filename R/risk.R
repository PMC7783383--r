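# Charlson comorbidity scoring and operative risk classification.

#' Load a Charlson condition-weight map
#'
#' A Charlson map is a data frame with columns `flag` (the diagnosis flag as
#' recorded on admissions), `condition` (the comorbidity it maps to; several
#' flags may map to one condition) and integer `weight` (>= 1). Two maps ship
#' with the package: `"weighted17"`, the classic 17-condition weighted index
#' (weights 1/2/3/6), and `"unit14"`, a 14-condition unit-weight variant.
#' Which modification a given study used should be chosen explicitly; both are
#' available so either convention can be reproduced.
#'
#' @param variant `"weighted17"` or `"unit14"`, or a path to a CSV with the
#'   three columns above.
#' @return A data frame with columns `flag`, `condition`, `weight`.
#' @export
load_charlson_map <- function(variant = c("weighted17", "unit14")) {
  path <- if (length(variant) == 1L && file.exists(variant) &&
              !variant %in% c("weighted17", "unit14")) {
    variant
  } else {
    variant <- match.arg(variant)
    system.file("extdata", paste0("charlson_", variant, ".csv"),
                package = "surgcomm", mustWork = TRUE)
  }
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("flag", "condition", "weight") %in% names(map))) {
    stop_input("Charlson map needs columns flag, condition, weight")
  }
  if (any(map$weight < 1)) stop_input("Charlson weights must be >= 1")
  if (anyDuplicated(map$flag)) stop_input("each flag must map to one condition")
  map
}

#' Charlson comorbidity score with a six-month lookback
#'
#' Scores one patient at one index admission: diagnosis flags are pooled over
#' the index admission and every other admission of the same patient dated
#' within `lookback_days` before (and including) the index date, mapped to
#' conditions, de-duplicated, and the distinct condition weights summed.
#' Flags absent from the map are ignored with a warning.
#'
#' @param patient_id patient identifier.
#' @param index_admission_id admission identifier of the index (operative)
#'   admission; must belong to `patient_id`.
#' @param admissions data frame with one row per admission: `admission_id`,
#'   `patient_id`, `admission_date` (Date or ISO string) and `comorbidities`
#'   (";"-separated flag string, possibly empty).
#' @param map Charlson map, see [load_charlson_map()].
#' @param lookback_days window length in days; the default 183 operationalises
#'   a six-month lookback, inclusive of the index date.
#' @return Integer score >= 0.
#' @export
charlson_score <- function(patient_id, index_admission_id, admissions,
                           map = load_charlson_map(), lookback_days = 183) {
  idx <- admissions[admissions$admission_id == index_admission_id, , drop = FALSE]
  if (nrow(idx) != 1L || idx$patient_id != patient_id) {
    stop_input("index admission not found for patient ", patient_id)
  }
  dates <- as.Date(admissions$admission_date)
  index_date <- as.Date(idx$admission_date)
  in_window <- admissions$patient_id == patient_id &
    dates >= index_date - lookback_days & dates <= index_date
  flags <- unique(unlist(split_flags(admissions$comorbidities[in_window])))
  score_flags(flags, map)
}

split_flags <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

score_flags <- function(flags, map) {
  flags <- flags[nzchar(flags)]
  unknown <- setdiff(flags, map$flag)
  if (length(unknown)) {
    warning("ignoring unknown diagnosis flags: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  cond <- unique(map$condition[match(intersect(flags, map$flag), map$flag)])
  as.integer(sum(map$weight[match(cond, map$condition)]))
}

#' Classify operative risk from age and Charlson score
#'
#' Three-by-three lookup over age bands \{<60, 60-74, 75+\} and Charlson bands
#' \{0, 1-2, 3+\}:
#'
#' | age \\ score | 0      | 1-2    | 3+     |
#' |-------------|--------|--------|--------|
#' | <60         | Low    | Low    | Medium |
#' | 60-74       | Low    | Medium | High   |
#' | 75+         | Medium | High   | High   |
#'
#' @param age age in whole years, >= 18 expected (any non-negative age is
#'   banded the same way).
#' @param charlson Charlson score, >= 0.
#' @return An ordered factor with levels `Low < Medium < High`, vectorised
#'   over the inputs.
#' @export
#' @examples
#' classify_risk(c(55, 65, 80), c(0, 2, 5))
classify_risk <- function(age, charlson) {
  if (any(!is.finite(age)) || any(age < 0)) stop_input("age must be non-negative")
  if (any(!is.finite(charlson)) || any(charlson < 0)) {
    stop_input("charlson must be non-negative")
  }
  grid <- matrix(c("Low",    "Low",    "Medium",
                   "Low",    "Medium", "High",
                   "Medium", "High",   "High"),
                 nrow = 3, byrow = TRUE)
  ai <- 1L + (age >= 60) + (age >= 75)
  ci <- 1L + (charlson >= 1) + (charlson >= 3)
  factor(grid[cbind(ai, ci)], levels = c("Low", "Medium", "High"), ordered = TRUE)
}

#' Append Charlson score and risk class to a table of procedure events
#'
#' Vectorised wrapper around [charlson_score()] and [classify_risk()]: every
#' event is scored from the diagnosis flags of its admission plus all other
#' admissions of the same patient inside the lookback window.
#'
#' @param events events table (one row per counted procedure) carrying
#'   `patient_id`, `admission_id`, `age`.
#' @param admissions per-admission table as for [charlson_score()].
#' @param map Charlson map.
#' @param lookback_days lookback window, default 183 days.
#' @return `events` with added integer `charlson` and ordered-factor
#'   `risk_class` columns.
#' @export
add_risk <- function(events, admissions, map = load_charlson_map(),
                     lookback_days = 183) {
  adm <- unique(admissions[, c("admission_id", "patient_id",
                               "admission_date", "comorbidities")])
  adm$admission_date <- as.Date(adm$admission_date)
  # all (index admission, prior admission) pairs of the same patient
  pairs <- dplyr::inner_join(
    adm[, c("admission_id", "patient_id", "admission_date")],
    adm[, c("patient_id", "admission_date", "comorbidities")],
    by = "patient_id", relationship = "many-to-many",
    suffix = c("", "_other"))
  pairs <- pairs[pairs$admission_date_other >= pairs$admission_date - lookback_days &
                 pairs$admission_date_other <= pairs$admission_date, , drop = FALSE]
  flag_sets <- lapply(
    split(pairs$comorbidities, pairs$admission_id),
    function(x) unique(unlist(split_flags(x))))
  scores <- vapply(flag_sets, score_flags, integer(1), map = map)
  events$charlson <- unname(scores[match(events$admission_id, names(scores))])
  events$charlson[is.na(events$charlson)] <- 0L
  events$risk_class <- classify_risk(events$age, events$charlson)
  events
}
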