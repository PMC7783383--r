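test_that("risk classification reproduces the full age-by-Charlson grid", {
  # band representatives and boundaries; expectation built from an
  # independent lookup written out cell by cell
  expected_cell <- function(age, ch) {
    if (age < 60) {
      if (ch == 0) "Low" else if (ch <= 2) "Low" else "Medium"
    } else if (age <= 74) {
      if (ch == 0) "Low" else if (ch <= 2) "Medium" else "High"
    } else {
      if (ch == 0) "Medium" else if (ch <= 2) "High" else "High"
    }
  }
  ages <- c(18, 40, 59, 60, 67, 74, 75, 80, 95)
  scores <- 0:5
  for (a in ages) {
    for (s in scores) {
      expect_identical(as.character(classify_risk(a, s)),
                       expected_cell(a, s),
                       label = sprintf("age %d, score %d", a, s))
    }
  }
  expect_error(classify_risk(-1, 0), "age")
  expect_error(classify_risk(50, -1), "charlson")
})

test_that("risk never decreases with older age band or higher Charlson band", {
  ages <- c(30, 65, 80)
  scores <- c(0, 1, 4)
  grid <- outer(ages, scores,
                function(a, s) as.character(classify_risk(a, s)))
  lv <- matrix(as.integer(factor(grid, levels = c("Low", "Medium", "High"))),
               nrow = length(ages))
  expect_true(all(apply(lv, 1, diff) >= 0))  # across score bands
  expect_true(all(apply(lv, 2, diff) >= 0))  # across age bands
})

make_admissions <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, as.data.frame))
}

test_that("Charlson score pools distinct conditions over the lookback window", {
  map <- load_charlson_map("weighted17")
  adm <- make_admissions(
    list(admission_id = "A1", patient_id = "P1",
         admission_date = "2018-01-01", comorbidities = ""),
    list(admission_id = "A0", patient_id = "P1",
         admission_date = "2017-12-01", comorbidities = "diabetes"),
    list(admission_id = "A9", patient_id = "P1",
         admission_date = "2017-11-01", comorbidities = "diabetes"))
  expect_identical(charlson_score("P1", "A1", adm[1, , drop = FALSE], map), 0L)
  # same condition in two prior admissions counts once
  expect_identical(charlson_score("P1", "A1", adm, map), 1L)
  # weights add over distinct conditions
  adm2 <- make_admissions(
    list(admission_id = "A1", patient_id = "P1",
         admission_date = "2018-01-01", comorbidities = "diabetes;renal_disease"))
  expect_identical(charlson_score("P1", "A1", adm2, map), 3L)
})

test_that("the lookback window is 183 days inclusive", {
  map <- load_charlson_map("weighted17")
  idx <- as.Date("2018-01-01")
  adm <- make_admissions(
    list(admission_id = "A1", patient_id = "P1",
         admission_date = as.character(idx), comorbidities = ""),
    list(admission_id = "Ain", patient_id = "P1",
         admission_date = as.character(idx - 183), comorbidities = "dementia"),
    list(admission_id = "Aout", patient_id = "P1",
         admission_date = as.character(idx - 184), comorbidities = "renal_disease"),
    list(admission_id = "Aother", patient_id = "P2",
         admission_date = as.character(idx), comorbidities = "malignancy"))
  expect_identical(charlson_score("P1", "A1", adm, map), 1L)
})

test_that("unknown flags are ignored with a warning; scores are monotone in flags", {
  map <- load_charlson_map("unit14")
  adm <- make_admissions(
    list(admission_id = "A1", patient_id = "P1",
         admission_date = "2018-01-01", comorbidities = "diabetes;notacondition"))
  expect_warning(s <- charlson_score("P1", "A1", adm, map), "unknown")
  expect_identical(s, 1L)
  # adding a flag never decreases the score
  flags <- c("diabetes", "dementia", "renal_disease", "malignancy")
  scores <- vapply(seq_along(flags), function(k) {
    a <- make_admissions(list(admission_id = "A1", patient_id = "P1",
                              admission_date = "2018-01-01",
                              comorbidities = paste(flags[seq_len(k)],
                                                    collapse = ";")))
    charlson_score("P1", "A1", a, map)
  }, integer(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("add_risk agrees with per-event charlson_score on synthetic data", {
  world <- tiny_world(seed = 5)
  adm_long <- generate_admissions(world, 120, seed = 5)
  events <- extract_first_day_events(adm_long)
  adm <- unique(adm_long[, c("admission_id", "patient_id", "admission_date",
                             "comorbidities")])
  map <- load_charlson_map("weighted17")
  ev <- add_risk(events, adm_long, map)
  pick <- seq(1, nrow(ev), by = 7)
  for (i in pick) {
    expect_identical(ev$charlson[i],
                     charlson_score(ev$patient_id[i], ev$admission_id[i],
                                    adm, map))
  }
  expect_identical(as.character(ev$risk_class),
                   as.character(classify_risk(ev$age, ev$charlson)))
})
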