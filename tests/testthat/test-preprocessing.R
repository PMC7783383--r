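test_that("code rules exclude, merge and group as specified", {
  r <- code_rules()
  expect_identical(apply_code_rules(c("C71", "C75", "Y01"), r), "LENSX")
  expect_identical(apply_code_rules("C71", r), "C71")
  expect_identical(apply_code_rules("C75", r), "C75")
  expect_identical(apply_code_rules(c("U01", "Y02", "Z01", "X01"), r),
                   character(0))
  expect_identical(apply_code_rules(c("H22", "H20"), r), c("LGIEN", "LGIEN"))
  # upper-GI endoscopy stays itself
  expect_identical(apply_code_rules("G45", r), "G45")
})

make_adm <- function(aid, day, codes) {
  data.frame(admission_id = aid, patient_id = paste0("p", aid),
             lsoa_code = "L1", site_code = "S1", age = 50L,
             admission_date = as.Date("2017-06-01"), day_offset = day,
             opcs3 = codes, stringsAsFactors = FALSE)
}

test_that("first operative day is the first day with a countable code", {
  r <- code_rules()
  # excluded-only day 0 cannot anchor the operative day
  adm <- rbind(make_adm("a1", 0L, "U01"), make_adm("a1", 1L, "P01"))
  ev <- extract_first_day_events(adm, r)
  expect_equal(nrow(ev), 1)
  expect_identical(ev$opcs3, "P01")
  expect_equal(ev$operative_date, as.Date("2017-06-02"))
  # all first-day codes count, later days are dropped
  adm2 <- rbind(make_adm("a2", 0L, c("A01", "A02")), make_adm("a2", 1L, "A03"))
  ev2 <- extract_first_day_events(adm2, r)
  expect_setequal(ev2$opcs3, c("A01", "A02"))
  # excluded-only admissions contribute nothing
  adm3 <- make_adm("a3", 0L, c("Y01", "Z02"))
  expect_equal(nrow(extract_first_day_events(adm3, r)), 0)
  # grouping then de-duplication collapses concurrent lower-GI endoscopies
  adm4 <- make_adm("a4", 0L, c("H22", "H20"))
  expect_identical(extract_first_day_events(adm4, r)$opcs3, "LGIEN")
  nodedup <- code_rules(dedup_same_day = FALSE)
  expect_identical(extract_first_day_events(adm4, nodedup)$opcs3,
                   c("LGIEN", "LGIEN"))
  expect_error(extract_first_day_events(make_adm("a5", -1L, "P01"), r),
               "non-negative")
})

test_that("event extraction matches the per-admission reference on 100 random admissions", {
  r <- code_rules()
  set.seed(21)
  pool <- c("P01", "P02", "P03", "A01", "C71", "C75", "H20", "H22", "H23",
            "U01", "Y01", "Z01", "X01", "G45")
  adm <- do.call(rbind, lapply(seq_len(100), function(i) {
    days <- sort(sample(0:2, sample(1:2, 1)))
    do.call(rbind, lapply(days, function(d) {
      make_adm(sprintf("r%03d", i), as.integer(d),
               sample(pool, sample(1:4, 1), replace = TRUE))
    }))
  }))
  got <- extract_first_day_events(adm, r)
  ref <- reference_extract(adm, r)
  got_sorted <- got[order(got$admission_id, got$opcs3), ]
  expect_equal(got_sorted$admission_id, ref$admission_id)
  expect_equal(got_sorted$opcs3, ref$opcs3)
  # no emitted event carries an excluded-family code
  expect_false(any(substr(got$opcs3, 1, 1) %in% r$excluded_prefixes))
})

km_north <- function(lat, km) lat + km / (6371 * pi / 180)

test_that("site merging is single-linkage with highest-volume representatives", {
  # chain: A-B 0.8 km, B-C 0.8 km, A-C 1.6 km -> one cluster
  sites <- data.frame(site_code = c("A", "B", "C"),
                      lat = c(51, km_north(51, 0.8), km_north(51, 1.6)),
                      lon = 0)
  reg <- merge_nearby_sites(sites, c(A = 5, B = 1, C = 2))
  expect_identical(unname(reg$map), rep("A", 3))
  # far-apart sites stay themselves
  sites2 <- data.frame(site_code = c("A", "B"), lat = c(51, 52), lon = 0)
  reg2 <- merge_nearby_sites(sites2, c(A = 1, B = 1))
  expect_identical(unname(reg2$map), c("A", "B"))
  # co-located pair maps to the higher-volume code
  sites3 <- data.frame(site_code = c("X", "Y"), lat = 51, lon = 0)
  reg3 <- merge_nearby_sites(sites3, c(X = 10, Y = 200))
  expect_identical(unname(reg3$map), c("Y", "Y"))
  # volume tie resolves to the lexicographically smaller code
  reg4 <- merge_nearby_sites(sites3, c(X = 7, Y = 7))
  expect_identical(unname(reg4$map), c("X", "X"))
  expect_error(merge_nearby_sites(data.frame(site_code = "A", lat = NA,
                                             lon = 0)),
               "missing")
})

test_that("site merging is idempotent", {
  w <- tiny_world(seed = 12, lsoas = 3, sites = 3,
                  duplicate_site_fraction = 0.5)
  reg <- merge_nearby_sites(w$sites)
  reg2 <- merge_nearby_sites(reg$sites)
  expect_identical(unname(reg2$map), reg$sites$site_code)
  expect_equal(reg2$sites$site_code, reg$sites$site_code)
})

events_from_volumes <- function(volumes, site = "S1") {
  data.frame(opcs3 = rep(names(volumes), volumes),
             site_code = site, lsoa_code = "L1")
}

test_that("HVPs are the minimal prefix strictly exceeding half of volume", {
  h <- identify_hvps(events_from_volumes(c(A = 40, B = 30, C = 20, D = 10)))
  expect_identical(h$codes, c("A", "B"))
  expect_equal(h$cut_share, 0.7)
  expect_identical(identify_hvps(events_from_volumes(c(A = 60, B = 40)))$codes,
                   "A")
  # exactly 50% is not "more than 50%": both codes are needed
  expect_identical(identify_hvps(events_from_volumes(c(A = 50, B = 50)))$codes,
                   c("A", "B"))
  expect_error(identify_hvps(data.frame(opcs3 = character(0))), "no events")
})

provider_events <- function(volumes, code = "A") {
  data.frame(opcs3 = code, site_code = rep(names(volumes), volumes),
             lsoa_code = "L1")
}

test_that("regular providers are the minimal prefix reaching 99%", {
  h <- structure(list(codes = "A", cut_share = 1,
                      table = tibble::tibble(opcs3 = "A", volume = 100L,
                                             cum_share = 1)),
                 class = "surgcomm_hvp_set")
  p <- regular_providers(provider_events(c(S1 = 90, S2 = 9, S3 = 1)), h)
  expect_identical(p$providers$A, c("S1", "S2"))
  p2 <- regular_providers(provider_events(c(S1 = 50)), h)
  expect_identical(p2$providers$A, "S1")
  # volume tie at the cut resolves by site code order
  p3 <- regular_providers(provider_events(c(S1 = 98, S2 = 1, S3 = 1)), h)
  expect_identical(p3$providers$A, c("S1", "S2"))
})

test_that("HVP and provider prefixes are minimal on random volume vectors", {
  set.seed(31)
  for (rep in seq_len(200)) {
    k <- sample(2:8, 1)
    vols <- setNames(sample(1:30, k, replace = TRUE),
                     sprintf("C%02d", seq_len(k)))
    h <- identify_hvps(events_from_volumes(vols))
    tab <- h$table
    sel <- cumsum(tab$volume)[length(h$codes)] / sum(tab$volume)
    expect_gt(sel, 0.5)
    if (length(h$codes) > 1) {
      expect_lte(cumsum(tab$volume)[length(h$codes) - 1] / sum(tab$volume),
                 0.5)
    }
    pv <- setNames(sample(1:30, k, replace = TRUE),
                   sprintf("S%02d", seq_len(k)))
    hA <- structure(list(codes = "A", cut_share = 1, table = NULL),
                    class = "surgcomm_hvp_set")
    p <- regular_providers(provider_events(pv), hA)
    ptab <- p$table
    m <- length(p$providers$A)
    expect_gte(ptab$cum_share[m], 0.99 - 1e-9)
    if (m > 1) expect_lt(ptab$cum_share[m - 1], 0.99)
  }
})
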