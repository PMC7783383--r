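test_that("world dimensions and labels follow the configuration exactly", {
  cfg <- world_config(n_regions = 2, subregions_per_region = 2,
                      lsoas_per_subregion = 10, sites_per_subregion = 2,
                      duplicate_site_fraction = 0)
  w <- generate_world(cfg, seed = 1)
  expect_equal(nrow(w$lsoas), 40)
  expect_equal(nrow(w$sites), 8)
  expect_false(anyDuplicated(w$lsoas$lsoa_code) > 0)
  expect_false(anyDuplicated(w$sites$site_code) > 0)
  # subregions nest exactly within coarse regions
  nest <- unique(w$lsoas[, c("truth_subregion", "truth_region")])
  expect_equal(nrow(nest), length(unique(w$lsoas$truth_subregion)))
  # coordinates inside the configured grid
  extent <- cfg$subregion_size_deg *
    c(cfg$subregions_per_region, cfg$n_regions)
  expect_true(all(w$lsoas$lat >= cfg$lat_min & w$lsoas$lat <= cfg$lat_min + extent[1]))
  expect_true(all(w$lsoas$lon >= cfg$lon_min & w$lsoas$lon <= cfg$lon_min + extent[2]))
  expect_true(all(w$lsoas$population > 0))
  expect_error(world_config(n_regions = 0), "configuration error")
  expect_error(world_config(duplicate_site_fraction = 2), "configuration error")
})

test_that("generation is deterministic in (config, seed)", {
  cfg <- world_config(lsoas_per_subregion = 4, sites_per_subregion = 1)
  w1 <- generate_world(cfg, seed = 9)
  w2 <- generate_world(cfg, seed = 9)
  expect_identical(w1, w2)
  a1 <- generate_admissions(w1, 200, seed = 4)
  a2 <- generate_admissions(w2, 200, seed = 4)
  expect_identical(a1, a2)
  w3 <- generate_world(cfg, seed = 10)
  expect_false(identical(w1$lsoas$lat, w3$lsoas$lat))
})

test_that("twin sites appear at the configured rate and within 1 km", {
  cfg <- world_config(n_regions = 2, subregions_per_region = 2,
                      lsoas_per_subregion = 5, sites_per_subregion = 2,
                      duplicate_site_fraction = 0.5)
  w <- generate_world(cfg, seed = 2)
  twins <- w$sites[!is.na(w$sites$twin_of), ]
  expect_equal(nrow(twins), 4)  # half of the 8 base sites
  base <- w$sites[match(twins$twin_of, w$sites$site_code), ]
  # haversine oracle from geosphere, same earth radius
  d <- geosphere::distHaversine(cbind(twins$lon, twins$lat),
                                cbind(base$lon, base$lat), r = 6371000) / 1000
  expect_true(all(d < 1))
})

test_that("a co-located site dominates choice as the decay length shrinks", {
  cfg <- world_config(n_regions = 1, subregions_per_region = 1,
                      lsoas_per_subregion = 3, sites_per_subregion = 3,
                      duplicate_site_fraction = 0, leakage = NULL,
                      decay_lambda_km = 0.01, within_subregion_boost = 1)
  w <- generate_world(cfg, seed = 3)
  # move one site onto the first LSOA centroid
  w$sites$lat[1] <- w$lsoas$lat[1]
  w$sites$lon[1] <- w$lsoas$lon[1]
  p <- site_choice_probs(w)
  expect_gt(p[1, 1], 0.999)
})

test_that("choice frequencies are uniform when gravity is flat", {
  cfg <- world_config(n_regions = 2, subregions_per_region = 1,
                      lsoas_per_subregion = 2, sites_per_subregion = 3,
                      duplicate_site_fraction = 0, leakage = NULL,
                      decay_lambda_km = 1e9, within_subregion_boost = 1)
  w <- generate_world(cfg, seed = 4)
  set.seed(42)
  draws <- sample_site(w, w$lsoas$lsoa_code[1], n = 10000)
  tab <- table(factor(draws, levels = w$sites$site_code))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("a subregion boost concentrates choices within the home subregion", {
  base_cfg <- list(n_regions = 2, subregions_per_region = 2,
                   lsoas_per_subregion = 3, sites_per_subregion = 2,
                   duplicate_site_fraction = 0, leakage = NULL,
                   decay_lambda_km = 50)
  w1 <- generate_world(do.call(world_config,
                               c(base_cfg, within_subregion_boost = 1)),
                       seed = 6)
  w5 <- generate_world(do.call(world_config,
                               c(base_cfg, within_subregion_boost = 8)),
                       seed = 6)
  home <- w1$lsoas$truth_subregion[1]
  frac_home <- function(w) {
    set.seed(99)
    draws <- sample_site(w, w$lsoas$lsoa_code[1], n = 10000)
    mean(w$sites$home_subregion[match(draws, w$sites$site_code)] == home)
  }
  expect_gt(frac_home(w5), frac_home(w1))
})

test_that("leakage controls the cross-region choice mass", {
  cfg <- world_config(lsoas_per_subregion = 2, leakage = 0.05)
  w <- generate_world(cfg, seed = 7)
  p <- site_choice_probs(w)
  cross <- outer(w$lsoas$truth_region, w$sites$home_region, "!=")
  expect_equal(unname(rowSums(p * cross)), rep(0.05, nrow(p)),
               tolerance = 1e-12)
})

test_that("admissions respect the configured structure", {
  w <- tiny_world(seed = 8)
  expect_equal(nrow(generate_admissions(w, 0, seed = 1)), 0)
  expect_error(generate_admissions(w, -1), "configuration error")

  adm <- generate_admissions(w, 400, seed = 8)
  expect_true(all(adm$age >= 18))
  expect_true(all(adm$day_offset >= 0))
  expect_true(all(adm$admission_date >= as.Date(w$config$study_start) - 200))
  # with multi-day and excluded fractions at zero and a pure catalog, every
  # admission is a single day-0 record
  cfg0 <- world_config(lsoas_per_subregion = 3, multiday_fraction = 0,
                       excluded_day0_fraction = 0, second_code_fraction = 0,
                       lens_pair_prob = 0, prior_admission_fraction = 0)
  w0 <- generate_world(cfg0, seed = 9)
  adm0 <- generate_admissions(w0, 200, seed = 9)
  expect_true(all(adm0$day_offset == 0))
  expect_equal(nrow(adm0), 200)
  expect_equal(length(unique(adm0$admission_id)), 200)
})
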