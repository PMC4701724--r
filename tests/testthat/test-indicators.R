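test_that("indicator registry has exactly 22 entries with 6 PP ratios", {
  reg <- indicator_registry()
  expect_equal(nrow(reg), 22L)
  expect_false(anyDuplicated(reg$code) > 0)
  expect_equal(sum(reg$needs_pp), 6L)
})

test_that("ratio and weighted-mean indicators match hand arithmetic", {
  ds <- make_mini_dataset(dem_bio = 10, pel_bio = 5, ben_bio = 20,
                          whale_bio = 2, dem_catch = 3, pel_catch = 2,
                          pp = 100, dem_tl = 4, pel_tl = 3,
                          dem_price = 10, pel_price = 1)
  dp <- compute_indicator("demersal_pelagic_ratio", ds, "observed")
  expect_true(all(dp$values == 2))

  # MTL of the catch: (4*3 + 3*2) / 5 = 3.6
  mtl_c <- compute_indicator("mtl_catch", ds, "observed")
  expect_true(all(abs(mtl_c$values - 3.6) < 1e-12))

  # value: 10*3 + 1*2 = 32
  val <- compute_indicator("value", ds, "observed")
  expect_true(all(val$values == 32))

  # catch/biomass: (3+2) / (10+5+20+2)
  cb <- compute_indicator("catch_biomass", ds, "observed")
  expect_true(all(abs(cb$values - 5 / 37) < 1e-12))

  tot <- compute_indicator("total_biomass", ds, "observed")
  expect_true(all(tot$values == 37))
  expect_equal(tot$units, "t")
  expect_equal(cb$units, "dimensionless")
})

test_that("spec worked examples: equal catches at TL 4 and 3 average to 3.5", {
  ds <- make_mini_dataset(dem_catch = 10, pel_catch = 10,
                          dem_tl = 4.0, pel_tl = 3.0,
                          dem_price = 10, pel_price = 1)
  mtl <- compute_indicator("mtl_catch", ds, "observed")
  expect_true(all(abs(mtl$values - 3.5) < 1e-12))
  # value with catches (2, 3) and prices (10, 1): the spec's 23
  ds2 <- make_mini_dataset(dem_catch = 2, pel_catch = 3,
                           dem_price = 10, pel_price = 1)
  expect_true(all(compute_indicator("value", ds2, "observed")$values == 23))
  # catch 5, biomass 50
  ds3 <- make_mini_dataset(dem_bio = 20, pel_bio = 20, ben_bio = 8,
                           whale_bio = 2, dem_catch = 2, pel_catch = 3)
  expect_true(all(abs(compute_indicator("catch_biomass", ds3,
                                        "observed")$values - 0.1) < 1e-12))
})

test_that("equal guild biomasses give a demersal/pelagic ratio of one", {
  ds <- make_mini_dataset(dem_bio = 8, pel_bio = 8)
  expect_true(all(compute_indicator("demersal_pelagic_ratio", ds,
                                    "observed")$values == 1))
})

test_that("MTL of a one-species system equals that species' trophic level", {
  years <- 2000:2009
  md <- data.frame(group_id = "ONE", name = "one", guild = "demersal_fish",
                   is_fish = TRUE, is_commercial = TRUE, is_tep = FALSE,
                   trophic_level = 4.2, price_per_ton = 1)
  bio <- data.frame(group_id = "ONE", source = "observed", year = years,
                    value = seq(10, 19))
  lan <- data.frame(group_id = "ONE", source = "observed", year = years,
                    value = 1)
  ds <- ecosystem_dataset(bio, lan, metadata = md)
  expect_true(all(compute_indicator("mtl_system", ds, "observed")$values == 4.2))
})

test_that("proportion_overfished matches the depletion example and bounds", {
  years <- 2000:2009
  md <- data.frame(
    group_id = paste0("C", 1:4), name = paste0("c", 1:4),
    guild = "demersal_fish", is_fish = TRUE, is_commercial = TRUE,
    is_tep = FALSE, trophic_level = 4, price_per_ton = 1)
  rel_end <- c(0.1, 0.5, 0.15, 0.9)
  bio <- do.call(rbind, lapply(1:4, function(i) {
    v <- c(rep(1, 7), rep(rel_end[i], 3))  # max = 1, final window = rel_end
    data.frame(group_id = paste0("C", i), source = "observed",
               year = years, value = v)
  }))
  lan <- bio[bio$year == 2000, ]
  ds <- ecosystem_dataset(bio, lan, metadata = md)
  expect_equal(proportion_overfished(ds, "observed",
                                     depletion_threshold = 0.2,
                                     end_window = 3), 0.5)
  # all flat at the maximum: nothing depleted
  flat <- bio; flat$value <- 1
  ds_flat <- ecosystem_dataset(flat, lan, metadata = md)
  expect_equal(proportion_overfished(ds_flat, "observed"), 0)
  # threshold 1 with every series below its maximum in the window
  expect_equal(proportion_overfished(ds, "observed",
                                     depletion_threshold = 1,
                                     end_window = 3), 1)
  # no commercial groups is an error
  md_nc <- md; md_nc$is_commercial <- FALSE
  ds_nc <- ecosystem_dataset(bio, lan, metadata = md_nc)
  expect_error(proportion_overfished(ds_nc, "observed"), "commercial")
})

test_that("unknown indicator codes and missing denominators error", {
  ds <- make_mini_dataset()
  expect_error(compute_indicator("nope", ds, "observed"), "unknown indicator")
  zero_pp <- make_mini_dataset(pp = 0)
  expect_error(compute_indicator("catch_pp", zero_pp, "observed"),
               "denominator")
})

test_that("compute_all_indicators returns 22 entries; PP gaps are flagged", {
  eco <- generate_ecosystem(ecosystem_config(seed = 2, n_groups = 15))
  ind <- compute_all_indicators(eco$dataset, "observed")
  expect_length(ind, 22L)
  expect_named(ind, indicator_registry()$code)
  expect_equal(sum(vapply(ind, is_missing_indicator, logical(1))), 0L)

  no_pp <- eco$dataset
  no_pp$primary_production <- NULL
  ind2 <- compute_all_indicators(no_pp, "observed")
  missing <- vapply(ind2, is_missing_indicator, logical(1))
  expect_equal(sum(missing), 6L)
  expect_setequal(names(ind2)[missing],
                  indicator_registry()$code[indicator_registry()$needs_pp])
})

test_that("identical observed and modeled inputs give identical indicators", {
  eco <- generate_ecosystem(ecosystem_config(seed = 4, n_groups = 10))
  ds <- eco$dataset
  mirrored <- ds$biomass[ds$biomass$source == "observed", ]
  mirrored$source <- "modeled"
  ds$biomass <- rbind(ds$biomass[ds$biomass$source == "observed", ], mirrored)
  lan <- ds$landings[ds$landings$source == "observed", ]
  lan2 <- lan; lan2$source <- "modeled"
  ds$landings <- rbind(lan, lan2)
  pp <- ds$primary_production[ds$primary_production$source == "observed", ]
  pp2 <- pp; pp2$source <- "modeled"
  ds$primary_production <- rbind(pp, pp2)
  io <- compute_all_indicators(ds, "observed")
  im <- compute_all_indicators(ds, "modeled")
  for (code in names(io)) {
    if (is_missing_indicator(io[[code]])) next
    expect_identical(io[[code]]$values, im[[code]]$values, label = code)
    expect_identical(io[[code]]$years, im[[code]]$years, label = code)
  }
})

test_that("total biomass is additive over its components", {
  eco <- generate_ecosystem(ecosystem_config(seed = 6, n_groups = 12))
  ds <- eco$dataset
  tot <- compute_indicator("total_biomass", ds, "modeled")
  fish <- compute_indicator("fish_biomass", ds, "modeled")
  md <- ds$metadata
  nonfish_ids <- md$group_id[!md$is_fish]
  bio <- ds$biomass[ds$biomass$source == "modeled" &
                    ds$biomass$group_id %in% nonfish_ids, ]
  nonfish <- aggregate(value ~ year, bio, sum)
  yrs <- tot$years
  expect_true(all(yrs %in% fish$years), info = "aligned years")
  recon <- fish$values[match(yrs, fish$years)] +
    nonfish$value[match(yrs, nonfish$year)]
  expect_equal(tot$values, recon, tolerance = 1e-9)
})

test_that("ratio indicators are scale invariant; sums and value are not", {
  ds <- make_mini_dataset(dem_bio = 4, pel_bio = 3, ben_bio = 2,
                          whale_bio = 1, dem_catch = 1, pel_catch = 0.5)
  scaled <- ds
  for (nm in c("biomass", "landings")) scaled[[nm]]$value <- 3 * ds[[nm]]$value
  scaled$primary_production$value <- 3 * ds$primary_production$value
  for (code in c("demersal_pelagic_ratio", "catch_biomass", "mtl_catch",
                 "mtl_system", "catch_pp", "proportion_overfished")) {
    a <- compute_indicator(code, ds, "observed")
    b <- compute_indicator(code, scaled, "observed")
    expect_equal(a$values, b$values, tolerance = 1e-12, label = code)
  }
  expect_equal(compute_indicator("value", scaled, "observed")$values,
               3 * compute_indicator("value", ds, "observed")$values)
  expect_equal(compute_indicator("total_biomass", scaled, "observed")$values,
               3 * compute_indicator("total_biomass", ds, "observed")$values)
})

test_that("data onsets propagate into indicator year coverage", {
  eco <- generate_ecosystem(ecosystem_config(seed = 9, n_groups = 20))
  tot_obs <- compute_indicator("total_biomass", eco$dataset, "observed")
  # whale biomass only observed from 1990, so the observed total starts then
  expect_equal(min(tot_obs$years), 1990L)
  tot_mod <- compute_indicator("total_biomass", eco$dataset, "modeled")
  expect_equal(min(tot_mod$years), 1964L)
  bp <- compute_indicator("biomass_pp", eco$dataset, "observed")
  expect_true(min(bp$years) >= 1998L)
})
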