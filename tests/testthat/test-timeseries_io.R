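test_that("read_timeseries_csv constructs one series per (id, source)", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("series_id,category,source,year,value,units",
               "cod,biomass,observed,1964,10.5,t",
               "cod,biomass,observed,1965,11.25,t",
               "cod,biomass,modeled,1964,9.75,t",
               "cod,biomass,modeled,1965,10,t",
               "cod,biomass,modeled,1966,,t"), path)
  out <- read_timeseries_csv(path)
  expect_length(out, 2L)
  expect_equal(out[["cod.observed"]]$values, c(10.5, 11.25))
  expect_equal(out[["cod.observed"]]$years, c(1964L, 1965L))
  # the empty-value 1966 row is a gap, not an NA point
  expect_equal(out[["cod.modeled"]]$years, c(1964L, 1965L))
  expect_length(out[["cod.modeled"]]$values, 2L)
})

test_that("header-only file yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("series_id,category,source,year,value,units", path)
  expect_length(read_timeseries_csv(path), 0L)
})

test_that("duplicate and malformed rows are hard errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("series_id,category,source,year,value,units",
               "cod,biomass,observed,1990,1,t",
               "cod,biomass,observed,1990,2,t"), path)
  expect_error(read_timeseries_csv(path), "duplicate.*cod.*1990")

  writeLines(c("series_id,category,source,year,value,units",
               "cod,abundance,observed,1990,1,t"), path)
  expect_error(read_timeseries_csv(path), "unknown category")

  writeLines(c("series_id,category,source,year,value,units",
               "cod,biomass,simulated,1990,1,t"), path)
  expect_error(read_timeseries_csv(path), "unknown source")
})

test_that("series round trips losslessly through write/read", {
  s1 <- make_series(c(pi, exp(1), 1/3, 1e-7), id = "a")
  s2 <- make_series(c(5, 6, 7), id = "b", source = "modeled")
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries_csv(list(s1, s2), path)
  back <- read_timeseries_csv(path)
  expect_identical(back[["a.observed"]]$values, s1$values)
  expect_identical(back[["a.observed"]]$years, s1$years)
  expect_identical(back[["b.modeled"]]$values, s2$values)
})

test_that("eco_series enforces its invariants", {
  expect_error(eco_series("x", "biomass", "observed", c(1, 1), c(1, 2)),
               "strictly increasing")
  expect_error(eco_series("x", "biomass", "observed", c(2, 1), c(1, 2)),
               "strictly increasing")
  expect_error(eco_series("x", "biomass", "observed", c(1, NA), c(1, 2)),
               "years may not")
  expect_error(eco_series("x", "biomass", "observed", 1:3, 1:2),
               "equal length")
  # NA values within the recorded span are allowed
  s <- eco_series("x", "biomass", "observed", 1:3, c(1, NA, 3))
  expect_true(is.na(s$values[2]))
})

test_that("align_pair intersects non-missing years and clips to the period", {
  obs <- make_series(1:10, years = 1990:1999)
  mod <- make_series(11:21, years = 1995:2005, source = "modeled")
  p <- align_pair(obs, mod, eco_period("win", 1994, 2004))
  expect_equal(p$years, 1995:1999)
  expect_equal(p$n, 5L)
  expect_equal(p$obs, 6:10)
  expect_equal(p$mod, 11:15)

  full_o <- make_series(rnorm(41), years = 1964:2004)
  full_m <- make_series(rnorm(41), years = 1964:2004, source = "modeled")
  expect_equal(align_pair(full_o, full_m)$n, 41L)

  # NA values are treated as gaps
  gappy <- make_series(c(1, NA, 3, 4, 5), years = 1990:1994)
  other <- make_series(1:5, years = 1990:1994, source = "modeled")
  expect_equal(align_pair(gappy, other)$years, c(1990L, 1992L, 1993L, 1994L))
})

test_that("align_pair errors on insufficient overlap and mismatched identity", {
  a <- make_series(1:5, years = 1990:1994)
  b <- make_series(1:5, years = 2000:2004, source = "modeled")
  expect_error(align_pair(a, b), "insufficient overlap")
  c2 <- make_series(1:5, years = 1990:1994, id = "other", source = "modeled")
  expect_error(align_pair(a, c2), "different series_id")
})

test_that("align_pair year set is symmetric in its arguments", {
  set.seed(42)
  for (k in 1:20) {
    y1 <- sort(sample(1964:2013, 25))
    y2 <- sort(sample(1964:2013, 25))
    a <- make_series(rnorm(25), years = y1)
    b <- make_series(rnorm(25), years = y2, source = "modeled")
    common <- intersect(y1, y2)
    if (length(common) < 3) next
    expect_identical(align_pair(a, b)$years, align_pair(b, a)$years)
  }
})

test_that("standardize gives mean 0, sd 1 and is idempotent", {
  s <- standardize(make_series(c(1, 2, 3)))
  expect_equal(s$values, c(-1, 0, 1))
  expect_equal(s$units, "dimensionless")

  set.seed(1)
  x <- standardize(make_series(rnorm(30, 50, 7)))
  expect_equal(mean(x$values), 0, tolerance = 1e-10)
  expect_equal(sd(x$values), 1, tolerance = 1e-10)
  twice <- standardize(x)
  expect_equal(twice$values, x$values, tolerance = 1e-10)
})

test_that("standardize rejects degenerate series", {
  expect_error(standardize(make_series(c(5, 5, 5))), "degenerate")
  expect_error(standardize(make_series(7)), "degenerate")
})

test_that("skill tables round trip exactly, including NA cells", {
  tab <- data.frame(
    series_id = rep(c("a", "b", "c"), each = 14),
    category = "biomass",
    metric = rep(metric_definitions()$code, 6),
    period = rep(rep(c("h", "f"), each = 7), 3),
    value = c(rnorm(41), NA),
    n = 10L, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 3 * 7 * 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_skill_table(tab, path)
  back <- read_skill_table(path)
  expect_identical(back$value, tab$value)
  expect_identical(back$series_id, tab$series_id)
  expect_equal(length(readLines(path)), 43L)  # header + 42 rows
})

test_that("one-cell skill table writes header plus one row", {
  tab <- data.frame(series_id = "a", category = "biomass", metric = "MEF",
                    period = "h", value = 0.5, n = 10L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_skill_table(tab, path)
  expect_equal(length(readLines(path)), 2L)
  expect_error(write_skill_table(tab[0, ], path))
})
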