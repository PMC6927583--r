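write_long_csv <- function(rows, path) {
  header <- "unit_id,parent_state,level,year,outcome,value,population"
  writeLines(c(header, rows), path)
  path
}

test_that("read_panel transcribes a clean long CSV faithfully", {
  path <- write_long_csv(c(
    "CA,CA,state,2011,mmr,94.0,1000000",
    "CA,CA,state,2012,mmr,94.5,1000000",
    "CA,CA,state,2013,mmr,95.0,1000000"
  ), withr::local_tempfile(fileext = ".csv"))
  p <- read_panel(path, level = "state", treated_units = "CA",
                  policy_year = 2013)
  expect_s3_class(p, "panel_dataset")
  expect_equal(nrow(p$data), 3)
  expect_equal(p$data$mmr, c(94.0, 94.5, 95.0))
  expect_false(anyNA(p$data$mmr))
})

test_that("read_panel rejects out-of-range values, duplicates, bad schema", {
  bad_value <- write_long_csv(c(
    "CA,CA,state,2011,mmr,101.0,1000000",
    "CA,CA,state,2012,mmr,94.5,1000000",
    "NY,NY,state,2011,mmr,94.0,1000000",
    "NY,NY,state,2012,mmr,94.2,1000000"
  ), withr::local_tempfile(fileext = ".csv"))
  expect_error(
    read_panel(bad_value, "state", treated_units = "CA", policy_year = 2012),
    "CA.*2011.*101", class = "vaxpolicy_validation_error"
  )

  dup <- write_long_csv(c(
    "CA,CA,state,2015,mmr,94.0,1000000",
    "CA,CA,state,2015,mmr,94.5,1000000"
  ), withr::local_tempfile(fileext = ".csv"))
  expect_error(
    read_panel(dup, "state", treated_units = "CA", policy_year = 2015),
    "duplicate", class = "vaxpolicy_validation_error"
  )

  missing_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,year,outcome,value",
               "CA,2011,mmr,94.0"), missing_col)
  expect_error(
    read_panel(missing_col, "state", treated_units = "CA",
               policy_year = 2012),
    "parent_state", class = "vaxpolicy_schema_error"
  )
})

test_that("missing cells survive a write/read round trip as missing", {
  path <- write_long_csv(c(
    "CA,CA,state,2011,mmr,94.0,1000000",
    "CA,CA,state,2012,mmr,,1000000",
    "CA,CA,state,2013,mmr,95.0,1000000"
  ), withr::local_tempfile(fileext = ".csv"))
  p <- read_panel(path, "state", treated_units = "CA", policy_year = 2013)
  expect_true(is.na(p$data$mmr[p$data$year == 2012]))
  out <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, out)
  p2 <- read_panel(out, "state", treated_units = "CA", policy_year = 2013)
  expect_equal(p2$data$mmr, p$data$mmr)
})

county_fixture <- function(populations, overall, mmr) {
  units <- names(populations)
  d <- tidyr::crossing(unit_id = units, year = 2014:2017)
  d <- tibble::tibble(
    unit_id = d$unit_id,
    parent_state = substr(d$unit_id, 1, 2),
    year = as.integer(d$year),
    population = populations[d$unit_id]
  )
  d$overall <- as.numeric(t(overall))
  d$mmr <- as.numeric(t(mmr))
  panel_dataset(d, level = "county", treated_units = units[startsWith(units, "CA")],
                policy_year = 2016)
}

test_that("population filter excludes counties below 65,000 and logs them", {
  ovl <- matrix(92, 3, 4, dimnames = list(c("CA_a", "S1_a", "S1_b"), NULL))
  pops <- c(CA_a = 2e6, S1_a = 64999, S1_b = 65000)
  panel <- county_fixture(pops, ovl, ovl)
  res <- apply_county_filters(panel, min_population = 65000)
  expect_equal(res$report$excluded_units$unit_id, "S1_a")
  expect_equal(res$report$excluded_units$reason, "population_below_threshold")
  expect_setequal(unique(res$panel$data$unit_id), c("CA_a", "S1_b"))
})

test_that("counties never reporting overall coverage are proxied from MMR", {
  ovl <- matrix(c(rep(92, 4), rep(NA, 4), rep(93, 4)), 3, 4, byrow = TRUE,
                dimnames = list(c("CA_a", "S1_a", "S1_b"), NULL))
  mmr <- matrix(c(rep(94, 4), 90, 91, 92, 93, rep(95, 4)), 3, 4, byrow = TRUE,
                dimnames = list(c("CA_a", "S1_a", "S1_b"), NULL))
  panel <- county_fixture(c(CA_a = 1e6, S1_a = 1e5, S1_b = 1e5), ovl, mmr)
  res <- apply_county_filters(panel)
  filled <- res$panel$data[res$panel$data$unit_id == "S1_a", ]
  expect_equal(filled$overall, c(90, 91, 92, 93))
  expect_equal(sort(res$report$proxy_substitutions$year), 2014:2017)
  expect_equal(unique(res$report$proxy_substitutions$unit_id), "S1_a")
  # a county reporting overall coverage is untouched
  expect_equal(res$panel$data$overall[res$panel$data$unit_id == "S1_b"],
               rep(93, 4))
})

test_that("filters are a no-op on a conforming panel, and idempotent", {
  ovl <- matrix(92:95, 3, 4, byrow = TRUE,
                dimnames = list(c("CA_a", "S1_a", "S1_b"), NULL))
  panel <- county_fixture(c(CA_a = 1e6, S1_a = 1e5, S1_b = 1e5), ovl, ovl)
  res <- apply_county_filters(panel)
  expect_equal(res$panel$data, panel$data)
  expect_equal(nrow(res$report$excluded_units), 0)
  expect_equal(nrow(res$report$proxy_substitutions), 0)
  twice <- apply_county_filters(res$panel)
  expect_equal(twice$panel$data, res$panel$data)
  expect_error(apply_county_filters(
    make_state_panel(list(mmr = matrix(90, 2, 3,
                                       dimnames = list(c("CA", "NY"), NULL))),
    2014:2016, "CA", 2016)
  ), class = "vaxpolicy_level_error")
})

missing_fixture <- function(vals_by_unit) {
  units <- names(vals_by_unit)
  years <- 2010:2017
  d <- tibble::tibble(
    unit_id = rep(units, each = length(years)),
    parent_state = rep(units, each = length(years)),
    year = rep(years, length(units)),
    population = 1e6,
    mmr = unlist(vals_by_unit, use.names = FALSE)
  )
  panel_dataset(d, level = "state", treated_units = units[1],
                policy_year = 2016)
}

test_that("handle_missing interpolates interior gaps and extends edges", {
  panel <- missing_fixture(list(
    CA = c(92, 92, 92, 90, NA, 92, 93, 93),     # interior gap: midpoint 91
    NY = c(NA, 94, 94, 94, 94, 94, 94, 95)      # leading gap: nearest value
  ))
  res <- handle_missing(panel, "mmr", max_missing_fraction = 0.2)
  ca <- res$panel$data[res$panel$data$unit_id == "CA", ]
  expect_equal(ca$mmr[ca$year == 2014], 91.0)
  ny <- res$panel$data[res$panel$data$unit_id == "NY", ]
  expect_equal(ny$mmr[ny$year == 2010], 94)
  expect_false(anyNA(res$panel$data$mmr))
  expect_equal(nrow(res$report$imputed_cells), 2)
  expect_true(all(c("CA", "NY") %in% res$report$imputed_cells$unit_id))
})

test_that("handle_missing excludes units over the threshold and never touches observed cells", {
  panel <- missing_fixture(list(
    CA = c(92, 92, 92, 90, 91, 92, 93, 93),
    NY = c(NA, NA, NA, NA, 94, 94, 94, 95)      # 4/8 missing > 0.2
  ))
  res <- handle_missing(panel, "mmr", max_missing_fraction = 0.2)
  expect_equal(res$report$excluded_units$unit_id, "NY")
  expect_equal(res$report$excluded_units$reason, "missing_above_threshold")
  expect_false("NY" %in% res$panel$data$unit_id)
  orig <- panel$data[panel$data$unit_id == "CA", ]
  kept <- res$panel$data[res$panel$data$unit_id == "CA", ]
  expect_identical(kept$mmr, orig$mmr)
  # excluded and imputed unit sets are disjoint
  expect_length(intersect(res$report$excluded_units$unit_id,
                          res$report$imputed_cells$unit_id), 0)
})

test_that("handle_missing is a no-op on complete data and idempotent", {
  panel <- missing_fixture(list(
    CA = c(92, 92, 92, 90, 91, 92, 93, 93),
    NY = c(93, 94, 94, 94, 94, 94, 94, 95)
  ))
  res <- handle_missing(panel, "mmr")
  expect_equal(res$panel$data, panel$data)
  expect_equal(nrow(res$report$imputed_cells), 0)
  expect_equal(nrow(res$report$excluded_units), 0)
  # idempotence on a panel that required repair
  rep1 <- handle_missing(missing_fixture(list(
    CA = c(92, 92, 92, 90, NA, 92, 93, 93),
    NY = c(93, 94, 94, 94, 94, 94, 94, 95)
  )), "mmr")
  rep2 <- handle_missing(rep1$panel, "mmr")
  expect_equal(rep2$panel$data, rep1$panel$data)
  expect_equal(nrow(rep2$report$imputed_cells), 0)
  expect_error(handle_missing(panel, "mmr", max_missing_fraction = 1.5),
               class = "vaxpolicy_parameter_error")
  expect_error(handle_missing(panel, "nope"),
               class = "vaxpolicy_name_error")
})

test_that("panel invariants are enforced at construction", {
  d <- tibble::tibble(unit_id = c("CA", "CA"), parent_state = "CA",
                      year = c(2015L, 2015L), population = 1e6, mmr = 90)
  expect_error(panel_dataset(d, "state", "CA", 2015),
               "duplicate", class = "vaxpolicy_validation_error")
  d2 <- tibble::tibble(unit_id = c("CA", "NY"), parent_state = c("CA", "NY"),
                       year = 2015L, population = 1e6, mmr = c(90, 91))
  expect_error(panel_dataset(d2, "state", character(0), 2015),
               class = "vaxpolicy_validation_error")
  expect_error(panel_dataset(d2, "state", "TX", 2015),
               class = "vaxpolicy_validation_error")
})
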