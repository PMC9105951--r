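test_that("packaged population fixture matches the baseline birth-cohort table", {
  pop <- fixture_population()
  expect_equal(pop$births_thousands, table1_births)
  expect_equal(pop$mean_hb, table1_hb)
  expect_equal(pop$income_share, table1_income)
  expect_equal(pop$births_thousands[1], 436)
  expect_equal(pop$mean_hb[1], 10.4)
  expect_equal(pop$income_share[1], 1.92)
  expect_equal(pop$births_thousands[10], 355)
  expect_equal(pop$mean_hb[10], 11.2)
  expect_equal(pop$income_share[10], 34.8)
  expect_equal(pop$hb_sd, rep(1.4, 10))
})

test_that("population validation rejects malformed inputs naming the field", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  pop <- fixture_population()
  # nine strata
  write_population(pop, tmp)
  nine <- read.csv(tmp)[-4, ]
  write.csv(nine, tmp, row.names = FALSE)
  expect_error(load_population(tmp), "decile")
  # non-numeric cell
  bad <- read.csv(ida_fixture("population"))
  bad$mean_hb_gdl <- as.character(bad$mean_hb_gdl)
  bad$mean_hb_gdl[3] <- "ten"
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_population(tmp), "mean_hb_gdl")
  # income shares off by more than 0.5
  bad2 <- read.csv(ida_fixture("population"))
  bad2$income_share_pct[10] <- 40
  write.csv(bad2, tmp, row.names = FALSE)
  expect_error(load_population(tmp), "income_share")
  expect_error(ida_population(1:10, table1_births, table1_hb,
                              hb_sd = -1, table1_income), "hb_sd")
})

test_that("decile-to-tertile mapping is a partition and is configurable", {
  pop <- fixture_population()
  expect_equal(pop$tertile, c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3))
  expect_true(all(table(pop$tertile) >= 1))
  alt <- load_population(ida_fixture("population"), tertile_cuts = c(4, 8))
  expect_equal(alt$tertile, c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3))
  expect_error(tertile_of(1:10, c(7, 3)), "tertile_cuts")
})

test_that("population and consumption configs round-trip bit-for-bit", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  pop <- fixture_population()
  write_population(pop, tmp)
  expect_identical(load_population(tmp), pop)

  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  prof <- fixture_consumption()
  write_consumption(prof, tmp2)
  back <- load_consumption(tmp2)
  expect_equal(back$share_overall, prof$share_overall)
  expect_equal(back$share_tertile, prof$share_tertile)
  expect_equal(back$duration_pmf, prof$duration_pmf)
  expect_equal(back$servings_per_day, prof$servings_per_day)

  tmp3 <- withr::local_tempfile(fileext = ".yaml")
  pars <- default_parameters(ida_share = 0.33, income_growth = 0.025)
  write_parameters(pars, tmp3)
  back3 <- load_parameters(tmp3)
  expect_equal(back3$ida_share, 0.33)
  expect_equal(back3$income_growth, 0.025)
  expect_equal(unname(back3$anemia_cutoffs), unname(pars$anemia_cutoffs))
})

test_that("parameter defaults, overrides and range contracts behave", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", tmp)                      # empty override file
  p <- load_parameters(tmp)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$exposure_years, 1.5)

  writeLines("ida_share: 0.46", tmp)
  expect_equal(load_parameters(tmp)$ida_share, 0.46)

  writeLines("ida_share: 1.2", tmp)
  expect_error(load_parameters(tmp), "ida_share")

  # outside the literature envelope but still a fraction: explicit opt-in
  writeLines("ida_share: 0.1", tmp)
  expect_error(load_parameters(tmp), "envelope")
  expect_equal(
    load_parameters(tmp, allow_ida_outside_envelope = TRUE)$ida_share, 0.1)

  expect_error(default_parameters(working_ages = c(65, 15)), "working_ages")
  expect_error(default_parameters(nonsense = 1), "nonsense")
})

test_that("decile wages scale the national mean by income share by default", {
  pop <- fixture_population()
  p <- default_parameters()
  w <- decile_wages(p, pop)
  national <- p$mean_monthly_wage_idr * 12 / p$exchange_rate_idr_per_usd
  expect_equal(w, national * table1_income / 10)
  p2 <- default_parameters(mean_wage_by_decile_usd = rep(1000, 10))
  expect_equal(decile_wages(p2, pop), rep(1000, 10))
})
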