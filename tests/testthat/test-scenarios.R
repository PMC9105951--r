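test_that("scenario transformations act on the declared levers only", {
  prof <- fixture_consumption()
  eff <- effect_model()

  cur <- apply_scenario(prof, eff, "CURRENT")
  expect_identical(cur$profile, prof)
  expect_identical(cur$effect, eff)

  nf <- apply_scenario(prof, eff, "NO_FORTIFICATION")
  expect_equal(nf$effect$max_effect, 0)
  expect_identical(nf$profile$duration_pmf, prof$duration_pmf)

  ts <- apply_scenario(prof, eff, "TWO_SERVINGS_ALL_PLUS2")
  expect_equal(ts$profile$servings_per_day, 2)

  lift <- apply_scenario(prof, eff, "LIFT_LOWEST_TO_MIDDLE")
  expect_equal(unname(lift$profile$share_tertile[, 1]),
               unname(prof$share_tertile[, 2]))
  expect_equal(unname(lift$profile$share_tertile["6", 1]), 0.49)
  expect_equal(unname(lift$profile$share_tertile[, 2]),
               unname(prof$share_tertile[, 2]))

  expect_error(scenario("SOMETHING_ELSE"), "kind")
})

test_that("extending short consumers moves pmf mass without leaks", {
  pmf <- setNames(c(0.3, 0.2, 0.3, 0, 0.2), 0:4)
  out <- extend_pmf(pmf, threshold = 3, extension = 2)
  expect_equal(unname(out["0"]), 0.3)       # never-consumers untouched
  expect_equal(unname(out["3"]), 0.2)       # mass at 1 moved to 3
  expect_equal(unname(out["4"]), 0.5)       # 0.3 from 2, plus existing 0.2
  expect_equal(sum(out), 1)
  expect_true(all(out >= 0))
  # defaults per scenario kind
  expect_equal(scenario("EXTEND_SHORT_PLUS2")$short_duration_threshold, 3)
  expect_equal(scenario("LIFT_AND_EXTEND")$short_duration_threshold, 5)
  expect_equal(scenario("EXTEND_SHORT_PLUS2")$extension, 2)
})

test_that("scenario application never leaves the valid domain", {
  prof <- fixture_consumption()
  eff <- effect_model()
  for (kind in c("CURRENT", "NO_FORTIFICATION", "EXTEND_SHORT_PLUS2",
                 "LIFT_LOWEST_TO_MIDDLE", "LIFT_AND_EXTEND",
                 "TWO_SERVINGS_ALL_PLUS2")) {
    s <- apply_scenario(prof, eff, kind)
    expect_true(all(s$profile$share_tertile >= 0 &
                      s$profile$share_tertile <= 1))
    expect_true(all(s$profile$duration_pmf >= 0))
    expect_true(all(as.numeric(names(s$profile$duration_pmf)) >= 0))
    expect_equal(sum(s$profile$duration_pmf), 1, tolerance = 1e-9)
    expect_gte(s$effect$max_effect, 0)
  }
})

test_that("self-comparison and effect-free analyses are exactly zero", {
  m <- ida_model()
  res <- scenario_analysis(m, scenarios = list("CURRENT"))
  expect_equal(unname(res$CURRENT$difference), rep(0, 7))
  expect_equal(unname(res$CURRENT$pct), rep(0, 7))

  m0 <- ida_model(effect = effect_model(max_effect = 0))
  res0 <- scenario_analysis(m0)
  for (cmp in res0) {
    expect_equal(unname(cmp$difference), rep(0, 7), tolerance = 1e-12)
    expect_equal(unname(cmp$pct), rep(0, 7), tolerance = 1e-12)
  }
})

test_that("difference arithmetic uses the current-consumption denominator", {
  nofort <- burden_result(2175.3, 5.3, 56, 534.1, 6.2)
  current <- burden_result(2005.2, 4.7, 51.9, 495.5, 5.5)
  cmp <- compare_burden(nofort, current, reference = "alternative")
  expect_equal(unname(cmp$difference["losses_total"]), 2180.6 - 2009.9)
  expect_equal(unname(cmp$pct["losses_total"]),
               100 * (2180.6 - 2009.9) / 2009.9)
  # published percentage convention: 171/2009.9 = 8.5%, not 171/2180.6
  expect_equal(round(unname(cmp$pct["losses_total"]), 1), 8.5)
  ident <- compare_burden(current, current)
  expect_equal(unname(ident$difference), rep(0, 7))
})

test_that("scenario burdens are ordered: none >= current >= enhanced", {
  m <- ida_model()
  cur <- burden(m, "CURRENT")
  nofort <- burden(m, "NO_FORTIFICATION")
  for (kind in c("EXTEND_SHORT_PLUS2", "TWO_SERVINGS_ALL_PLUS2")) {
    enh <- burden(m, kind)
    for (comp in burden_components_for_tests()) {
      expect_gte(nofort[[comp]], cur[[comp]] - 1e-9)
      expect_gte(cur[[comp]], enh[[comp]] - 1e-9)
    }
  }
  # tertile-lift scenarios compare within the lowest tertile
  cur1 <- burden(m, "CURRENT", restrict_tertile = 1)
  lift <- burden(m, "LIFT_LOWEST_TO_MIDDLE")
  both <- burden(m, "LIFT_AND_EXTEND")
  for (comp in burden_components_for_tests()) {
    expect_gte(cur1[[comp]], lift[[comp]] - 1e-9)
    # lift plus extension reduces burden at least as much as the lift alone
    expect_gte(lift[[comp]], both[[comp]] - 1e-9)
  }
})

test_that("scenario ordering agrees with a brute-force microsimulation", {
  m <- ida_model()
  prof <- m$consumption
  eff <- m$effect
  pmf <- prof$duration_pmf
  set.seed(31415)
  n <- 1e5
  dur <- as.numeric(names(pmf))[
    sample.int(length(pmf), n, replace = TRUE, prob = pmf)]
  hb0 <- rnorm(n, 10.5 - sum(pmf * fic_effect(as.numeric(names(pmf)), eff)),
               1.4)
  anemic_frac <- function(hb) mean(hb < 11)
  hb_cur <- hb0 + fic_effect(dur, eff)
  hb_nofort <- hb0
  dur2 <- ifelse(dur > 0 & dur < 3, dur + 2, dur)
  hb_two <- hb0 + fic_effect(dur2, eff, servings = 2)
  expect_gte(anemic_frac(hb_nofort), anemic_frac(hb_cur))
  expect_gte(anemic_frac(hb_cur), anemic_frac(hb_two))

  cur <- burden(m, "CURRENT")
  nofort <- burden(m, "NO_FORTIFICATION")
  two <- burden(m, "TWO_SERVINGS_ALL_PLUS2")
  expect_gte(nofort$dalys_total, cur$dalys_total)
  expect_gte(cur$dalys_total, two$dalys_total)
})

test_that("full analysis pairs scenarios as published and is deterministic", {
  m <- ida_model()
  res1 <- scenario_analysis(m)
  res2 <- scenario_analysis(m)
  expect_identical(res1, res2)
  expect_named(res1, c("NO_FORTIFICATION", "EXTEND_SHORT_PLUS2",
                       "LIFT_LOWEST_TO_MIDDLE", "LIFT_AND_EXTEND",
                       "TWO_SERVINGS_ALL_PLUS2"))
  # the no-fortification pair holds the counterfactual as baseline and the
  # current scenario as percentage reference
  expect_equal(res1$NO_FORTIFICATION$reference, "alternative")
  expect_equal(res1$EXTEND_SHORT_PLUS2$reference, "baseline")
  # all differences non-negative (current never does worse than enhanced,
  # and no-fortification never better than current)
  for (cmp in res1) expect_true(all(cmp$difference >= -1e-9))
  # the lift comparisons report the lowest-tertile subpopulation: the
  # current-consumption side is about one third of the national burden
  nat <- burden(m, "CURRENT")
  t1 <- res1$LIFT_LOWEST_TO_MIDDLE$baseline["losses_total"]
  expect_lt(unname(t1), 0.5 * nat$losses_total)
})
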