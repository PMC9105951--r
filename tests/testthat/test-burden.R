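test_that("present value has its closed-form and degenerate behaviours", {
  # growth equal to discount: terms cancel, PV = years x wage
  s <- income_stream(1200, 15, 65, growth = 0.03, discount = 0.03)
  expect_equal(present_value(s), 50 * 1200)
  expect_equal(present_value(income_stream(0, 15, 65)), 0)
  expect_error(income_stream(1000, 65, 15), "start_age")
  expect_error(income_stream(1000, 15, 65, discount = -1), "discount")
})

test_that("present value matches a year-by-year loop oracle", {
  pv_loop <- function(w, a0, a1, g, r, v) {
    total <- 0
    for (a in a0:(a1 - 1)) total <- total + w * (1 + g)^(a - v) / (1 + r)^(a - v)
    total
  }
  expect_equal(present_value(income_stream(1000, 15, 65, growth = 0,
                                           discount = 0.03)),
               pv_loop(1000, 15, 65, 0, 0.03, 1), tolerance = 1e-6)
  set.seed(42)
  for (i in 1:200) {
    w <- runif(1, 100, 20000)
    a0 <- sample(10:25, 1); a1 <- a0 + sample(20:50, 1)
    g <- runif(1, 0, 0.08); r <- runif(1, 0, 0.08); v <- runif(1, 0, 5)
    s <- income_stream(w, a0, a1, growth = g, discount = r,
                       valuation_age = v)
    expect_equal(present_value(s), pv_loop(w, a0, a1, g, r, v),
                 tolerance = 1e-9)
  }
})

test_that("present value strictly decreases in the discount rate", {
  rates <- seq(0.01, 0.1, by = 0.01)
  pv <- vapply(rates, function(r) present_value(
    income_stream(1000, 15, 65, growth = 0.005, discount = r)), numeric(1))
  expect_true(all(diff(pv) < 0))
})

test_that("discounted life years match the geometric closed form", {
  expect_equal(discounted_life_years(10, 0), 10)
  expect_equal(discounted_life_years(0, 0.03), 0)
  closed <- (1 - 1.03^(-70)) / (1 - 1.03^(-1))
  expect_equal(discounted_life_years(70, 0.03), closed, tolerance = 1e-9)
  # fractional final year prorated
  expect_equal(discounted_life_years(2.5, 0.1),
               1 + 1 / 1.1 + 0.5 / 1.1^2, tolerance = 1e-12)
})

test_that("iron-deficiency attribution scales severities and conserves mass", {
  anemia <- structure(c(none = 0.369, mild = 0.304, moderate = 0.314,
                        severe = 0.013), class = "ida_prevalence")
  expect_equal(unname(unclass(ida_prevalence(anemia, 0))),
               c(1, 0, 0, 0))
  expect_equal(unclass(ida_prevalence(anemia, 1)), unclass(anemia))
  r <- ida_prevalence(anemia, 0.46)
  expect_equal(unname(r[c("mild", "moderate", "severe")]),
               c(0.304, 0.314, 0.013) * 0.46)
  expect_equal(unname(r["mild"]), 0.13984)
  expect_equal(unname(r["moderate"]), 0.14444)
  expect_equal(unname(r["severe"]), 0.00598)
  expect_equal(sum(r), 1, tolerance = 1e-12)
})

test_that("burden on a single stratum equals a hand-computed oracle", {
  pop <- fixture_population()
  one <- pop[pop$decile == 1, ]
  params <- default_parameters(
    disability_weights = c(mild = 0.004, moderate = 0.052, severe = 0.149),
    dw_cognitive = 0.05, mortality_risk_severe = 0.01,
    cognitive_income_loss = 0.02, exposure_years = 1.5,
    life_expectancy = 10, discount_rate = 0,
    income_growth = 0, working_ages = c(15, 25),
    mean_wage_by_decile_usd = rep(1000, 10))
  prev <- c(none = 0.9, mild = 0.05, moderate = 0.04, severe = 0.01)
  b <- compute_burden(one, list(prev), params)

  births <- 436 * 1000
  pv <- 10 * 1000                           # 10 undiscounted years of 1000
  n_ida <- births * 0.10
  deaths <- births * 0.01 * 0.01
  expect_equal(b$dalys_physical,
               births * (0.05 * 0.004 + 0.04 * 0.052 + 0.01 * 0.149) * 1.5 / 1e3,
               tolerance = 1e-9)
  expect_equal(b$dalys_cognitive, n_ida * 0.05 * 10 / 1e3, tolerance = 1e-9)
  expect_equal(b$dalys_mortality, deaths * 10 / 1e3, tolerance = 1e-9)
  expect_equal(b$losses_cognitive, n_ida * 0.02 * pv / 1e6, tolerance = 1e-9)
  expect_equal(b$losses_mortality, deaths * pv / 1e6, tolerance = 1e-9)
  expect_equal(b$losses_total, b$losses_cognitive + b$losses_mortality)
  expect_equal(b$dalys_total,
               b$dalys_physical + b$dalys_cognitive + b$dalys_mortality)
})

test_that("burden is zero under a null epidemic and linear in its coefficients", {
  pop <- fixture_population()
  params <- default_parameters()
  zero <- lapply(1:10, function(i)
    c(none = 1, mild = 0, moderate = 0, severe = 0))
  b0 <- compute_burden(pop, zero, params)
  expect_true(all(unlist(b0[burden_components_for_tests()]) == 0))

  prev <- lapply(1:10, function(i)
    c(none = 0.8, mild = 0.1, moderate = 0.08, severe = 0.02))
  b1 <- compute_burden(pop, prev, params)
  params2 <- default_parameters(cognitive_income_loss =
                                  2 * params$cognitive_income_loss)
  b2 <- compute_burden(pop, prev, params2)
  expect_equal(b2$losses_cognitive, 2 * b1$losses_cognitive)
  expect_equal(b2$losses_mortality, b1$losses_mortality)
  expect_equal(b2$dalys_total, b1$dalys_total)
})

test_that("burden is additive over strata and homogeneous in births", {
  pop <- fixture_population()
  params <- default_parameters()
  set.seed(9)
  prev <- lapply(1:10, function(i) {
    sick <- runif(3, 0, 0.1)
    c(none = 1 - sum(sick), mild = sick[1], moderate = sick[2],
      severe = sick[3])
  })
  joint <- compute_burden(pop, prev, params)
  parts <- lapply(1:10, function(i)
    compute_burden(pop[i, ], prev[i], params))
  for (comp in burden_components_for_tests())
    expect_equal(joint[[comp]], sum(vapply(parts, `[[`, numeric(1), comp)),
                 tolerance = 1e-12)

  pop3 <- pop
  pop3$births_thousands <- 3 * pop3$births_thousands
  scaled <- compute_burden(pop3, prev, params)
  for (comp in burden_components_for_tests())
    expect_equal(scaled[[comp]], 3 * joint[[comp]], tolerance = 1e-12)

  expect_error(compute_burden(pop, prev[1:9], params), "prevalence")
})

test_that("burden is component-wise monotone in each prevalence fraction", {
  pop <- fixture_population()
  params <- default_parameters()
  base <- lapply(1:10, function(i)
    c(none = 0.9, mild = 0.05, moderate = 0.04, severe = 0.01))
  b <- compute_burden(pop, base, params)
  for (sev in c("mild", "moderate", "severe")) {
    up <- base
    up[[4]][sev] <- up[[4]][sev] + 0.05
    up[[4]]["none"] <- up[[4]]["none"] - 0.05
    b_up <- compute_burden(pop, up, params)
    for (comp in burden_components_for_tests())
      expect_gte(b_up[[comp]], b[[comp]] - 1e-12)
  }
})
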