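degenerate_spec <- function(n_draws = 5, seed = 1) {
  p <- default_parameters()
  psa_spec(n_draws = n_draws, seed = seed, distributions = list(
    ida_share = list(family = "degenerate", value = p$ida_share),
    cognitive_income_loss = list(family = "degenerate",
                                 value = p$cognitive_income_loss)))
}

test_that("parameter draws respect supports and are reproducible", {
  spec <- psa_spec(n_draws = 50, seed = 11)
  d1 <- draw_parameters(spec, 1)
  d1b <- draw_parameters(spec, 1)
  expect_identical(d1, d1b)
  d2 <- draw_parameters(spec, 2)
  expect_false(identical(d1, d2))
  # draws do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(draw_parameters(spec, 3)); after <- runif(1)
  expect_identical(before, after)

  for (k in 1:100) {
    d <- draw_parameters(spec, k)
    expect_true(d$ida_share >= 0.25 && d$ida_share <= 0.67)
    expect_true(d$dw_mild >= 0 && d$dw_mild <= 1)
    expect_true(d$max_effect >= 0)
    expect_true(d$mean_monthly_wage_idr > 0)
  }

  # degenerate family returns the point value
  dd <- draw_parameters(degenerate_spec(), 7)
  expect_equal(dd$ida_share, default_parameters()$ida_share)

  # unsatisfiable truncation is reported
  bad <- psa_spec(n_draws = 1, seed = 1, distributions = list(
    ida_share = list(family = "uniform", min = 0, max = 1,
                     lower = 2, upper = 3)))
  expect_error(draw_parameters(bad, 1), "unsatisfiable")
})

test_that("a degenerate PSA collapses to the deterministic run", {
  m <- ida_model()
  psa <- run_psa(m$population, m$consumption, m$effect, m$parameters,
                 degenerate_spec(n_draws = 5, seed = 2))
  det <- burden(m, "CURRENT")
  s <- psa$summary
  for (comp in burden_components_for_tests()) {
    row <- s[s$component == comp, ]
    expect_equal(row$mean, det[[comp]])
    expect_equal(row$lower, det[[comp]])
    expect_equal(row$upper, det[[comp]])
  }
})

test_that("seeded PSA runs are bit-reproducible and order-invariant", {
  m <- ida_model()
  spec <- psa_spec(n_draws = 40, seed = 123)
  p1 <- run_psa(m$population, m$consumption, m$effect, m$parameters, spec)
  p2 <- run_psa(m$population, m$consumption, m$effect, m$parameters, spec)
  expect_identical(p1$summary, p2$summary)
  expect_identical(p1$draws, p2$draws)
  # summaries are invariant to permuting the draw matrix
  perm <- p1$draws[sample(nrow(p1$draws)), , drop = FALSE]
  expect_equal(unname(colMeans(perm)), p1$summary$mean)
  expect_equal(unname(apply(perm, 2, quantile, 0.025, names = FALSE)),
               p1$summary$lower)
})

test_that("economic uncertainty widens losses more than DALYs", {
  m <- ida_model()
  # health parameters shared (degenerate), economic parameters uncertain
  spec <- psa_spec(n_draws = 300, seed = 5, distributions = list(
    ida_share = list(family = "degenerate",
                     value = m$parameters$ida_share),
    mean_monthly_wage_idr = list(family = "gamma", shape = 16,
                                 scale = 2.7e6 / 16),
    income_growth = list(family = "normal", mean = 0.04, sd = 0.01,
                         lower = 0, upper = 0.08)))
  psa <- run_psa(m$population, m$consumption, m$effect, m$parameters, spec)
  s <- psa$summary
  rel_width <- function(comp) {
    row <- s[s$component == comp, ]
    (row$upper - row$lower) / row$mean
  }
  expect_gt(rel_width("losses_total"), rel_width("dalys_total"))
  expect_equal(rel_width("dalys_total"), 0, tolerance = 1e-12)
})

test_that("mean-preserving spread does not narrow the output interval", {
  m <- ida_model()
  mk <- function(sd) psa_spec(n_draws = 400, seed = 17, distributions = list(
    cognitive_income_loss = list(family = "normal", mean = 0.025, sd = sd)))
  narrow <- run_psa(m$population, m$consumption, m$effect, m$parameters,
                    mk(0.002))$summary
  wide <- run_psa(m$population, m$consumption, m$effect, m$parameters,
                  mk(0.006))$summary
  width <- function(s, comp) {
    row <- s[s$component == comp, ]
    row$upper - row$lower
  }
  expect_gte(width(wide, "losses_cognitive"),
             width(narrow, "losses_cognitive"))
  expect_gte(width(wide, "losses_total"), width(narrow, "losses_total"))
})
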