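# shared fixture accessors and small builders used across test files

fixture_population <- function() load_population(ida_fixture("population"))
fixture_consumption <- function() load_consumption(ida_fixture("consumption"))

# profile with every monthly share zero and nobody consuming
null_profile <- function() {
  consumption_profile(
    months = 6:23,
    share_overall = rep(0, 18),
    share_tertile = matrix(0, 18, 3),
    duration_pmf = stats::setNames(c(1, rep(0, 18)), 0:18))
}

# profile where every consumer reaches the full-effect horizon
saturated_profile <- function(p_consumer = 0.6) {
  pmf <- stats::setNames(rep(0, 19), 0:18)
  pmf["0"] <- 1 - p_consumer
  pmf["9"] <- p_consumer
  prof <- fixture_consumption()
  prof$duration_pmf <- pmf
  prof
}

burden_components_for_tests <- function() {
  c("losses_cognitive", "losses_mortality", "losses_total",
    "dalys_physical", "dalys_cognitive", "dalys_mortality", "dalys_total")
}

table1_births <- c(436, 427, 418, 413, 400, 376, 371, 370, 357, 355)
table1_hb <- c(10.4, 10.4, 10.5, 10.6, 10.8, 10.9, 11.1, 11.1, 11.2, 11.2)
table1_income <- c(1.92, 3.21, 4.23, 5.18, 6.28, 7.6, 9.29, 11.6, 15.9, 34.8)
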