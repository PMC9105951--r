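#' Discounted lifetime income stream (human capital approach)
#'
#' Present value, at `valuation_age`, of annual wages earned from
#' `start_age` (inclusive) to `end_age` (exclusive), growing at `growth` per
#' year and discounted at `discount` per year:
#' sum over ages a of `annual_wage * ((1 + growth)/(1 + discount))^(a - valuation_age)`.
#'
#' @param annual_wage USD per year at the valuation age.
#' @param start_age,end_age working ages in years (end exclusive).
#' @param growth,discount per-year fractions; `discount > -1`.
#' @param valuation_age age at which the present value is taken (default 1,
#'   the age of the affected child).
#' @return object of class `ida_income_stream`.
#' @examples
#' s <- income_stream(1000, 15, 65, growth = 0, discount = 0.03)
#' present_value(s)
#' @export
income_stream <- function(annual_wage, start_age, end_age,
                          growth = 0, discount = 0.03, valuation_age = 1) {
  check_number(annual_wage, "annual_wage", lower = 0)
  if (start_age >= end_age)
    stop_validation("start_age", "must be below end_age")
  if (discount <= -1) stop_validation("discount", "must exceed -1")
  check_number(growth, "growth", lower = -1, strict_lower = TRUE)
  structure(list(annual_wage = annual_wage, start_age = start_age,
                 end_age = end_age, growth = growth, discount = discount,
                 valuation_age = valuation_age),
            class = "ida_income_stream")
}

#' @rdname income_stream
#' @param stream an `ida_income_stream`.
#' @return present value in USD.
#' @export
present_value <- function(stream) {
  stopifnot(inherits(stream, "ida_income_stream"))
  ages <- seq(stream$start_age, stream$end_age - 1)
  ratio <- (1 + stream$growth) / (1 + stream$discount)
  sum(stream$annual_wage * ratio^(ages - stream$valuation_age))
}

#' Discounted life years
#'
#' Sum of `(1 + discount)^(-t)` over whole years `t = 0, 1, ...` spanning
#' `years`, with a fractional final year prorated. With no discounting this
#' is `years` exactly.
#'
#' @param years duration in years (>= 0).
#' @param discount per-year fraction (>= 0).
#' @return dimensionless discounted years.
#' @examples
#' discounted_life_years(10, 0)      # 10
#' discounted_life_years(70, 0.03)   # about 30
#' @export
discounted_life_years <- function(years, discount = 0.03) {
  check_number(years, "years", lower = 0)
  check_number(discount, "discount", lower = 0)
  if (years == 0) return(0)
  full <- floor(years)
  t <- seq_len(full) - 1
  v <- sum((1 + discount)^(-t))
  frac <- years - full
  if (frac > 0) v <- v + frac * (1 + discount)^(-full)
  v
}

#' Restrict anemia prevalence to its iron-deficiency share
#'
#' Each severity fraction is multiplied by the attribution share; the `none`
#' class absorbs the remainder so the four fractions still sum to 1.
#'
#' @param anemia an `ida_prevalence` (or named none/mild/moderate/severe
#'   vector).
#' @param ida_share fraction of anemia attributed to iron deficiency.
#' @return an `ida_prevalence` of iron-deficiency anemia.
#' @export
ida_prevalence <- function(anemia, ida_share) {
  check_fraction(ida_share, "ida_share")
  sev <- c("mild", "moderate", "severe")
  out <- anemia
  out[sev] <- anemia[sev] * ida_share
  out["none"] <- 1 - sum(out[sev])
  structure(out, class = "ida_prevalence")
}

#' Assemble a burden result
#'
#' Container for the three burden channels: production losses from cognitive
#' impairment and from mortality (millions of USD), and DALYs from impaired
#' physical activity, cognitive impairment and mortality (thousands). Totals
#' are the channel sums. [compute_burden()] builds these from prevalence;
#' the constructor also accepts externally reported channel values (e.g.
#' published table rows) for difference arithmetic.
#'
#' @param losses_cognitive,losses_mortality millions of USD.
#' @param dalys_physical,dalys_cognitive,dalys_mortality thousands of DALYs.
#' @param per_stratum optional per-decile data frame of the same components.
#' @return object of class `ida_burden`.
#' @export
burden_result <- function(losses_cognitive, losses_mortality,
                          dalys_physical, dalys_cognitive, dalys_mortality,
                          per_stratum = NULL) {
  vals <- c(losses_cognitive = losses_cognitive,
            losses_mortality = losses_mortality,
            dalys_physical = dalys_physical,
            dalys_cognitive = dalys_cognitive,
            dalys_mortality = dalys_mortality)
  check_number(unname(vals), "burden components", lower = 0)
  structure(list(
    losses_cognitive = losses_cognitive,
    losses_mortality = losses_mortality,
    losses_total = losses_cognitive + losses_mortality,
    dalys_physical = dalys_physical,
    dalys_cognitive = dalys_cognitive,
    dalys_mortality = dalys_mortality,
    dalys_total = dalys_physical + dalys_cognitive + dalys_mortality,
    per_stratum = per_stratum),
    class = "ida_burden")
}

burden_components <- function() {
  c("losses_cognitive", "losses_mortality", "losses_total",
    "dalys_physical", "dalys_cognitive", "dalys_mortality", "dalys_total")
}

#' @export
print.ida_burden <- function(x, ...) {
  cat("IDA burden\n")
  cat(sprintf("  Production losses (millions USD): cognitive %.1f + mortality %.1f = %.1f\n",
              x$losses_cognitive, x$losses_mortality, x$losses_total))
  cat(sprintf("  DALYs (thousands): physical %.1f + cognitive %.1f + mortality %.1f = %.1f\n",
              x$dalys_physical, x$dalys_cognitive, x$dalys_mortality,
              x$dalys_total))
  invisible(x)
}

#' @export
as.data.frame.ida_burden <- function(x, ...) {
  data.frame(component = burden_components(),
             value = unlist(x[burden_components()], use.names = FALSE))
}

#' Lifetime burden of iron-deficiency anemia across strata
#'
#' Converts per-stratum IDA prevalence into the three burden channels of the
#' comparative risk assessment:
#' \itemize{
#'   \item impaired physical activity: affected children times the severity
#'     disability weight times years of exposure in the 6--23-month window
#'     (YLD during childhood);
#'   \item cognitive impairment: all IDA-positive children carry a lifelong
#'     cognitive sequel (disability weight `dw_cognitive` over discounted
#'     life expectancy) and lose `cognitive_income_loss` of their discounted
#'     lifetime earnings;
#'   \item mortality: severe cases times `mortality_risk_severe` deaths,
#'     each losing discounted life expectancy (YLL) and full discounted
#'     lifetime earnings.
#' }
#' Wages are decile-specific ([decile_wages()]); present values are taken at
#' `valuation_age`. Losses are reported in millions of USD, DALYs in
#' thousands.
#'
#' @param strata an `ida_population` (any subset of deciles is accepted,
#'   e.g. a single wealth tertile).
#' @param prevalence_by_stratum matrix (or list) of IDA-restricted
#'   prevalence rows, one per stratum, columns none/mild/moderate/severe.
#' @param params an `ida_parameters`.
#' @return an `ida_burden` with a `per_stratum` breakdown.
#' @export
compute_burden <- function(strata, prevalence_by_stratum, params) {
  if (is.list(prevalence_by_stratum) && !is.data.frame(prevalence_by_stratum))
    prevalence_by_stratum <- do.call(rbind, prevalence_by_stratum)
  prev <- as.matrix(prevalence_by_stratum)
  if (nrow(prev) != nrow(strata))
    stop_validation("prevalence_by_stratum",
                    sprintf("%d prevalence rows for %d strata",
                            nrow(prev), nrow(strata)))
  if (is.null(colnames(prev))) colnames(prev) <- severity_levels()
  dw <- params$disability_weights
  disc <- if (isTRUE(params$daly_discounting)) params$discount_rate else 0
  dly <- discounted_life_years(params$life_expectancy, disc)
  wages <- decile_wages(params, strata)
  if (!is.null(strata$decile) && length(wages) == 10L)
    wages <- wages[strata$decile]
  births <- strata$births_thousands * 1000
  n_mild <- births * prev[, "mild"]
  n_mod <- births * prev[, "moderate"]
  n_sev <- births * prev[, "severe"]
  n_ida <- n_mild + n_mod + n_sev
  pv <- vapply(wages, function(w) present_value(income_stream(
    w, params$working_ages[1], params$working_ages[2],
    growth = params$income_growth, discount = params$discount_rate,
    valuation_age = params$valuation_age)), numeric(1))
  deaths <- n_sev * params$mortality_risk_severe

  dalys_physical <- (n_mild * dw["mild"] + n_mod * dw["moderate"] +
                       n_sev * dw["severe"]) * params$exposure_years
  dalys_cognitive <- n_ida * params$dw_cognitive * dly
  dalys_mortality <- deaths * dly
  losses_cognitive <- n_ida * params$cognitive_income_loss * pv
  losses_mortality <- deaths * pv

  per <- data.frame(
    decile = strata$decile,
    losses_cognitive = unname(losses_cognitive) / 1e6,
    losses_mortality = unname(losses_mortality) / 1e6,
    dalys_physical = unname(dalys_physical) / 1e3,
    dalys_cognitive = unname(dalys_cognitive) / 1e3,
    dalys_mortality = unname(dalys_mortality) / 1e3)
  burden_result(sum(per$losses_cognitive), sum(per$losses_mortality),
                sum(per$dalys_physical), sum(per$dalys_cognitive),
                sum(per$dalys_mortality), per_stratum = per)
}
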