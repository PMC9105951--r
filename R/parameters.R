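#' Model parameter configuration
#'
#' All coefficients of the burden engine in one validated list. The defaults
#' are documented, literature-conventional stand-ins chosen once for this
#' package — anemia severity thresholds follow the WHO convention for
#' children 6--59 months; the iron-deficiency attribution share defaults to
#' the midpoint of the 25--67% literature envelope; disability weights for
#' mild/moderate/severe anemia are the conventional 0.004/0.052/0.149; the
#' economic block uses a 3% discount rate, income growth equal to the
#' average of the preceding decade, a 2020 exchange rate and an ILO-scale
#' mean wage allocated across deciles by income share. Every field can be
#' overridden via [load_parameters()].
#'
#' @param ... named overrides of the defaults listed below.
#' @return object of class `ida_parameters`, a validated named list with
#'   fields:
#' \describe{
#'   \item{anemia_cutoffs}{g/dL thresholds `c(severe, moderate, mild)` =
#'     `c(7, 10, 11)`: severe below 7, moderate 7--9.9, mild 10--10.9,
#'     none at 11 and above.}
#'   \item{ida_share}{fraction of anemia attributed to iron deficiency,
#'     default 0.46.}
#'   \item{disability_weights}{named `c(mild, moderate, severe)` anemia
#'     disability weights.}
#'   \item{dw_cognitive}{disability weight of the lifelong cognitive sequel,
#'     default 0.024.}
#'   \item{mortality_risk_severe}{probability of death attributable to
#'     severe iron-deficiency anemia, default 0.005.}
#'   \item{cognitive_income_loss}{fraction of lifetime earnings lost per
#'     affected child, default 0.025.}
#'   \item{exposure_years}{years of anemia exposure in the 6--23-month
#'     window, default 1.5.}
#'   \item{discount_rate}{per-year, default 0.03.}
#'   \item{income_growth}{per-year, default 0.04.}
#'   \item{working_ages}{`c(start, end)` in years, default `c(15, 65)`
#'     (end exclusive).}
#'   \item{life_expectancy}{years, default 71.}
#'   \item{valuation_age}{age (years) at which present values are taken,
#'     default 1.}
#'   \item{exchange_rate_idr_per_usd}{default 14582 (2020 mean).}
#'   \item{mean_monthly_wage_idr}{default 2,700,000 IDR.}
#'   \item{mean_wage_by_decile_usd}{optional 10-vector of annual wages; when
#'     `NULL` it is derived as national mean annual wage scaled by each
#'     decile's income share (share/10%).}
#'   \item{daly_discounting}{logical; discount DALYs at `discount_rate`
#'     (default TRUE).}
#' }
#' @examples
#' p <- default_parameters()
#' p$discount_rate             # 0.03
#' p2 <- default_parameters(ida_share = 0.3)
#' @export
default_parameters <- function(...) {
  p <- list(
    anemia_cutoffs = c(severe = 7, moderate = 10, mild = 11),
    ida_share = 0.46,
    disability_weights = c(mild = 0.004, moderate = 0.052, severe = 0.149),
    dw_cognitive = 0.024,
    mortality_risk_severe = 0.005,
    cognitive_income_loss = 0.025,
    exposure_years = 1.5,
    discount_rate = 0.03,
    income_growth = 0.04,
    working_ages = c(15, 65),
    life_expectancy = 71,
    valuation_age = 1,
    exchange_rate_idr_per_usd = 14582,
    mean_monthly_wage_idr = 2.7e6,
    mean_wage_by_decile_usd = NULL,
    daly_discounting = TRUE
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop_validation(unknown[1], "unknown parameter")
    p[names(over)] <- over
  }
  validate_parameters(p)
}

#' @rdname default_parameters
#' @param p a parameter list.
#' @param allow_ida_outside_envelope permit `ida_share` outside the
#'   literature envelope `[0.25, 0.67]` (it must still be a fraction).
#' @export
validate_parameters <- function(p, allow_ida_outside_envelope = FALSE) {
  cut <- p$anemia_cutoffs
  if (length(cut) != 3L || any(diff(cut) <= 0))
    stop_validation("anemia_cutoffs", "need three strictly increasing g/dL cutoffs")
  check_fraction(p$ida_share, "ida_share")
  if (!allow_ida_outside_envelope &&
      (p$ida_share < 0.25 || p$ida_share > 0.67))
    stop_validation("ida_share",
                    "outside the literature envelope [0.25, 0.67]; pass allow_ida_outside_envelope = TRUE to override")
  if (length(p$disability_weights) != 3L)
    stop_validation("disability_weights", "need mild, moderate, severe weights")
  check_fraction(unname(p$disability_weights), "disability_weights")
  names(p$disability_weights) <- c("mild", "moderate", "severe")
  check_fraction(p$dw_cognitive, "dw_cognitive")
  check_fraction(p$mortality_risk_severe, "mortality_risk_severe")
  check_fraction(p$cognitive_income_loss, "cognitive_income_loss")
  check_number(p$exposure_years, "exposure_years", lower = 0)
  check_number(p$discount_rate, "discount_rate", lower = 0)
  check_number(p$income_growth, "income_growth", lower = -1,
               strict_lower = TRUE)
  if (length(p$working_ages) != 2L || p$working_ages[1] >= p$working_ages[2])
    stop_validation("working_ages", "need start < end")
  check_number(p$life_expectancy, "life_expectancy", lower = 0,
               strict_lower = TRUE)
  check_number(p$valuation_age, "valuation_age", lower = 0)
  check_number(p$exchange_rate_idr_per_usd, "exchange_rate_idr_per_usd",
               lower = 0, strict_lower = TRUE)
  check_number(p$mean_monthly_wage_idr, "mean_monthly_wage_idr", lower = 0)
  if (!is.null(p$mean_wage_by_decile_usd)) {
    if (length(p$mean_wage_by_decile_usd) != 10L)
      stop_validation("mean_wage_by_decile_usd", "need one wage per decile")
    check_number(p$mean_wage_by_decile_usd, "mean_wage_by_decile_usd",
                 lower = 0)
  }
  structure(p, class = "ida_parameters")
}

#' Annual wage per decile (USD)
#'
#' Uses the configured per-decile wages when present, otherwise the national
#' mean annual wage (monthly IDR wage x 12 / exchange rate) scaled by each
#' decile's household income share relative to an equal 10% share.
#'
#' @param params an `ida_parameters`.
#' @param population an `ida_population`.
#' @return numeric vector of 10 annual wages, USD.
#' @export
decile_wages <- function(params, population) {
  if (!is.null(params$mean_wage_by_decile_usd))
    return(params$mean_wage_by_decile_usd)
  mean_annual_usd <- params$mean_monthly_wage_idr * 12 /
    params$exchange_rate_idr_per_usd
  mean_annual_usd * population$income_share / 10
}

#' Read model parameters from a YAML override file
#'
#' Fields absent from the file keep their documented defaults; an empty file
#' returns [default_parameters()].
#'
#' @param path YAML file of overrides (may be empty).
#' @param allow_ida_outside_envelope see [validate_parameters()].
#' @return an `ida_parameters`.
#' @export
load_parameters <- function(path, allow_ida_outside_envelope = FALSE) {
  if (!file.exists(path)) stop_validation("path", paste("no such file:", path))
  y <- yaml::read_yaml(path)
  p <- unclass(default_parameters())
  if (length(y)) {
    unknown <- setdiff(names(y), names(p))
    if (length(unknown)) stop_validation(unknown[1], "unknown parameter")
    for (nm in names(y)) p[[nm]] <- unlist(y[[nm]])
  }
  validate_parameters(p, allow_ida_outside_envelope)
}

#' Write model parameters to YAML
#'
#' @param params an `ida_parameters`.
#' @param path output path.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "ida_parameters"))
  y <- unclass(params)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(lapply(y, unname), path, precision = 15)
  invisible(path)
}

#' @export
print.ida_parameters <- function(x, ...) {
  cat("IDA model parameters:\n")
  cat(sprintf("  anemia cutoffs (g/dL): severe <%g, moderate <%g, mild <%g\n",
              x$anemia_cutoffs[1], x$anemia_cutoffs[2], x$anemia_cutoffs[3]))
  cat(sprintf("  ida_share %.2f; discount %.1f%%; income growth %.1f%%\n",
              x$ida_share, 100 * x$discount_rate, 100 * x$income_growth))
  cat(sprintf("  disability weights m/M/S: %.3f/%.3f/%.3f; cognitive %.3f\n",
              x$disability_weights[1], x$disability_weights[2],
              x$disability_weights[3], x$dw_cognitive))
  invisible(x)
}
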