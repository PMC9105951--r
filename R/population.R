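#' Baseline population strata by socioeconomic decile
#'
#' The simulation stratifies the national birth cohort into ten
#' socioeconomic (SES) deciles, each carrying the number of births (in
#' thousands), the mean hemoglobin concentration of children aged 6--23
#' months (g/dL), the decile's share of national household income (percent),
#' and a wealth tertile derived from the decile. The packaged fixture
#' (`ida_fixture("population")`) holds the 2017 Indonesian birth cohort used
#' throughout the package documentation.
#'
#' @param decile integer 1--10.
#' @param births_thousands births in the stratum, thousands.
#' @param mean_hb mean hemoglobin, g/dL.
#' @param hb_sd hemoglobin standard deviation, g/dL. A single dispersion is
#'   typically available for the whole population; it is recycled per decile
#'   and can be overridden per stratum.
#' @param income_share percent of national household income; must sum to
#'   100 (within 0.5) across the ten strata.
#' @param tertile_cuts upper decile of tertiles 1 and 2; default `c(3, 7)`
#'   maps deciles 1--3, 4--7, 8--10 to tertiles 1--3 so tertiles approximate
#'   population thirds.
#' @return An object of class `ida_population`: a data frame with columns
#'   `decile`, `births_thousands`, `mean_hb`, `hb_sd`, `income_share`,
#'   `tertile`, sorted by decile.
#' @examples
#' pop <- load_population(ida_fixture("population"))
#' pop$births_thousands[1]   # 436 thousand births in decile 1
#' @export
ida_population <- function(decile, births_thousands, mean_hb,
                           hb_sd = 1.4, income_share,
                           tertile_cuts = c(3, 7)) {
  df <- data.frame(
    decile = as.integer(decile),
    births_thousands = as.numeric(births_thousands),
    mean_hb = as.numeric(mean_hb),
    hb_sd = as.numeric(rep_len(hb_sd, length(decile))),
    income_share = as.numeric(income_share)
  )
  df <- df[order(df$decile), , drop = FALSE]
  rownames(df) <- NULL
  validate_population(df)
  df$tertile <- tertile_of(df$decile, tertile_cuts)
  structure(df, class = c("ida_population", "data.frame"),
            tertile_cuts = tertile_cuts)
}

tertile_of <- function(decile, cuts = c(3, 7)) {
  if (length(cuts) != 2L || cuts[1] >= cuts[2])
    stop_validation("tertile_cuts", "must be two increasing cut deciles")
  as.integer(1L + (decile > cuts[1]) + (decile > cuts[2]))
}

validate_population <- function(df) {
  if (nrow(df) != 10L)
    stop_validation("decile", sprintf("expected 10 strata, got %d", nrow(df)))
  if (!identical(sort(df$decile), 1:10))
    stop_validation("decile", paste(
      "must be exactly 1..10; missing:",
      paste(setdiff(1:10, df$decile), collapse = ", ")))
  check_number(df$births_thousands, "births_thousands", lower = 0)
  check_number(df$mean_hb, "mean_hb", lower = 0, upper = 25,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(df$hb_sd, "hb_sd", lower = 0, strict_lower = TRUE)
  check_number(df$income_share, "income_share", lower = 0, upper = 100)
  tot <- sum(df$income_share)
  if (abs(tot - 100) > 0.5)
    stop_validation("income_share",
                    sprintf("shares must sum to 100 +/- 0.5, got %.3f", tot))
  invisible(df)
}

#' Read a population table from CSV
#'
#' Expects columns `decile`, `births_thousands`, `mean_hb_gdl`,
#' `income_share_pct` and optionally `hb_sd_gdl` (defaults to 1.4 g/dL, the
#' population-level dispersion, when absent). Units are explicit in the
#' column names for auditability.
#'
#' @param path CSV file path.
#' @param tertile_cuts see [ida_population()].
#' @return an `ida_population`.
#' @export
load_population <- function(path, tertile_cuts = c(3, 7)) {
  if (!file.exists(path)) stop_validation("path", paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("decile", "births_thousands", "mean_hb_gdl", "income_share_pct")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_validation(missing[1], "column missing from population file")
  for (col in needed)
    if (!is.numeric(df[[col]]))
      stop_validation(col, "non-numeric cell in population file")
  hb_sd <- if ("hb_sd_gdl" %in% names(df)) df$hb_sd_gdl else 1.4
  ida_population(df$decile, df$births_thousands, df$mean_hb_gdl,
                 hb_sd, df$income_share_pct, tertile_cuts)
}

#' Write a population table to CSV
#'
#' Inverse of [load_population()]; the decimal representations round-trip
#' exactly.
#'
#' @param pop an `ida_population`.
#' @param path output CSV path.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "ida_population"))
  out <- data.frame(decile = pop$decile,
                    births_thousands = pop$births_thousands,
                    mean_hb_gdl = pop$mean_hb,
                    hb_sd_gdl = pop$hb_sd,
                    income_share_pct = pop$income_share)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to a packaged input fixture
#'
#' @param which one of `"population"`, `"consumption"`, `"parameters"`.
#' @return file path inside the installed package.
#' @export
ida_fixture <- function(which = c("population", "consumption", "parameters")) {
  which <- match.arg(which)
  fn <- switch(which,
               population = "population_deciles.csv",
               consumption = "consumption_profile.yaml",
               parameters = "model_parameters.yaml")
  system.file("extdata", fn, package = "idaburden", mustWork = TRUE)
}

#' @export
print.ida_population <- function(x, ...) {
  cat("Population strata (SES deciles):",
      sprintf("%.0f thousand births,", sum(x$births_thousands)),
      sprintf("mean Hb %.2f g/dL (births-weighted)\n",
              stats::weighted.mean(x$mean_hb, x$births_thousands)))
  print.data.frame(x, ...)
  invisible(x)
}
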