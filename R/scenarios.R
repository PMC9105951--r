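#' Policy scenarios on fortified infant cereal consumption
#'
#' A scenario is a transformation of the consumption profile and/or the
#' effect model:
#' \describe{
#'   \item{CURRENT}{identity — the observed consumption of one serving/day.}
#'   \item{NO_FORTIFICATION}{cereals are consumed but not fortified: the
#'     hemoglobin effect is zeroed (the counterfactual of Table-2-style
#'     comparisons).}
#'   \item{EXTEND_SHORT_PLUS2}{consumers of a short duration (below
#'     `short_duration_threshold`, default 3 months, i.e. 1--2 months)
#'     consume `extension` (default 2) months longer.}
#'   \item{LIFT_LOWEST_TO_MIDDLE}{the lowest wealth tertile's monthly
#'     consumption curve is replaced by the middle tertile's; its duration
#'     distribution is re-derived from the lifted curve by the survival
#'     construction ([duration_pmf_from_shares()]).}
#'   \item{LIFT_AND_EXTEND}{the lift plus an `extension` for lowest-tertile
#'     consumers below `short_duration_threshold` (default 5 months).}
#'   \item{TWO_SERVINGS_ALL_PLUS2}{every consumer takes two servings per day
#'     (halving the effect lag) and short consumers (below 3 months) get the
#'     `extension`.}
#' }
#'
#' @param kind scenario kind (see above; case-insensitive).
#' @param short_duration_threshold months; durations strictly below it count
#'   as "short". Defaults per kind: 3 for EXTEND_SHORT_PLUS2 and
#'   TWO_SERVINGS_ALL_PLUS2, 5 for LIFT_AND_EXTEND.
#' @param extension months added to short consumers' duration (default 2).
#' @return object of class `ida_scenario`.
#' @export
scenario <- function(kind, short_duration_threshold = NULL, extension = 2) {
  kinds <- c("CURRENT", "NO_FORTIFICATION", "EXTEND_SHORT_PLUS2",
             "LIFT_LOWEST_TO_MIDDLE", "LIFT_AND_EXTEND",
             "TWO_SERVINGS_ALL_PLUS2")
  kind <- toupper(kind)
  if (!kind %in% kinds)
    stop_validation("kind", paste("unknown scenario; expected one of",
                                  paste(kinds, collapse = ", ")))
  if (is.null(short_duration_threshold))
    short_duration_threshold <- switch(kind, LIFT_AND_EXTEND = 5,
                                       EXTEND_SHORT_PLUS2 = 3,
                                       TWO_SERVINGS_ALL_PLUS2 = 3, 0)
  check_number(short_duration_threshold, "short_duration_threshold", lower = 0)
  check_number(extension, "extension", lower = 0)
  structure(list(kind = kind,
                 short_duration_threshold = short_duration_threshold,
                 extension = extension),
            class = "ida_scenario")
}

as_scenario <- function(x) if (inherits(x, "ida_scenario")) x else scenario(x)

#' @export
print.ida_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s (short-duration threshold %g mo, extension %g mo)\n",
              x$kind, x$short_duration_threshold, x$extension))
  invisible(x)
}

#' Shift short consumers to longer durations in a duration pmf
#'
#' Mass at durations strictly between 0 and `threshold` moves to
#' `duration + extension`; never-consumers and longer consumers are
#' untouched.
#'
#' @param pmf named duration pmf.
#' @param threshold,extension months.
#' @return named duration pmf.
#' @export
extend_pmf <- function(pmf, threshold, extension) {
  pmf <- validate_duration_pmf(pmf)
  d <- as.numeric(names(pmf))
  d_new <- ifelse(d > 0 & d < threshold, d + extension, d)
  out <- tapply(as.numeric(pmf), d_new, sum)
  validate_duration_pmf(stats::setNames(as.numeric(out),
                                        names(out)))
}

#' Apply a scenario to consumption and effect inputs
#'
#' @param profile an `ida_consumption`.
#' @param model an `ida_effect`.
#' @param scn an `ida_scenario` (or kind string).
#' @return list with elements `profile` and `effect`, transformed. The
#'   profile's tertile share curves, overall duration pmf and servings are
#'   updated; lifted tertile duration distributions are re-derived from the
#'   share curves downstream (see [tertile_duration_pmfs()]).
#' @export
apply_scenario <- function(profile, model, scn) {
  scn <- as_scenario(scn)
  out_p <- profile
  out_m <- model
  switch(scn$kind,
    CURRENT = NULL,
    NO_FORTIFICATION = {
      out_m$max_effect <- 0
    },
    EXTEND_SHORT_PLUS2 = {
      out_p$duration_pmf <- extend_pmf(profile$duration_pmf,
                                       scn$short_duration_threshold,
                                       scn$extension)
    },
    LIFT_LOWEST_TO_MIDDLE = {
      out_p$share_tertile[, 1] <- profile$share_tertile[, 2]
    },
    LIFT_AND_EXTEND = {
      out_p$share_tertile[, 1] <- profile$share_tertile[, 2]
      out_p$duration_pmf <- extend_pmf(profile$duration_pmf,
                                       scn$short_duration_threshold,
                                       scn$extension)
    },
    TWO_SERVINGS_ALL_PLUS2 = {
      out_p$servings_per_day <- 2
      out_p$duration_pmf <- extend_pmf(profile$duration_pmf,
                                       scn$short_duration_threshold,
                                       scn$extension)
    })
  list(profile = out_p, effect = out_m)
}

scenario_restricts_to_lowest_tertile <- function(scn) {
  scn$kind %in% c("LIFT_LOWEST_TO_MIDDLE", "LIFT_AND_EXTEND")
}

tertile_weights <- function(population) {
  w <- tapply(population$births_thousands, population$tertile, sum)
  out <- numeric(3)
  out[as.integer(names(w))] <- as.numeric(w)
  out / sum(out)
}

#' Evaluate the IDA burden under a scenario
#'
#' Core of the comparative risk assessment. For each decile the observed
#' mean hemoglobin is first stripped of the current fortification effect
#' (expected effect under the tertile's current duration distribution),
#' giving an unexposed baseline; the scenario's duration distribution and
#' effect model are then layered back on as a normal mixture, classified
#' into anemia severities, restricted to the iron-deficiency share, and
#' passed through [compute_burden()]. Evaluating the CURRENT scenario
#' reproduces the observed distribution.
#'
#' @param population an `ida_population`.
#' @param profile an `ida_consumption` (current consumption).
#' @param effect an `ida_effect` (current dose-response).
#' @param params an `ida_parameters`.
#' @param scn an `ida_scenario` or kind string.
#' @param restrict_tertile optionally report only this wealth tertile's
#'   strata (tertile-lift scenarios default to tertile 1).
#' @return an `ida_burden`.
#' @export
evaluate_burden <- function(population, profile, effect, params, scn,
                            restrict_tertile = NULL) {
  scn <- as_scenario(scn)
  if (is.null(restrict_tertile) && scenario_restricts_to_lowest_tertile(scn))
    restrict_tertile <- 1L
  w <- tertile_weights(population)
  current_pmfs <- tertile_duration_pmfs(profile, w)
  applied <- apply_scenario(profile, effect, scn)
  scn_pmfs <- tertile_duration_pmfs(applied$profile, w)
  if (scn$kind %in% c("EXTEND_SHORT_PLUS2", "LIFT_AND_EXTEND",
                      "TWO_SERVINGS_ALL_PLUS2")) {
    idx <- if (scn$kind == "LIFT_AND_EXTEND") 1L else 1:3
    scn_pmfs[idx] <- lapply(scn_pmfs[idx], extend_pmf,
                            threshold = scn$short_duration_threshold,
                            extension = scn$extension)
  }
  strata <- population
  if (!is.null(restrict_tertile))
    strata <- population[population$tertile == restrict_tertile, ,
                         drop = FALSE]
  prev <- lapply(seq_len(nrow(strata)), function(i) {
    t <- strata$tertile[i]
    cur <- current_pmfs[[t]]
    mean_now <- sum(cur * fic_effect(as.numeric(names(cur)), effect,
                                     profile$servings_per_day))
    mean0 <- strata$mean_hb[i] - mean_now
    pmf <- scn_pmfs[[t]]
    mix <- hb_mixture(
      weight = as.numeric(pmf),
      mean = mean0 + fic_effect(as.numeric(names(pmf)), applied$effect,
                                applied$profile$servings_per_day),
      sd = strata$hb_sd[i],
      duration = as.numeric(names(pmf)))
    ida_prevalence(prevalence_from_distribution(mix, params$anemia_cutoffs),
                   params$ida_share)
  })
  compute_burden(strata, prev, params)
}

#' Compare two burden results
#'
#' Absolute differences are `baseline - alternative` per channel; percentage
#' differences are relative to the side representing current consumption
#' (`reference`), matching how published difference rows are expressed.
#'
#' @param baseline,alternative `ida_burden` objects (baseline is the
#'   higher-burden side in the conventional table layout).
#' @param reference `"baseline"` or `"alternative"`: which side is the
#'   current-consumption scenario used as the percentage denominator.
#' @param labels length-2 character labels for printing.
#' @return object of class `ida_comparison` with named vectors `baseline`,
#'   `alternative`, `difference`, `pct`.
#' @export
compare_burden <- function(baseline, alternative,
                           reference = c("baseline", "alternative"),
                           labels = c("baseline", "alternative")) {
  stopifnot(inherits(baseline, "ida_burden"),
            inherits(alternative, "ida_burden"))
  reference <- match.arg(reference)
  comp <- burden_components()
  b <- unlist(baseline[comp])
  a <- unlist(alternative[comp])
  d <- b - a
  ref <- if (reference == "baseline") b else a
  pct <- ifelse(ref == 0, 0, 100 * d / ref)
  structure(list(baseline = b, alternative = a, difference = d, pct = pct,
                 reference = reference, labels = labels),
            class = "ida_comparison")
}

#' @export
print.ida_comparison <- function(x, ...) {
  cat(render_comparison(x), sep = "\n")
  invisible(x)
}

#' Run the full scenario analysis
#'
#' Evaluates the current-consumption burden once and each requested scenario
#' once, pairing them as published: the no-fortification counterfactual is
#' compared as (no fortification) minus (current); improvement scenarios as
#' (current) minus (improved); tertile-lift scenarios restrict both sides to
#' the lowest wealth tertile. Deterministic given its inputs.
#'
#' @param population,profile,effect,params model inputs (see
#'   [evaluate_burden()]).
#' @param scenarios list of `ida_scenario` objects or kind strings; default
#'   all five non-identity kinds.
#' @return named list of `ida_comparison` objects.
#' @export
run_full_analysis <- function(population, profile, effect, params,
                              scenarios = c("NO_FORTIFICATION",
                                            "EXTEND_SHORT_PLUS2",
                                            "LIFT_LOWEST_TO_MIDDLE",
                                            "LIFT_AND_EXTEND",
                                            "TWO_SERVINGS_ALL_PLUS2")) {
  scenarios <- lapply(scenarios, as_scenario)
  current_all <- evaluate_burden(population, profile, effect, params,
                                 "CURRENT")
  current_t1 <- NULL
  out <- lapply(scenarios, function(s) {
    alt <- evaluate_burden(population, profile, effect, params, s)
    if (s$kind == "CURRENT")
      return(compare_burden(current_all, alt, reference = "baseline",
                            labels = c("Current consumption",
                                       "Current consumption")))
    if (scenario_restricts_to_lowest_tertile(s)) {
      if (is.null(current_t1))
        current_t1 <<- evaluate_burden(population, profile, effect, params,
                                       "CURRENT", restrict_tertile = 1L)
      compare_burden(current_t1, alt, reference = "baseline",
                     labels = c("Current consumption (lowest tertile)",
                                scenario_label(s)))
    } else if (s$kind == "NO_FORTIFICATION") {
      compare_burden(alt, current_all, reference = "alternative",
                     labels = c(scenario_label(s),
                                "With current level of consumption and fortification"))
    } else {
      compare_burden(current_all, alt, reference = "baseline",
                     labels = c("Current consumption", scenario_label(s)))
    }
  })
  names(out) <- vapply(scenarios, function(s) s$kind, character(1))
  out
}

scenario_label <- function(s) {
  switch(s$kind,
         CURRENT = "Current consumption",
         NO_FORTIFICATION = "Without fortification of infant cereals",
         EXTEND_SHORT_PLUS2 = "Increased duration of consumption",
         LIFT_LOWEST_TO_MIDDLE = "Increased consumption level",
         TWO_SERVINGS_ALL_PLUS2 = "Two servings per day",
         LIFT_AND_EXTEND = "Increased consumption level and duration")
}
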