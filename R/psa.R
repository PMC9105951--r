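#' Probabilistic sensitivity analysis specification
#'
#' Declares, per uncertain parameter, a sampling distribution for the Monte
#' Carlo probabilistic sensitivity analysis (PSA). Supported families:
#' `beta` (`shape1`, `shape2`), `gamma` (`shape`, `scale`), `lognormal`
#' (`meanlog`, `sdlog`), `normal` (`mean`, `sd`), `uniform` (`min`, `max`)
#' and `degenerate` (`value`). Optional `lower`/`upper` bounds truncate by
#' rejection. Parameter names address [default_parameters()] fields, the
#' disability weights as `dw_mild`/`dw_moderate`/`dw_severe`, and the effect
#' model's `max_effect`.
#'
#' Default distributions follow the parameters' nature: beta for
#' probabilities and weights, gamma for the wage, normal (centered on
#' 0.87 g/dL) for the hemoglobin effect, uniform over the 0.25--0.67
#' literature envelope for the iron-deficiency attribution share, and normal
#' for income growth. Draws are independent across parameters.
#'
#' @param n_draws number of model evaluations (default 10000).
#' @param seed integer RNG seed; every draw index is reproducible from it.
#' @param distributions named list of distribution specs (see above);
#'   defaults provided by `default_psa_distributions()`.
#' @return object of class `ida_psa_spec`.
#' @examples
#' spec <- psa_spec(n_draws = 100, seed = 7)
#' draw_parameters(spec, 1)$ida_share
#' @export
psa_spec <- function(n_draws = 10000, seed = 1,
                     distributions = default_psa_distributions()) {
  check_number(n_draws, "n_draws", lower = 1)
  check_number(seed, "seed")
  for (nm in names(distributions)) {
    d <- distributions[[nm]]
    if (is.null(d$family) ||
        !d$family %in% c("beta", "gamma", "lognormal", "normal",
                         "uniform", "degenerate"))
      stop_validation(nm, "unknown distribution family")
  }
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 distributions = distributions),
            class = "ida_psa_spec")
}

#' @rdname psa_spec
#' @export
default_psa_distributions <- function() {
  list(
    ida_share = list(family = "uniform", min = 0.25, max = 0.67),
    max_effect = list(family = "normal", mean = 0.87, sd = 0.1, lower = 0),
    dw_mild = list(family = "beta", shape1 = 4, shape2 = 996),
    dw_moderate = list(family = "beta", shape1 = 52, shape2 = 948),
    dw_severe = list(family = "beta", shape1 = 149, shape2 = 851),
    dw_cognitive = list(family = "beta", shape1 = 24, shape2 = 976),
    mortality_risk_severe = list(family = "beta", shape1 = 5, shape2 = 995),
    cognitive_income_loss = list(family = "beta", shape1 = 25, shape2 = 975),
    mean_monthly_wage_idr = list(family = "gamma", shape = 16,
                                 scale = 2.7e6 / 16),
    income_growth = list(family = "normal", mean = 0.04, sd = 0.01,
                         lower = 0)
  )
}

draw_one <- function(d, nm) {
  r <- function() switch(d$family,
    beta = stats::rbeta(1, d$shape1, d$shape2),
    gamma = stats::rgamma(1, shape = d$shape, scale = d$scale),
    lognormal = stats::rlnorm(1, d$meanlog, d$sdlog),
    normal = stats::rnorm(1, d$mean, d$sd),
    uniform = stats::runif(1, d$min, d$max),
    degenerate = d$value)
  lo <- if (is.null(d$lower)) -Inf else d$lower
  hi <- if (is.null(d$upper)) Inf else d$upper
  for (i in 1:1000) {
    x <- r()
    if (x >= lo && x <= hi) return(x)
  }
  stop_validation(nm, "truncation bounds rejected 1000 consecutive draws (unsatisfiable support)")
}

#' Draw one parameter set from a PSA specification
#'
#' Reproducible: the same `(seed, k)` always yields the same draw, whatever
#' order draws are requested in. The caller's RNG state is preserved.
#'
#' @param spec an `ida_psa_spec`.
#' @param k draw index (1-based).
#' @return named list of drawn parameter values.
#' @export
draw_parameters <- function(spec, k) {
  stopifnot(inherits(spec, "ida_psa_spec"))
  check_number(k, "k", lower = 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((spec$seed %% 1000003L) * 2011L + as.integer(k))
  lapply_named <- function(l, f) stats::setNames(
    lapply(names(l), function(nm) f(l[[nm]], nm)), names(l))
  lapply_named(spec$distributions, draw_one)
}

apply_draw <- function(params, effect, draw) {
  for (nm in names(draw)) {
    v <- draw[[nm]]
    if (nm == "max_effect") effect$max_effect <- v
    else if (nm == "dw_mild") params$disability_weights["mild"] <- v
    else if (nm == "dw_moderate") params$disability_weights["moderate"] <- v
    else if (nm == "dw_severe") params$disability_weights["severe"] <- v
    else if (nm %in% names(params)) params[[nm]] <- v
    else stop_validation(nm, "draw does not map to any model parameter")
  }
  params <- validate_parameters(unclass(params),
                                allow_ida_outside_envelope = TRUE)
  list(params = params, effect = effect)
}

#' Run the probabilistic sensitivity analysis
#'
#' Repeats the full burden evaluation under `spec$n_draws` parameter sets
#' drawn from the PSA distributions and summarizes each burden component by
#' its mean and empirical 2.5th/97.5th percentiles (a synthetic 95%
#' confidence interval, as published PSA clouds are summarized).
#'
#' @param population,profile,effect,params model inputs (point estimates;
#'   parameters not named in the spec stay fixed).
#' @param spec an `ida_psa_spec`.
#' @param scn scenario evaluated per draw (default `"CURRENT"`, the base
#'   case).
#' @param keep_draws retain the per-draw component matrix (needed by
#'   [plot.ida_psa()]).
#' @return object of class `ida_psa`: `summary` data frame (component, mean,
#'   lower, upper), `n_draws`, `seed`, and optionally `draws`.
#' @export
run_psa <- function(population, profile, effect, params,
                    spec = psa_spec(), scn = "CURRENT", keep_draws = TRUE) {
  scn <- as_scenario(scn)
  comp <- burden_components()
  draws <- matrix(NA_real_, nrow = spec$n_draws, ncol = length(comp),
                  dimnames = list(NULL, comp))
  for (k in seq_len(spec$n_draws)) {
    dk <- draw_parameters(spec, k)
    ap <- apply_draw(params, effect, dk)
    b <- evaluate_burden(population, profile, ap$effect, ap$params, scn)
    draws[k, ] <- unlist(b[comp])
  }
  q <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  summary <- data.frame(component = comp,
                        mean = unname(colMeans(draws)),
                        lower = q[1, ], upper = q[2, ],
                        row.names = NULL)
  structure(list(summary = summary, n_draws = spec$n_draws,
                 seed = spec$seed, scenario = scn$kind,
                 draws = if (keep_draws) draws),
            class = "ida_psa")
}

#' @export
print.ida_psa <- function(x, ...) {
  cat(sprintf("PSA (%d draws, seed %d, scenario %s); 95%% percentile intervals:\n",
              x$n_draws, x$seed, x$scenario))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-17s mean %10.1f  [%10.1f, %10.1f]\n",
                s$component[i], s$mean[i], s$lower[i], s$upper[i]))
  invisible(x)
}

#' @export
summary.ida_psa <- function(object, ...) object$summary

#' Scatter of economic versus health burden across PSA draws
#'
#' @param x an `ida_psa` run with `keep_draws = TRUE`.
#' @param ... passed to [plot()].
#' @export
plot.ida_psa <- function(x, ...) {
  if (is.null(x$draws))
    stop("run_psa(..., keep_draws = TRUE) is required for plotting")
  graphics::plot(x$draws[, "losses_total"], x$draws[, "dalys_total"],
                 xlab = "Production losses (millions USD)",
                 ylab = "DALYs (thousands)",
                 main = sprintf("PSA, %d draws", x$n_draws),
                 pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.4), ...)
  s <- x$summary
  graphics::abline(v = s$lower[s$component == "losses_total"], lty = 3)
  graphics::abline(v = s$upper[s$component == "losses_total"], lty = 3)
  graphics::abline(h = s$lower[s$component == "dalys_total"], lty = 3)
  graphics::abline(h = s$upper[s$component == "dalys_total"], lty = 3)
  invisible(x)
}
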