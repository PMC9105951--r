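#' Decile mean hemoglobin from child-level survey records
#'
#' Fits a linear model of altitude-adjusted hemoglobin on socioeconomic
#' decile indicators (no intercept), so each coefficient is the decile mean,
#' and propagates standard errors by the delta method for an optional
#' transformation of the mean (identity by default, in which case the delta
#' method reduces to the usual coefficient standard error).
#'
#' @param survey data frame with columns `decile` (1--10) and `hb_adjusted`
#'   (altitude-adjusted hemoglobin, g/dL); [generate_survey()] output works
#'   directly.
#' @param transform optional function g applied to each decile mean; the
#'   reported standard error is |g'(mean)| * SE(mean), with g' obtained by
#'   central finite differencing.
#' @return object of class `ida_decile_means`: a data frame with columns
#'   `decile`, `n`, `mean_hb`, `se` and `reliable` (`FALSE` for single-child
#'   strata, whose residual-based standard error is undefined).
#' @examples
#' svy <- generate_survey(survey_config(n_children = 2000, seed = 1))
#' estimate_decile_means(svy)
#' @export
estimate_decile_means <- function(survey, transform = NULL) {
  if (!all(c("decile", "hb_adjusted") %in% names(survey)))
    stop_validation("survey", "needs columns decile and hb_adjusted")
  present <- sort(unique(survey$decile))
  absent <- setdiff(1:10, present)
  if (length(absent))
    stop_validation("decile", paste("strata absent from survey:",
                                    paste(absent, collapse = ", ")))
  f <- factor(survey$decile, levels = 1:10)
  fit <- stats::lm(hb_adjusted ~ 0 + f, data = data.frame(
    hb_adjusted = survey$hb_adjusted, f = f))
  mu <- unname(stats::coef(fit))
  # a zero-residual survey (constant strata) is a valid degenerate input;
  # summary.lm's perfect-fit warning is uninformative here
  se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit)))))
  n <- as.integer(table(f))
  # single-observation strata: mean is the value itself, SE unreliable
  reliable <- n > 1L
  se[!reliable] <- NA_real_
  if (!is.null(transform)) {
    h <- pmax(abs(mu), 1) * 1e-6
    grad <- (vapply(mu + h, transform, numeric(1)) -
               vapply(mu - h, transform, numeric(1))) / (2 * h)
    mu <- vapply(mu, transform, numeric(1))
    se <- abs(grad) * se
  }
  structure(data.frame(decile = 1:10, n = n, mean_hb = mu, se = se,
                       reliable = reliable),
            class = c("ida_decile_means", "data.frame"),
            sigma = stats::sigma(fit))
}

#' @export
print.ida_decile_means <- function(x, ...) {
  cat("Decile mean Hb (g/dL), delta-method standard errors:\n")
  print.data.frame(
    data.frame(decile = x$decile, n = x$n,
               mean_hb = round(x$mean_hb, 3),
               se = signif(x$se, 3),
               reliable = x$reliable),
    row.names = FALSE, ...)
  invisible(x)
}
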