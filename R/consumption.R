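#' Fortified infant cereal consumption profile
#'
#' Holds the share of children consuming fortified infant cereals (FIC) at
#' each month of age 6--23, overall and by wealth tertile, together with the
#' population distribution of total consumption duration (months, 0--18) and
#' the assumed number of daily servings. The packaged fixture encodes the
#' survey anchors: 74% ever-consumers; overall monthly shares 46% at month 6,
#' a 63% peak at month 7, 25% at 12, 13% at 18 and 9% at 23; tertile shares
#' 39/49/52% at month 6 and 18/26/28% at month 12; duration bands 26% never,
#' 17% under 3 months, 21% 3--5, 25% 6--11, 11% 12 months or longer (spread
#' uniformly within bands). Months between anchors are linearly interpolated.
#'
#' @param months integer vector of months of age (must be 6:23).
#' @param share_overall fraction consuming at each month, overall.
#' @param share_tertile 18 x 3 matrix (or data frame) of per-tertile shares.
#' @param duration_pmf named numeric vector over durations `"0"`..`"18"`
#'   summing to 1 (within 1e-9).
#' @param servings_per_day positive real; 1 is the observed norm.
#' @return object of class `ida_consumption`.
#' @examples
#' prof <- load_consumption(ida_fixture("consumption"))
#' consumer_fraction(prof)        # 0.74
#' duration_median(prof)          # 5 months among consumers
#' @export
consumption_profile <- function(months, share_overall, share_tertile,
                                duration_pmf, servings_per_day = 1) {
  months <- as.integer(months)
  if (!identical(months, 6:23))
    stop_validation("months", "profile must cover months of age 6..23")
  check_fraction(share_overall, "share_overall")
  share_tertile <- as.matrix(share_tertile)
  if (!all(dim(share_tertile) == c(18L, 3L)))
    stop_validation("share_tertile", "must be 18 months x 3 tertiles")
  check_fraction(as.numeric(share_tertile), "share_tertile")
  dimnames(share_tertile) <- list(month = months, tertile = 1:3)
  duration_pmf <- validate_duration_pmf(duration_pmf)
  check_number(servings_per_day, "servings_per_day", lower = 0,
               strict_lower = TRUE)
  structure(list(months = months,
                 share_overall = stats::setNames(share_overall, months),
                 share_tertile = share_tertile,
                 duration_pmf = duration_pmf,
                 servings_per_day = servings_per_day),
            class = "ida_consumption")
}

validate_duration_pmf <- function(pmf, field = "duration_pmf") {
  if (is.null(names(pmf))) names(pmf) <- seq_along(pmf) - 1L
  d <- as.integer(names(pmf))
  if (anyNA(d) || any(d < 0))
    stop_validation(field, "durations must be named non-negative months")
  check_fraction(as.numeric(pmf), field)
  if (abs(sum(pmf) - 1) > 1e-9)
    stop_validation(field, sprintf("must sum to 1, got %.12f", sum(pmf)))
  pmf[order(d)]
}

#' @rdname consumption_profile
#' @param profile an `ida_consumption`.
#' @export
consumer_fraction <- function(profile) {
  unname(1 - profile$duration_pmf["0"])
}

#' Median consumption duration
#'
#' @param profile an `ida_consumption`.
#' @param among `"consumers"` (default; never-consumers excluded, matching
#'   how survey medians of consumption duration are reported) or
#'   `"population"`.
#' @return median duration in months (smallest duration with cumulative
#'   probability >= 0.5).
#' @export
duration_median <- function(profile, among = c("consumers", "population")) {
  among <- match.arg(among)
  pmf <- profile$duration_pmf
  if (among == "consumers") {
    pmf <- pmf[names(pmf) != "0"]
    if (sum(pmf) <= 0) return(NA_real_)
    pmf <- pmf / sum(pmf)
  }
  d <- as.numeric(names(pmf))
  d[which(cumsum(pmf) >= 0.5 - 1e-12)[1]]
}

#' Duration distribution from a monthly consumption curve
#'
#' Treats the share consuming at month `m` as the probability of still
#' consuming at that month (a survival curve, monotonized from the right
#' because observed curves peak after month 6), anchors consumption at month
#' 6, and converts to a duration probability mass function. The never-
#' consumer mass is pinned to `1 - consumer_frac` and the conditional
#' duration shape is taken from the normalized survival decrements, so churn
#' (ever-consumers exceeding the peak monthly share) is preserved.
#'
#' @param shares numeric vector of monthly shares for months 6..23.
#' @param consumer_frac fraction ever consuming, in (0,1].
#' @return named pmf over durations 0..18.
#' @export
duration_pmf_from_shares <- function(shares, consumer_frac) {
  check_fraction(shares, "shares")
  check_fraction(consumer_frac, "consumer_frac")
  n <- length(shares)
  if (n != 18L) stop_validation("shares", "expected 18 monthly shares (6..23)")
  if (consumer_frac == 0 || all(shares == 0))
    return(validate_duration_pmf(stats::setNames(c(1, rep(0, 18)), 0:18)))
  surv <- rev(cummax(rev(shares)))        # monotone non-increasing
  surv <- surv / surv[1]                  # P(duration >= k | consumer), k=1..18
  dec <- c(surv, 0)                       # survival at k = 1..19 (19 -> 0)
  p_cond <- -diff(dec)                    # P(duration = k | consumer), k=1..18
  pmf <- c(1 - consumer_frac, consumer_frac * p_cond)
  validate_duration_pmf(stats::setNames(pmf, 0:18))
}

#' Per-tertile duration distributions
#'
#' Ever-consumer fractions per tertile are proportional to the tertile's
#' peak monthly share and normalized so the weighted mean equals the overall
#' ever-consumer fraction; conditional duration shapes come from each
#' tertile's survival curve via [duration_pmf_from_shares()].
#'
#' @param profile an `ida_consumption`.
#' @param weights tertile population weights (length 3, summing to 1).
#' @return list of three duration pmfs (durations 0..18).
#' @export
tertile_duration_pmfs <- function(profile, weights) {
  check_fraction(weights, "weights")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_validation("weights", "tertile weights must sum to 1")
  peaks <- apply(profile$share_tertile, 2, max)
  overall_c <- consumer_fraction(profile)
  denom <- sum(weights * peaks)
  cf <- if (denom > 0) pmin(1, overall_c * peaks / denom) else rep(0, 3)
  lapply(1:3, function(t)
    duration_pmf_from_shares(profile$share_tertile[, t], cf[t]))
}

#' Read a consumption profile from a YAML file
#'
#' @param path YAML file with fields `months`, `share_overall`,
#'   `share_tertile` (list of three 18-vectors), `duration_pmf` (map
#'   duration -> probability), `servings_per_day`.
#' @return an `ida_consumption`.
#' @export
load_consumption <- function(path) {
  if (!file.exists(path)) stop_validation("path", paste("no such file:", path))
  y <- yaml::read_yaml(path)
  pmf <- unlist(y$duration_pmf)
  consumption_profile(
    months = unlist(y$months),
    share_overall = unlist(y$share_overall),
    share_tertile = cbind(unlist(y$share_tertile$t1),
                          unlist(y$share_tertile$t2),
                          unlist(y$share_tertile$t3)),
    duration_pmf = pmf,
    servings_per_day = if (is.null(y$servings_per_day)) 1
                       else y$servings_per_day)
}

#' Write a consumption profile to YAML
#'
#' @param profile an `ida_consumption`.
#' @param path output path.
#' @export
write_consumption <- function(profile, path) {
  stopifnot(inherits(profile, "ida_consumption"))
  y <- list(
    months = as.integer(profile$months),
    share_overall = unname(profile$share_overall),
    share_tertile = list(t1 = unname(profile$share_tertile[, 1]),
                         t2 = unname(profile$share_tertile[, 2]),
                         t3 = unname(profile$share_tertile[, 3])),
    duration_pmf = as.list(profile$duration_pmf),
    servings_per_day = profile$servings_per_day)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' @export
print.ida_consumption <- function(x, ...) {
  cat(sprintf(
    "FIC consumption profile: %.0f%% ever-consumers, median duration %g mo",
    100 * consumer_fraction(x), duration_median(x)),
    sprintf("(consumers), %g serving(s)/day\n", x$servings_per_day))
  cat(sprintf("  monthly share: %.0f%% at month 6, peak %.0f%% at month %d\n",
              100 * x$share_overall[1], 100 * max(x$share_overall),
              x$months[which.max(x$share_overall)]))
  invisible(x)
}
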