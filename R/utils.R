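stop_validation <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (length(x) == 0L || anyNA(x) || !is.numeric(x))
    stop_validation(field, "must be a non-missing number")
  bad_lo <- if (strict_lower) any(x <= lower) else any(x < lower)
  bad_hi <- if (strict_upper) any(x >= upper) else any(x > upper)
  if (bad_lo || bad_hi)
    stop_validation(field, sprintf(
      "must lie in %s%s, %s%s; got %s",
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]",
      paste(format(x[ (if (strict_lower) x <= lower else x < lower) |
                      (if (strict_upper) x >= upper else x > upper) ]),
            collapse = ", ")))
  invisible(x)
}

check_fraction <- function(x, field) check_number(x, field, 0, 1)

#' @importFrom stats setNames
severity_levels <- function() c("none", "mild", "moderate", "severe")
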