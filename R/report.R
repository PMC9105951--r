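format_level <- function(x) sprintf("%.1f", x)

# differences: published convention rounds to integers once >= 10,
# one decimal below
format_diff <- function(x) ifelse(abs(x) >= 10, sprintf("%.0f", x),
                                  sprintf("%.1f", x))

format_diff_cell <- function(diff, pct) {
  sprintf("%s (%.1f%%)", format_diff(diff), pct)
}

loss_channels <- function() c(losses_cognitive = "Cognitive impairment",
                              losses_mortality = "Mortality",
                              losses_total = "Total")

daly_channels <- function() c(dalys_physical = "Impaired physical activity",
                              dalys_cognitive = "Cognitive impairment",
                              dalys_mortality = "Mortality",
                              dalys_total = "Total")

render_block <- function(x, keys, title) {
  ref_first <- x$reference == "baseline"
  rows <- if (ref_first) list(first = x$baseline, second = x$alternative)
          else list(first = x$alternative, second = x$baseline)
  labs <- if (ref_first) x$labels else rev(x$labels)
  widths <- pmax(nchar(keys), 12L)
  pad <- function(cells) paste(mapply(formatC, cells, width = widths),
                               collapse = "  ")
  c(title,
    paste0(formatC("", width = 44), "  ", pad(unname(keys))),
    paste0(formatC(labs[1], width = 44, flag = "-"), "  ",
           pad(format_level(rows$first[names(keys)]))),
    paste0(formatC(labs[2], width = 44, flag = "-"), "  ",
           pad(format_level(rows$second[names(keys)]))),
    paste0(formatC("Difference (%)", width = 44, flag = "-"), "  ",
           pad(format_diff_cell(x$difference[names(keys)],
                                x$pct[names(keys)]))))
}

render_comparison <- function(x) {
  c(render_block(x, loss_channels(),
                 "Production losses (millions of U.S. dollars)"),
    "",
    render_block(x, daly_channels(), "DALYs (thousands)"))
}

#' Render scenario comparisons as text tables
#'
#' Produces the published two-block layout (production losses in millions of
#' USD; DALYs in thousands) per comparison, with a `Difference (%)` row.
#' Levels print with one decimal; differences print as integers once they
#' reach 10 and with one decimal below. Rendering is pure: the same results
#' yield byte-identical text.
#'
#' @param results list of `ida_comparison` objects (named by scenario), as
#'   returned by [scenario_analysis()].
#' @param psa optional `ida_psa`; appends 95% interval lines per output.
#' @param file optional path; when given the report is also written there.
#' @return character vector of report lines, invisibly when `file` is set.
#' @export
render_tables <- function(results, psa = NULL, file = NULL) {
  if (inherits(results, "ida_comparison")) results <- list(results)
  if (length(results) == 0L)
    stop_validation("results", "must contain at least one comparison")
  nm <- names(results)
  lines <- character(0)
  for (i in seq_along(results)) {
    header <- if (!is.null(nm) && nzchar(nm[i]))
      sprintf("== Scenario %s ==", nm[i]) else sprintf("== Comparison %d ==", i)
    lines <- c(lines, header, render_comparison(results[[i]]), "")
  }
  if (!is.null(psa)) {
    lines <- c(lines, sprintf(
      "== Probabilistic sensitivity analysis (%d draws, seed %d) ==",
      psa$n_draws, psa$seed))
    s <- psa$summary
    lines <- c(lines, vapply(seq_len(nrow(s)), function(i)
      sprintf("%s: mean %s, 95%% interval [%s, %s]",
              s$component[i], format_level(s$mean[i]),
              format_level(s$lower[i]), format_level(s$upper[i])),
      character(1)))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Write a comparison to CSV
#'
#' One row per burden component with baseline, alternative, absolute and
#' percentage difference at full precision.
#'
#' @param x an `ida_comparison`.
#' @param path output CSV path.
#' @export
write_comparison_csv <- function(x, path) {
  stopifnot(inherits(x, "ida_comparison"))
  df <- data.frame(component = burden_components(),
                   baseline = unname(x$baseline),
                   alternative = unname(x$alternative),
                   difference = unname(x$difference),
                   pct = unname(x$pct))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
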