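.cc_component_labels <- c(
  absenteeism = "Cost of absenteeism",
  presenteeism = "Cost of presenteeism",
  turnover = "Cost of staff turnover",
  intervention = "Intervention cost"
)

#' Round half away from zero
#'
#' Commercial rounding used at the report layer: exact halves move away
#' from zero (-130.375 -> -130 at 0 digits is truncation of the half rule;
#' 4.6 -> 5; -22,099.5 -> -22,100), unlike [round()]'s round-half-even.
#' Model arithmetic is never rounded; only displayed values are.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep (default 0 = whole currency units).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format currency for display
#'
#' @param x Numeric vector (currency units).
#' @param symbol Currency symbol prefix.
#' @param exact If `TRUE`, print the exact value; otherwise round half
#'   away from zero to whole units first (report convention).
#' @return Character vector like `"-£5,215"`.
#' @export
format_currency <- function(x, symbol = "£", exact = FALSE) {
  shown <- if (exact) x else round_half_away(x)
  vapply(shown, function(v) {
    body <- if (exact && v != trunc(v))
      formatC(abs(v), format = "f", digits = 2, big.mark = ",")
    else
      formatC(abs(v), format = "d", big.mark = ",")
    paste0(if (v < 0) "-" else "", symbol, body)
  }, "")
}

#' Render evaluated scenarios as a rounded report table
#'
#' Builds the presentation-layer table: one row per modelled component per
#' scenario, then "Total costs" and "Net cost per person" summary rows.
#' Currency values are rounded half away from zero to whole units at this
#' point only; the total row is the rounding of the exact total, never the
#' sum of the rounded component rows. Components a scenario does not model
#' are omitted from its rows.
#'
#' @param results A `cc_result` or a list of them.
#' @return A `cc_report` data frame with columns `scenario`, `item`,
#'   `cost` (rounded whole currency units). Print it for a formatted
#'   table, or pass to [write_report_csv()].
#' @examples
#' render_results(lapply(bundled_scenarios(), evaluate_scenario))
#' @export
render_results <- function(results) {
  if (inherits(results, "cc_result")) results <- list(results)
  if (!length(results)) {
    out <- data.frame(scenario = character(), item = character(),
                      cost = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("cc_report", "data.frame")
    return(out)
  }
  rows <- lapply(results, function(r) {
    if (!inherits(r, "cc_result"))
      cc_abort("'results' must contain 'cc_result' objects",
               "wellcost_validation_error")
    items <- c(unname(.cc_component_labels[names(r$components)]),
               "Total costs", "Net cost per person")
    vals <- c(unname(r$components), r$total, r$net_per_person)
    data.frame(scenario = r$scenario$name, item = items,
               cost = round_half_away(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cc_report", "data.frame")
  out
}

#' @export
print.cc_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("Empty cost-consequence report.\n")
    return(invisible(x))
  }
  for (sc in unique(x$scenario)) {
    cat(sc, "\n", sep = "")
    sub <- x[x$scenario == sc, , drop = FALSE]
    width <- max(nchar(sub$item))
    for (i in seq_len(nrow(sub))) {
      emph <- sub$item[i] %in% c("Total costs", "Net cost per person")
      cat(sprintf("  %-*s  %12s%s\n", width, sub$item[i],
                  format_currency(sub$cost[i]), if (emph) "  *" else ""))
    }
  }
  cat("* summary row; savings shown as negative incremental costs\n")
  invisible(x)
}

#' Write a report or tornado table as CSV
#'
#' Plain CSV serialisation of the rounded report table
#' ([render_results()]) or of a tornado table ([tornado()]); one row per
#' table row, no row names. Output is byte-stable for identical input.
#'
#' @param x A `cc_report` or `cc_tornado` data frame.
#' @param file Path or connection to write to.
#' @return `x`, invisibly.
#' @export
write_report_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(x)
}
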