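#' Consumer price index series
#'
#' A price index series maps calendar years to (annual-average) index
#' values, used to restate unit costs between price years — the usual
#' CPIH-style uplift applied to published unit costs before they enter a
#' decision model. Index values are dimensionless and must be positive;
#' only the ratio between two years matters.
#'
#' @param years Integer vector of calendar years (unique).
#' @param values Positive numeric index values, one per year.
#' @return A `price_index` object (named numeric vector, names = years).
#' @seealso [inflate()], [read_price_index()]
#' @export
price_index <- function(years, values) {
  if (length(years) != length(values) || !length(years))
    cc_abort("'years' and 'values' must be non-empty and of equal length",
             "wellcost_validation_error")
  years <- as.integer(years)
  if (anyNA(years) || anyDuplicated(years))
    cc_abort("'years' must be unique integer calendar years",
             "wellcost_validation_error", field = "year")
  if (!is.numeric(values) || anyNA(values) || any(values <= 0))
    cc_abort("index values must all be positive",
             "wellcost_validation_error", field = "index")
  ord <- order(years)
  structure(as.numeric(values)[ord], names = as.character(years[ord]),
            class = "price_index")
}

#' Read a price index series from a delimited text file
#'
#' Expects a two-column file (year, index) with a header row; comma, tab
#' or whitespace separated.
#'
#' @param path Path to the file.
#' @return A [price_index()] object.
#' @export
read_price_index <- function(path) {
  if (!file.exists(path))
    cc_abort(sprintf("price index file not found: '%s'", path),
             "wellcost_file_error", path = path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE),
    error = function(e) cc_abort(
      sprintf("cannot parse price index file '%s': %s", path, conditionMessage(e)),
      "wellcost_parse_error", path = path)
  )
  if (ncol(df) < 2L)
    cc_abort(sprintf("price index file '%s' must have two columns (year, index)", path),
             "wellcost_parse_error", path = path)
  price_index(df[[1]], df[[2]])
}

#' @export
print.price_index <- function(x, ...) {
  cat(sprintf("Price index series, %d year(s) [%s-%s]\n",
              length(x), names(x)[1], names(x)[length(x)]))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Restate an amount between price years
#'
#' Multiplies `amount` by the ratio of the index values of the target and
#' source years: `amount * series[year_to] / series[year_from]`. Full
#' precision, no rounding; the operation is linear in the amount and
#' composes multiplicatively across years, so inflating a -> b -> a is an
#' exact round trip up to floating point.
#'
#' @param amount Currency amount(s) expressed in `year_from` prices.
#' @param year_from,year_to Calendar years; both must be present in the
#'   series (annual-average indices, no interpolation).
#' @param series A [price_index()] object.
#' @return `amount` restated in `year_to` prices.
#' @examples
#' cpih <- price_index(2017:2019, c(100, 102.5, 104.1))
#' inflate(250, 2017, 2019, cpih)
#' @export
inflate <- function(amount, year_from, year_to, series) {
  if (!inherits(series, "price_index"))
    cc_abort("'series' must be a 'price_index' object", "wellcost_validation_error")
  if (!is.numeric(amount) || anyNA(amount))
    cc_abort("'amount' must be numeric", "wellcost_validation_error")
  lookup <- function(year) {
    key <- as.character(as.integer(year))
    if (!key %in% names(series))
      cc_abort(sprintf("year %s is not in the price index series", key),
               "wellcost_lookup_error", year = year)
    unname(series[[key]])
  }
  amount * lookup(year_to) / lookup(year_from)
}
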