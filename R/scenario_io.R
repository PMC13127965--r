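.cc_scenario_keys <- c("name", "n_participants", "cost_per_person",
                       "fixed_cost", "unit_costs", "effects")
.cc_config_keys <- c("scenarios", "dsa_ranges")
.cc_range_keys <- c("parameter", "low", "high")

.check_keys <- function(x, allowed, where) {
  if (!is.list(x))
    cc_abort(sprintf("%s must be a mapping/object", where),
             "wellcost_parse_error")
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    cc_abort(sprintf("unknown key(s) in %s: %s", where,
                     paste(bad, collapse = ", ")),
             "wellcost_parse_error", keys = bad)
  invisible(x)
}

.parse_config_text <- function(text, format, source = "<config>") {
  parse_err <- function(e) cc_abort(
    sprintf("cannot parse %s: %s", source, conditionMessage(e)),
    "wellcost_parse_error", path = source)
  switch(format,
    json = tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                    error = parse_err),
    yaml = tryCatch(yaml::yaml.load(text), error = parse_err)
  )
}

#' Read scenario configurations from a file
#'
#' Parses a scenario configuration file — YAML or JSON, chosen by file
#' extension (`.json` vs anything else) — and validates every scenario
#' against the model's type invariants. Parsing is strict: unknown keys
#' are rejected with an error naming them, so a typo never silently drops
#' an input.
#'
#' The schema is a top-level `scenarios` list, each entry with keys
#' `name`, `n_participants`, optional `cost_per_person` and `fixed_cost`
#' (default 0), and optional `unit_costs` / `effects` mappings using the
#' identifiers in [cc_parameters]. An optional top-level `dsa_ranges`
#' list (`parameter`, `low`, `high` per entry) supplies per-parameter
#' sensitivity ranges and is returned as the `"dsa_ranges"` attribute.
#'
#' @param path Path to the configuration file.
#' @return Named list of `cc_scenario` objects (possibly empty), with a
#'   `dsa_ranges` attribute (data frame or `NULL`).
#' @seealso [write_scenarios()], [bundled_scenarios()]
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path))
    cc_abort(sprintf("config file not found: '%s'", path),
             "wellcost_file_error", path = path)
  format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  raw <- .parse_config_text(paste(readLines(path, warn = FALSE), collapse = "\n"),
                            format, source = path)
  if (is.null(raw)) raw <- list()
  .check_keys(raw, .cc_config_keys, sprintf("config '%s'", path))
  entries <- raw$scenarios
  if (is.null(entries)) entries <- list()
  if (!is.list(entries))
    cc_abort(sprintf("'scenarios' in '%s' must be a list", path),
             "wellcost_parse_error", path = path)
  scenarios <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    .check_keys(e, .cc_scenario_keys, sprintf("scenario entry %d", i))
    if (is.null(e$name))
      cc_abort(sprintf("scenario entry %d has no 'name'", i),
               "wellcost_validation_error", field = "name")
    cc_scenario(
      name = e$name,
      n_participants = e$n_participants %||% NA_real_,
      cost_per_person = e$cost_per_person %||% 0,
      fixed_cost = e$fixed_cost %||% 0,
      unit_costs = lapply(e$unit_costs %||% list(), as.numeric),
      effects = lapply(e$effects %||% list(), as.numeric)
    )
  })
  names(scenarios) <- vapply(scenarios, `[[`, "", "name")
  structure(scenarios, dsa_ranges = .parse_dsa_ranges(raw$dsa_ranges))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_dsa_ranges <- function(entries) {
  if (is.null(entries) || !length(entries)) return(NULL)
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    .check_keys(e, .cc_range_keys, sprintf("dsa_ranges entry %d", i))
    if (is.null(e$parameter) || !e$parameter %in% cc_parameters)
      cc_abort(sprintf("dsa_ranges entry %d: unknown or missing parameter '%s'",
                       i, e$parameter %||% "<missing>"),
               "wellcost_validation_error", field = "parameter")
    low <- as.numeric(e$low %||% NA_real_)
    high <- as.numeric(e$high %||% NA_real_)
    if (is.na(low) || is.na(high) || low > high)
      cc_abort(sprintf("dsa_ranges entry %d ('%s'): need low <= high",
                       i, e$parameter),
               "wellcost_validation_error", field = e$parameter)
    data.frame(parameter = e$parameter, low = low, high = high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.scenario_to_list <- function(s) {
  out <- list(name = s$name, n_participants = s$n_participants,
              cost_per_person = s$cost_per_person, fixed_cost = s$fixed_cost)
  if (length(s$unit_costs)) out$unit_costs <- s$unit_costs
  if (length(s$effects)) out$effects <- s$effects
  out
}

#' Write scenarios to a configuration file
#'
#' Serialises scenarios in the same schema [read_scenarios()] reads, so
#' that write-then-read is an identity round trip.
#'
#' @param scenarios A `cc_scenario` or list of them.
#' @param path Output file path; `.json` selects JSON, otherwise YAML.
#' @param dsa_ranges Optional data frame (`parameter`, `low`, `high`)
#'   stored as the config's `dsa_ranges` section.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path, dsa_ranges = NULL) {
  if (inherits(scenarios, "cc_scenario")) scenarios <- list(scenarios)
  body <- list(scenarios = lapply(unname(scenarios), .scenario_to_list))
  if (!is.null(dsa_ranges) && NROW(dsa_ranges))
    body$dsa_ranges <- lapply(seq_len(nrow(dsa_ranges)), function(i)
      list(parameter = dsa_ranges$parameter[i], low = dsa_ranges$low[i],
           high = dsa_ranges$high[i]))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    writeLines(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  } else {
    yaml::write_yaml(body, path, precision = 15)
  }
  invisible(path)
}

#' The six bundled hypothetical case studies
#'
#' Returns the package's bundled fixtures: a base case (50 participants,
#' a £100-per-person intervention, reductions of 4.3 absenteeism days and
#' 9.6 presenteeism days valued at £189.76 and £379.51 per day, and a
#' £18,488.43 turnover unit cost with no modelled turnover effect) plus
#' five contrasting scenarios spanning company sizes from 5 to 600
#' participants, opt-in participation (75 of a 250-person company),
#' lump-sum intervention funding, turnover-only benefits, and a scenario
#' in which absenteeism worsens by 0.3 days while presenteeism improves.
#'
#' The fixtures are read from the package's installed YAML config, so
#' they exercise the same strict reader as user-supplied files.
#'
#' @return Named list of six `cc_scenario` objects: `base_case`,
#'   `scenario_1` ... `scenario_5`.
#' @examples
#' names(bundled_scenarios())
#' @export
bundled_scenarios <- function() {
  path <- system.file("extdata", "case_studies.yaml", package = "wellcost",
                      mustWork = TRUE)
  out <- read_scenarios(path)
  attr(out, "dsa_ranges") <- NULL
  out
}
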