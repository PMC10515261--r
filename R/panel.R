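#' Multi-region annual rate panels
#'
#' A `riskcast_panel` holds one annual series per region on a shared year
#' grid.  Internally it is a long tibble with columns `region`, `code`,
#' `year`, `value`, completed over `regions x years` so that gaps are explicit
#' `NA` values and never silently zero-filled.  The `units` attribute is one
#' of `"count"`, `"percent"` (percent of local population per year),
#' `"per100k"` (converted to percent on load) or `"scaled"` (after division
#' by hazard limits).
#'
#' @param data Tibble with columns `region`, `year`, `value` and optionally
#'   `code`.
#' @param units Units string.
#' @param scaled Logical; `TRUE` once hazard-limit scaling has been applied.
#' @param meta Free-form provenance list.
#' @param allow_negative Permit negative values.  Observed mortality panels
#'   are non-negative by definition; simulation studies with unbounded
#'   marginals (e.g. a standard Gumbel) set this to `TRUE`.
#' @return A `riskcast_panel` object.
#' @export
as_panel <- function(data, units = "percent", scaled = FALSE, meta = list(),
                     allow_negative = FALSE) {
  stopifnot(is.data.frame(data), all(c("region", "year", "value") %in% names(data)))
  data <- tibble::as_tibble(data)
  if (!"code" %in% names(data)) data$code <- NA_character_
  if (!allow_negative && any(data$value < 0, na.rm = TRUE)) {
    stop_riskcast("panel values must be non-negative", "riskcast_integrity_error")
  }
  dup <- data[c("region", "year")][duplicated(data[c("region", "year")]), ]
  if (nrow(dup) > 0) {
    stop_riskcast(
      sprintf(
        "duplicate (region, year) observations: %s",
        paste(sprintf("(%s, %d)", dup$region, dup$year), collapse = ", ")
      ),
      "riskcast_integrity_error"
    )
  }
  codes <- data |>
    dplyr::filter(!is.na(.data$code)) |>
    dplyr::distinct(.data$region, .data$code)
  data <- data |>
    dplyr::select("region", "year", "value") |>
    tidyr::complete(region = unique(data$region), year = seq(min(data$year), max(data$year))) |>
    dplyr::left_join(codes, by = "region") |>
    dplyr::select("region", "code", "year", "value") |>
    dplyr::arrange(.data$region, .data$year)
  structure(
    list(data = data, units = units, scaled = scaled, meta = meta),
    class = "riskcast_panel"
  )
}

#' @export
print.riskcast_panel <- function(x, ...) {
  yr <- panel_year_range(x)
  cat(sprintf(
    "<riskcast_panel> %d regions, years %d-%d, units=%s%s, %d missing cells\n",
    dplyr::n_distinct(x$data$region), yr[1], yr[2], x$units,
    if (x$scaled) " (hazard-scaled)" else "",
    sum(is.na(x$data$value))
  ))
  invisible(x)
}

#' @export
#' @rdname as_panel
panel_year_range <- function(data) {
  if (inherits(data, "riskcast_panel")) data <- data$data
  range(data$year)
}

#' Region identifiers of a panel
#' @param panel A `riskcast_panel`.
#' @return Character vector of region ids.
#' @export
panel_regions <- function(panel) unique(panel$data$region)

default_schema <- list(region = "Entity", code = "Code", year = "Year")

#' Load a long-format country-year panel from CSV
#'
#' Reads a long-format CSV (default column names `Entity`, `Code`, `Year`,
#' matching the common public-health export format) into a [as_panel()]
#' panel.  Values given per 100,000 population are converted to percent of
#' population (x 1e-3) so that the canonical internal unit is always percent.
#'
#' @param path CSV file path.
#' @param value_col Name of the value column.
#' @param units Units of the value column: `"count"`, `"percent"` or
#'   `"per100k"`.
#' @param schema Optional column-name mapping overriding `Entity`/`Code`/
#'   `Year`; a list with elements `region`, `year` and optionally `code`.
#' @return A `riskcast_panel`.
#' @export
load_panel <- function(path, value_col, units = c("percent", "count", "per100k"),
                       schema = default_schema) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    stop_riskcast(sprintf("file not found: %s", path), "riskcast_schema_error")
  }
  schema <- utils::modifyList(default_schema, schema)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c(schema$region, schema$year, value_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_riskcast(
      sprintf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")),
      "riskcast_schema_error"
    )
  }
  value_chr <- raw[[value_col]]
  value <- suppressWarnings(as.numeric(value_chr))
  bad <- which(!is.na(value_chr) & value_chr != "" & is.na(value))
  if (length(bad) > 0) {
    stop_riskcast(
      sprintf("non-numeric value in column '%s' at data row(s): %s",
              value_col, paste(bad, collapse = ", ")),
      "riskcast_parse_error"
    )
  }
  year <- suppressWarnings(as.integer(raw[[schema$year]]))
  bad_year <- which(is.na(year))
  if (length(bad_year) > 0) {
    stop_riskcast(
      sprintf("non-integer year at data row(s): %s", paste(bad_year, collapse = ", ")),
      "riskcast_parse_error"
    )
  }
  df <- tibble::tibble(
    region = raw[[schema$region]],
    code = if (!is.null(schema$code) && schema$code %in% names(raw)) {
      raw[[schema$code]]
    } else {
      NA_character_
    },
    year = year,
    value = if (units == "per100k") value * 1e-3 else value
  )
  units_out <- if (units == "per100k") "percent" else units
  as_panel(df, units = units_out, meta = list(source = path, value_col = value_col,
                                              input_units = units))
}

#' Write a panel back to long-format CSV
#'
#' Serializes the canonical panel to the same long format that [load_panel()]
#' reads (columns `Entity`, `Code`, `Year`, `Value`; rows with missing values
#' are omitted, mirroring the sparse source format) plus an optional YAML
#' sidecar recording units, scaling and provenance.
#'
#' @param panel A `riskcast_panel`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.meta.yaml`?  Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sidecar = TRUE) {
  out <- panel$data |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::transmute(
      Entity = .data$region,
      Code = dplyr::coalesce(.data$code, ""),
      Year = .data$year,
      Value = .data$value
    )
  readr::write_csv(out, path, progress = FALSE)
  if (sidecar) {
    yaml::write_yaml(
      c(list(units = panel$units, scaled = panel$scaled), panel$meta),
      paste0(path, ".meta.yaml")
    )
  }
  invisible(path)
}

#' Convert a count panel to percent of local population
#'
#' Replaces raw death counts with `100 * deaths / population`, using a
#' per-region, per-year population table, so that every region shares the
#' natural hazard limit of 100 (the whole local population).
#'
#' @param panel A `riskcast_panel` with `units == "count"`.
#' @param pops Data frame with columns `region`, `year`, `population`.
#' @return A `riskcast_panel` in percent units.
#' @export
normalize_to_percent <- function(panel, pops) {
  stopifnot(inherits(panel, "riskcast_panel"))
  if (panel$units != "count") {
    stop_riskcast("normalize_to_percent() requires a count panel", "riskcast_schema_error")
  }
  pops <- tibble::as_tibble(pops)
  stopifnot(all(c("region", "year", "population") %in% names(pops)))
  if (any(pops$population <= 0)) {
    stop_riskcast("populations must be positive", "riskcast_integrity_error")
  }
  if (anyDuplicated(pops[c("region", "year")]) > 0) {
    stop_riskcast("duplicate (region, year) in population table", "riskcast_integrity_error")
  }
  joined <- panel$data |>
    dplyr::left_join(pops[c("region", "year", "population")], by = c("region", "year"))
  uncovered <- joined |>
    dplyr::filter(!is.na(.data$value) & is.na(.data$population))
  if (nrow(uncovered) > 0) {
    stop_riskcast(
      sprintf(
        "no population for observed (region, year): %s",
        paste(sprintf("(%s, %d)", uncovered$region, uncovered$year), collapse = ", ")
      ),
      "riskcast_coverage_error"
    )
  }
  out <- joined |>
    dplyr::mutate(value = 100 * .data$value / .data$population) |>
    dplyr::select("region", "code", "year", "value")
  as_panel(out, units = "percent", scaled = panel$scaled,
           meta = c(panel$meta, list(normalized = TRUE)))
}

#' Drop regions from a panel
#'
#' Removes the listed regions (for example known statistical outliers) and
#' returns a new panel; the input panel is untouched.  Blocklist entries not
#' present in the panel produce a warning, not an error.
#'
#' @param panel A `riskcast_panel`.
#' @param blocklist Character vector of region ids to drop.
#' @return A `riskcast_panel` without the listed regions; the number of
#'   removed regions is recorded in `meta$n_excluded`.
#' @export
exclude_regions <- function(panel, blocklist) {
  stopifnot(inherits(panel, "riskcast_panel"))
  blocklist <- unique(as.character(blocklist))
  present <- intersect(blocklist, panel_regions(panel))
  absent <- setdiff(blocklist, present)
  if (length(absent) > 0) {
    rlang::warn(sprintf("blocklist region(s) not in panel: %s",
                        paste(absent, collapse = ", ")))
  }
  if (length(present) == 0) {
    out <- panel
    out$meta$n_excluded <- (panel$meta$n_excluded %||% 0L) + 0L
    return(out)
  }
  data <- panel$data |> dplyr::filter(!.data$region %in% present)
  as_panel(
    data,
    units = panel$units, scaled = panel$scaled,
    meta = c(
      panel$meta[setdiff(names(panel$meta), c("excluded", "n_excluded"))],
      list(
        excluded = union(panel$meta$excluded %||% character(), present),
        n_excluded = (panel$meta$n_excluded %||% 0L) + length(present)
      )
    )
  )
}
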