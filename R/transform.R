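#' Scale panel components by their hazard limits
#'
#' Divides each region's series by its critical level eta so that every
#' component becomes non-dimensional with a common hazard limit of 1.  For
#' percent-of-population panels the natural limit is the whole population,
#' i.e. `limits = 100`.
#'
#' @param panel A `riskcast_panel`.
#' @param limits A single positive scalar applied to all regions, or a named
#'   numeric vector with one positive entry per region in the panel.
#' @return A hazard-scaled `riskcast_panel` (`units = "scaled"`).
#' @export
scale_components <- function(panel, limits) {
  stopifnot(inherits(panel, "riskcast_panel"))
  regions <- panel_regions(panel)
  if (is.null(names(limits))) {
    if (length(limits) != 1) {
      stop_riskcast("unnamed limits must be a single scalar", "riskcast_limits_error")
    }
    limits <- stats::setNames(rep(limits, length(regions)), regions)
  }
  missing_lim <- setdiff(regions, names(limits))
  if (length(missing_lim) > 0) {
    stop_riskcast(
      sprintf("no hazard limit for region(s): %s", paste(missing_lim, collapse = ", ")),
      "riskcast_limits_error"
    )
  }
  bad <- names(limits)[!is.finite(limits) | limits <= 0]
  bad <- intersect(bad, regions)
  if (length(bad) > 0) {
    stop_riskcast(
      sprintf("non-positive hazard limit for region(s): %s", paste(bad, collapse = ", ")),
      "riskcast_limits_error"
    )
  }
  data <- panel$data |>
    dplyr::mutate(value = .data$value / unname(limits[.data$region]))
  as_panel(data, units = "scaled", scaled = TRUE,
           meta = c(panel$meta, list(hazard_limits = limits[regions])))
}

# Local maxima of one (year, value) series; NAs are skipped, the comparison
# runs over the observed subsequence.
local_maxima <- function(years, values, mode = c("all_values", "strict")) {
  mode <- match.arg(mode)
  keep <- !is.na(values)
  if (!any(keep)) {
    stop_riskcast("series has no observed values", "riskcast_empty_error")
  }
  yrs <- years[keep]
  val <- values[keep]
  if (mode == "all_values") {
    return(tibble::tibble(time = yrs, value = val))
  }
  n <- length(val)
  if (n < 3) {
    return(tibble::tibble(time = integer(), value = double()))
  }
  i <- 2:(n - 1)
  peak <- i[val[i] > val[i - 1] & val[i] > val[i + 1]]
  tibble::tibble(time = yrs[peak], value = val[peak])
}

#' Extract per-region event lists of local maxima
#'
#' For annual surveillance panels each year carries exactly one value per
#' region, so "local maxima" degenerates; `mode = "all_values"` (the default)
#' keeps every observed point.  `mode = "strict"` keeps only interior points
#' exceeding both neighbours, for denser series.
#'
#' @param panel A `riskcast_panel`.
#' @param mode `"all_values"` or `"strict"`.
#' @return A named list (one element per region) of tibbles with columns
#'   `time` and `value`, each time-sorted.
#' @export
extract_local_maxima <- function(panel, mode = c("all_values", "strict")) {
  stopifnot(inherits(panel, "riskcast_panel"))
  mode <- match.arg(mode)
  regions <- panel_regions(panel)
  out <- lapply(regions, function(r) {
    d <- panel$data[panel$data$region == r, ]
    if (all(is.na(d$value))) {
      tibble::tibble(time = integer(), value = double())
    } else {
      local_maxima(d$year, d$value, mode)
    }
  })
  stats::setNames(out, regions)
}

new_merged_series <- function(data, strategy, scaled, span_years, events_per_year) {
  structure(
    list(data = tibble::as_tibble(data), strategy = strategy, scaled = scaled,
         span_years = span_years, events_per_year = events_per_year),
    class = "riskcast_merged"
  )
}

#' @export
print.riskcast_merged <- function(x, ...) {
  cat(sprintf(
    "<riskcast_merged> N=%d events (%s merge), span %.0f yr, %.3g events/yr%s\n",
    nrow(x$data), x$strategy, x$span_years, x$events_per_year,
    if (x$scaled) ", hazard-scaled" else ""
  ))
  invisible(x)
}

#' Values of a merged series
#' @param merged A `riskcast_merged` object or bare numeric vector.
#' @return Numeric event values in time order.
#' @export
merged_values <- function(merged) {
  if (inherits(merged, "riskcast_merged")) merged$data$value else as.numeric(merged)
}

#' Interleave per-region event lists into one synthetic vector
#'
#' All events are interleaved in non-decreasing time order.  Events landing
#' on the same timestamp in different regions are collapsed to a single event
#' carrying the componentwise maximum and all contributing source labels, so
#' every input event remains represented (zero net data loss).
#'
#' @param events Named list of time-sorted tibbles with columns `time`,
#'   `value`, as returned by [extract_local_maxima()].
#' @param scaled Whether the inputs were hazard-scaled.
#' @return A `riskcast_merged` series with columns `time`, `value`,
#'   `sources` (`;`-joined region labels).
#' @export
merge_interleave <- function(events, scaled = FALSE) {
  stopifnot(is.list(events))
  if (is.null(names(events)) || any(names(events) == "")) {
    names(events) <- paste0("S", seq_along(events))
  }
  nonempty <- events[vapply(events, nrow, 1L) > 0]
  if (length(nonempty) == 0) {
    stop_riskcast("no events to merge", "riskcast_empty_error")
  }
  for (nm in names(nonempty)) {
    if (is.unsorted(nonempty[[nm]]$time, strictly = TRUE)) {
      stop_riskcast(sprintf("event times of '%s' are not strictly increasing", nm),
                    "riskcast_integrity_error")
    }
  }
  all_ev <- dplyr::bind_rows(
    lapply(names(nonempty), function(nm) {
      dplyr::mutate(nonempty[[nm]], source = nm)
    })
  )
  merged <- all_ev |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      value = max(.data$value),
      sources = paste(sort(unique(.data$source)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$time)
  span <- diff(range(merged$time)) + 1
  new_merged_series(merged, strategy = "interleave", scaled = scaled,
                    span_years = span, events_per_year = nrow(merged) / span)
}

#' Pointwise-maximum merge of a synchronous panel
#'
#' One event per year: the maximum over all regions with data that year, with
#' the argmax region recorded as the source.  Years unobserved in every
#' region are dropped, never imputed.  This is the default merge for
#' synchronous annual panels.
#'
#' @param panel A `riskcast_panel`.
#' @return A `riskcast_merged` series with one event per observed year and
#'   `events_per_year = 1`.
#' @export
merge_pointwise_max <- function(panel) {
  stopifnot(inherits(panel, "riskcast_panel"))
  if (length(panel_regions(panel)) == 0 || all(is.na(panel$data$value))) {
    stop_riskcast("panel has no observed values", "riskcast_empty_error")
  }
  merged <- panel$data |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(time = .data$year) |>
    dplyr::summarise(
      sources = .data$region[which.max(.data$value)],
      value = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::select("time", "value", "sources") |>
    dplyr::arrange(.data$time)
  span <- diff(range(merged$time)) + 1
  new_merged_series(merged, strategy = "pointwise", scaled = panel$scaled,
                    span_years = span, events_per_year = 1)
}
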