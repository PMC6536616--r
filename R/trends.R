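#' Percentage with the reference printing convention
#'
#' `100 * numerator / denominator` rounded half-up to one decimal place, the
#' convention used when pairing counts with percentages in reports (e.g.
#' 85455 of 172453 prints as 49.6). Base `round()` rounds half to even, so
#' the half-up rule is applied explicitly.
#'
#' @param numerator,denominator Nonnegative counts; `denominator` must be
#'   positive. Both vectorized.
#' @return Numeric percentage(s) with one decimal.
#' @examples
#' proportion(85455, 172453) # 49.6
#' proportion(1, 3) # 33.3
#' @export
proportion <- function(numerator, denominator) {
  if (any(denominator == 0)) abort("`denominator` must be positive.")
  floor(1000 * numerator / denominator + 0.5) / 10
}

#' Annual phenotype-by-location trend table
#'
#' Attributes each investigator to exactly one year - the year of the first
#' submission (`firsub`), the date on which an investigator is plotted - and
#' tabulates counts by year, phenotype and location over the full window,
#' with zero cells present. Two shares accompany each count:
#' `share_of_year`, the cell's fraction of that year's new investigators,
#' and `share_of_phenotype_year`, each location's fraction of the
#' (year, phenotype) total.
#'
#' @param cohort A labeled cohort from [classify_phenotypes()] (or
#'   [read_cohort()]).
#' @param start_year,end_year Window years; every investigator's `firsub`
#'   must fall inside (a violation means the upstream window filter was
#'   skipped and is an error).
#' @return A tibble of class `trend_table` keyed by
#'   (`year`, `phenotype`, `location`) with columns `count`,
#'   `share_of_year`, `share_of_phenotype_year`. Shares are `NA` where the
#'   denominator cell is empty.
#' @seealso [autoplot.trend_table()], [write_trends()]
#' @export
annual_counts <- function(cohort, start_year = 1999L, end_year = 2015L) {
  if (!"phenotype" %in% names(cohort)) {
    abort("`cohort` is not labeled; run classify_phenotypes() first.")
  }
  years <- seq.int(start_year, end_year)
  fy <- as.integer(format(cohort$firsub, "%Y"))
  if (any(fy < start_year | fy > end_year)) {
    abort(paste0(
      "Some investigators have a first submission outside the window; ",
      "apply filter_window() before building histories."
    ))
  }
  grid <- tidyr::expand_grid(
    year = years,
    phenotype = factor(phenotype_levels(), levels = phenotype_levels()),
    location = factor(location_levels(), levels = location_levels())
  )
  counts <- tibble(
    year = fy,
    phenotype = cohort$phenotype,
    location = cohort$location
  ) |>
    dplyr::count(.data$year, .data$phenotype, .data$location, name = "count")
  out <- grid |>
    dplyr::left_join(counts, by = c("year", "phenotype", "location")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(
      share_of_year = .data$count / ifelse(sum(.data$count) > 0, sum(.data$count), NA_real_)
    ) |>
    dplyr::group_by(.data$year, .data$phenotype) |>
    dplyr::mutate(
      share_of_phenotype_year =
        .data$count / ifelse(sum(.data$count) > 0, sum(.data$count), NA_real_)
    ) |>
    dplyr::ungroup()
  attr(out, "window") <- c(start_year, end_year)
  class(out) <- c("trend_table", class(out))
  out
}

#' Write a trend table as CSV
#' @param trends A `trend_table` from [annual_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trends <- function(trends, path) {
  readr::write_csv(as_tibble(trends), path, na = "")
  invisible(path)
}

#' Structured summary of a labeled cohort
#'
#' Emits the quantities a turnover report prints: the cohort size, the
#' per-phenotype counts with one-decimal percentages, the per-year
#' per-phenotype US / non-US counts and shares, and the gap-time threshold
#' used. Field order is deterministic. [write_summary()] serializes it as
#' JSON with stable key names.
#'
#' @param cohort A labeled cohort from [classify_phenotypes()].
#' @param start_year,end_year Window years; default to the observed range of
#'   first-submission years.
#' @return An object of class `turnover_summary`.
#' @export
summary_report <- function(cohort, start_year = NULL, end_year = NULL) {
  fy <- as.integer(format(cohort$firsub, "%Y"))
  start_year <- start_year %||% min(fy)
  end_year <- end_year %||% max(fy)
  n <- nrow(cohort)
  ph_counts <- table(cohort$phenotype)
  phenotypes <- tibble(
    phenotype = phenotype_levels(),
    count = as.integer(ph_counts[phenotype_levels()]),
    pct = proportion(as.integer(ph_counts[phenotype_levels()]), n)
  )
  trend <- annual_counts(cohort, start_year, end_year)
  by_year_location <- trend |>
    as_tibble() |>
    dplyr::group_by(.data$year, .data$phenotype) |>
    dplyr::mutate(cell_total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      pct_of_phenotype_year = ifelse(
        .data$cell_total > 0,
        proportion(.data$count, pmax(.data$cell_total, 1L)),
        NA_real_
      )
    ) |>
    dplyr::select(
      "year", "phenotype", "location", "count", "pct_of_phenotype_year"
    )
  yearly_totals <- trend |>
    as_tibble() |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  structure(
    list(
      n_investigators = n,
      window = c(start_year = start_year, end_year = end_year),
      threshold = cohort_threshold(cohort),
      phenotypes = phenotypes,
      yearly_totals = yearly_totals,
      by_year_location = by_year_location
    ),
    class = "turnover_summary"
  )
}

#' @export
print.turnover_summary <- function(x, ...) {
  cat(sprintf(
    "Investigator turnover summary, %d-%d\n",
    x$window[["start_year"]], x$window[["end_year"]]
  ))
  cat(sprintf("  %d unique investigators\n", x$n_investigators))
  for (i in seq_len(nrow(x$phenotypes))) {
    cat(sprintf(
      "    %-13s %d (%.1f%%)\n",
      x$phenotypes$phenotype[i], x$phenotypes$count[i], x$phenotypes$pct[i]
    ))
  }
  th <- x$threshold
  if (!is.null(th)) {
    if (is.na(th$percentile)) {
      cat(sprintf("  gap cutoff: fixed at %g days\n", th$cutoff_days))
    } else {
      cat(sprintf(
        "  gap cutoff: %g days (%gth percentile of %d gaps)\n",
        th$cutoff_days, th$percentile, th$n_gaps
      ))
    }
  }
  invisible(x)
}

#' Serialize a turnover summary as JSON
#'
#' Key names are stable: `n_investigators`, `window`, `threshold`
#' (`percentile`, `cutoff_days`, `n_gaps`, `method`), `phenotypes`,
#' `yearly_totals`, `by_year_location`.
#'
#' @param x A `turnover_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  th <- x$threshold
  payload <- list(
    n_investigators = x$n_investigators,
    window = as.list(x$window),
    threshold = if (is.null(th)) NULL else unclass(th),
    phenotypes = x$phenotypes,
    yearly_totals = x$yearly_totals,
    by_year_location = x$by_year_location
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Plot annual turnover trends
#'
#' Line chart of new-investigator counts per first-submission year, colored
#' by location and faceted by phenotype - the conventional presentation of
#' turnover trend tables.
#'
#' @param object A `trend_table` from [annual_counts()].
#' @param measure Column to plot: `"count"` (default), `"share_of_year"` or
#'   `"share_of_phenotype_year"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trend_table <- function(object, measure = "count", ...) {
  measure <- match.arg(measure, c("count", "share_of_year", "share_of_phenotype_year"))
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(
      x = .data$year, y = .data[[measure]],
      colour = .data$location, group = .data$location
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$phenotype), scales = "free_y") +
    ggplot2::labs(
      x = "Year of first submission",
      y = gsub("_", " ", measure),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.trend_table
#' @param trends A `trend_table`.
#' @export
plot_trends <- function(trends, measure = "count") {
  autoplot(trends, measure = measure)
}
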