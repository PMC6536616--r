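#' Empirical percentile cutoff of the first-to-second submission gap
#'
#' Computes the gap-time cutoff (in days) separating "stayer" from
#' "stop-and-go" investigators as an empirical percentile of the observed
#' `secdiff` distribution. The default method is nearest-rank - the cutoff is
#' the `ceiling(p/100 * n)`-th order statistic - so the cutoff is always an
#' observed gap value; `method = "linear"` uses the usual interpolated sample
#' quantile (`stats::quantile` type 7) instead.
#'
#' In the reference analysis of the 1999-2015 registry the 75th percentile of
#' this distribution was 1013 days (the 50th, 411 days, was considered and
#' rejected as too short for investigators on long trials), which is why 75
#' is the default percentile.
#'
#' @param histories Tibble of investigator histories from
#'   [build_histories()]; only rows with a `secdiff` contribute.
#' @param percentile Number in (0, 100].
#' @param method `"nearest_rank"` (default) or `"linear"`.
#' @return An object of class `threshold_spec`: a list with `percentile`,
#'   `cutoff_days`, `n_gaps` and `method`.
#' @examples
#' h <- tibble::tibble(secdiff = c(10L, 20L, 30L, 40L), oad = FALSE)
#' gap_threshold(h, percentile = 75)$cutoff_days # 30
#' @export
gap_threshold <- function(histories, percentile = 75,
                          method = c("nearest_rank", "linear")) {
  method <- match.arg(method)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile > 100) {
    abort("`percentile` must be a single number in (0, 100].")
  }
  gaps <- histories$secdiff[!is.na(histories$secdiff)]
  if (length(gaps) == 0L) {
    abort(paste0(
      "No multi-submission investigator in the cohort: the gap-time ",
      "percentile cutoff is undefined."
    ))
  }
  cutoff <- switch(method,
    nearest_rank = sort(gaps)[ceiling(percentile / 100 * length(gaps))],
    linear = unname(quantile(gaps, probs = percentile / 100, type = 7))
  )
  new_threshold_spec(percentile, cutoff, length(gaps), method)
}

new_threshold_spec <- function(percentile, cutoff_days, n_gaps, method) {
  structure(
    list(
      percentile = percentile,
      cutoff_days = as.numeric(cutoff_days),
      n_gaps = as.integer(n_gaps),
      method = method
    ),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("<threshold_spec>\n")
  if (is.na(x$percentile)) {
    cat("  fixed cutoff: ", x$cutoff_days, " days\n", sep = "")
  } else {
    cat(sprintf(
      "  %gth percentile (%s) of %d gap times: %g days\n",
      x$percentile, x$method, x$n_gaps, x$cutoff_days
    ))
  }
  invisible(x)
}

classify_one <- function(oad, secdiff, cutoff, inclusive) {
  stayer <- if (inclusive) secdiff <= cutoff else secdiff < cutoff
  dplyr::case_when(
    oad ~ "one_and_done",
    stayer ~ "stayer",
    .default = "stop_and_go"
  )
}

#' Label every investigator with a turnover phenotype
#'
#' Partitions a cohort into the three turnover phenotypes:
#' \describe{
#'   \item{one_and_done}{exactly one submission in the study window;}
#'   \item{stayer}{two or more submissions with the first-to-second gap
#'     within the percentile cutoff - the most continuously engaged group;}
#'   \item{stop_and_go}{two or more submissions with the gap beyond the
#'     cutoff.}
#' }
#' The cutoff is recomputed from this cohort's gap distribution by default
#' ([gap_threshold()]); supply `cutoff_days` to classify against a fixed
#' externally derived cutoff (e.g. the reference 1013 days). "Within" is read
#' inclusively: a gap exactly equal to the cutoff is a stayer
#' (`boundary = "exclusive"` flips this). A cohort with no multi-submission
#' investigator is labeled all one_and_done without computing a threshold.
#'
#' @param histories Tibble from [build_histories()] (columns `oad`,
#'   `secdiff` required).
#' @param percentile Percentile for the cutoff, default 75.
#' @param cutoff_days Optional fixed cutoff in days overriding the
#'   empirical percentile.
#' @param method Percentile method, see [gap_threshold()].
#' @param boundary `"inclusive"` (gap equal to the cutoff is a stayer,
#'   default) or `"exclusive"`.
#' @return The histories tibble with a `phenotype` factor column appended,
#'   classed `turnover_cohort`; the `threshold_spec` used (or `NULL` for an
#'   all-single cohort) is attached and retrievable via [cohort_threshold()].
#' @seealso [tidy.turnover_cohort()], [glance.turnover_cohort()],
#'   [phenotype_counts()]
#' @export
classify_phenotypes <- function(histories, percentile = 75, cutoff_days = NULL,
                                method = c("nearest_rank", "linear"),
                                boundary = c("inclusive", "exclusive")) {
  method <- match.arg(method)
  boundary <- match.arg(boundary)
  if (nrow(histories) == 0L) abort("Cannot classify an empty cohort.")
  corrupt <- !histories$oad & is.na(histories$secdiff)
  if (any(corrupt)) {
    abort(sprintf(
      "%d multi-submission history(ies) lack a secdiff; the cohort is corrupt.",
      sum(corrupt)
    ))
  }
  any_multi <- any(!histories$oad)
  threshold <- if (!is.null(cutoff_days)) {
    new_threshold_spec(NA_real_, cutoff_days, sum(!is.na(histories$secdiff)), "fixed")
  } else if (any_multi) {
    gap_threshold(histories, percentile = percentile, method = method)
  } else {
    NULL
  }
  label <- if (is.null(threshold)) {
    rep("one_and_done", nrow(histories))
  } else {
    classify_one(
      histories$oad, histories$secdiff, threshold$cutoff_days,
      inclusive = boundary == "inclusive"
    )
  }
  out <- histories
  out$phenotype <- factor(label, levels = phenotype_levels())
  attr(out, "threshold") <- threshold
  class(out) <- c("turnover_cohort", class(tibble()))
  out
}

#' Threshold used to label a cohort
#' @param x A `turnover_cohort` from [classify_phenotypes()].
#' @return The `threshold_spec`, or `NULL` for an all-single cohort.
#' @export
cohort_threshold <- function(x) attr(x, "threshold")

#' Phenotype-by-location counts of a labeled cohort
#'
#' @param cohort A `turnover_cohort`.
#' @return A tibble with one row per (phenotype, location) cell, zero cells
#'   included; counts sum to the cohort size.
#' @export
phenotype_counts <- function(cohort) {
  if (!"phenotype" %in% names(cohort)) {
    abort("`cohort` is not labeled; run classify_phenotypes() first.")
  }
  cohort |>
    as_tibble() |>
    dplyr::count(.data$phenotype, .data$location, .drop = FALSE, name = "count")
}

#' @describeIn classify_phenotypes Per-investigator labels as a plain tibble.
#' @param x A `turnover_cohort`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.turnover_cohort <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "threshold") <- NULL
  out
}

#' One-row summary of a labeled cohort
#'
#' @param x A `turnover_cohort`.
#' @param ... Unused.
#' @return A one-row tibble: cohort size, per-phenotype counts and
#'   percentages (one decimal, half-up, as conventionally printed), and the
#'   threshold parameters.
#' @exportS3Method generics::glance
glance.turnover_cohort <- function(x, ...) {
  n <- nrow(x)
  counts <- table(x$phenotype)
  th <- cohort_threshold(x)
  tibble(
    n_investigators = n,
    n_one_and_done = as.integer(counts[["one_and_done"]]),
    n_stop_and_go = as.integer(counts[["stop_and_go"]]),
    n_stayer = as.integer(counts[["stayer"]]),
    pct_one_and_done = proportion(counts[["one_and_done"]], n),
    pct_stop_and_go = proportion(counts[["stop_and_go"]], n),
    pct_stayer = proportion(counts[["stayer"]], n),
    percentile = if (is.null(th)) NA_real_ else th$percentile,
    cutoff_days = if (is.null(th)) NA_real_ else th$cutoff_days,
    n_gaps = if (is.null(th)) 0L else th$n_gaps
  )
}

#' @export
print.turnover_cohort <- function(x, ...) {
  th <- cohort_threshold(x)
  cat(sprintf("<turnover_cohort> %d investigators\n", nrow(x)))
  if (!is.null(th)) {
    cat(sprintf(
      "  gap cutoff: %g days (%s)\n", th$cutoff_days,
      if (is.na(th$percentile)) "fixed" else sprintf("%gth percentile", th$percentile)
    ))
  }
  NextMethod()
}
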