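phenotype_levels <- function() c("one_and_done", "stop_and_go", "stayer")
location_levels <- function() c("US", "NON_US")

#' Normalize an investigator name for keying
#'
#' Trims surrounding whitespace, collapses internal whitespace runs to a
#' single space and case-folds. Registry entries for the same person often
#' differ in spacing and case only, so this is the default keying
#' transformation; pass `normalize = FALSE` to [assign_investigator_ids()]
#' for strict raw matching.
#'
#' @param x Character vector of names.
#' @return Normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- ifelse(is.na(x), "", x)
  toupper(gsub("\\s+", " ", trimws(x)))
}

#' Drop records with invalid last names
#'
#' Records whose last name is null, empty after trimming, or the literal
#' placeholder `"??"` cannot identify an investigator and are excluded
#' before keying. The number excluded is attached as attribute
#' `n_excluded` and available via [n_excluded()].
#'
#' @param records Tibble of submission records.
#' @return The filtered tibble, order preserved.
#' @export
exclude_invalid_names <- function(records) {
  ln <- trimws(ifelse(is.na(records$last_name), "", records$last_name))
  invalid <- ln == "" | ln == "??"
  out <- records[!invalid, , drop = FALSE]
  attr(out, "n_excluded") <- sum(invalid)
  out
}

#' Count of records dropped by [exclude_invalid_names()]
#' @param x A tibble returned by [exclude_invalid_names()].
#' @return Integer count.
#' @export
n_excluded <- function(x) {
  as.integer(attr(x, "n_excluded") %||% 0L)
}

#' Assign a unique investigator id to each record
#'
#' Two records receive the same `newid` exactly when their (last name,
#' first name) keys agree after normalization; ids are dense integers in
#' order of first appearance. Identity is name-based only - distinct people
#' sharing a name collapse to one id, a known limitation of name-keyed
#' registry deduplication (see the synthetic generator's
#' `name_collision_rate` for quantifying the resulting bias).
#'
#' @param records Tibble of submission records (already name-filtered).
#' @param normalize Apply [normalize_name()] before keying (default) or key
#'   on raw strings.
#' @return `records` with an integer `newid` column appended.
#' @export
assign_investigator_ids <- function(records, normalize = TRUE) {
  last <- if (normalize) normalize_name(records$last_name) else records$last_name
  first <- if (normalize) normalize_name(records$first_name) else records$first_name
  key <- paste(last, first, sep = "\x1f")
  records$newid <- match(key, unique(key))
  records
}

#' Classify a country field as US or non-US
#'
#' U.S. location is defined by the country field equaling `"USA"` after
#' trimming and case-folding; every other value - including missing or
#' empty, which cannot be verified as U.S. - is non-US.
#'
#' @param country Character vector of country names.
#' @return Factor with levels `US`, `NON_US`.
#' @export
classify_location <- function(country) {
  norm <- toupper(trimws(ifelse(is.na(country), "", country)))
  factor(
    ifelse(norm == "USA", "US", "NON_US"),
    levels = location_levels()
  )
}

#' Build one history per unique investigator
#'
#' Groups records by `newid` and derives the per-investigator variables:
#' `firsub`, the minimum (first) receipt date; `secdiff`, the number of days
#' from the first to the second submission (absent for single-submission
#' investigators); `oad`, the single-submission flag; and `location`, from
#' the country field of the first submission. Within an investigator,
#' submissions are ordered by receipt date with ties broken by original
#' record order, so a same-day second submission yields `secdiff = 0`.
#' Submissions beyond the second are retained in the `submissions`
#' list-column but never influence `secdiff` or the phenotype.
#'
#' @param records Tibble of submission records carrying a `newid` column
#'   (see [assign_investigator_ids()]).
#' @return A tibble with one row per `newid`: `newid`, `last_name`,
#'   `first_name`, `firsub` (Date), `secdiff` (integer days or `NA`),
#'   `oad` (logical), `n_submissions`, `location`, and the `submissions`
#'   list-column of ordered dates. Investigators whose later submissions
#'   carry a different country than the first are counted in attribute
#'   `n_country_conflicts`.
#' @export
build_histories <- function(records) {
  if (!"newid" %in% names(records)) {
    abort("`records` lacks a `newid` column; run assign_investigator_ids() first.")
  }
  rec <- records |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::arrange(.data$newid, .data$receipt_date, .data$.file_order)

  hist <- rec |>
    dplyr::group_by(.data$newid) |>
    dplyr::summarise(
      last_name = .data$last_name[1L],
      first_name = .data$first_name[1L],
      firsub = .data$receipt_date[1L],
      secdiff = as.integer(.data$receipt_date[2L] - .data$receipt_date[1L]),
      n_submissions = dplyr::n(),
      first_country = .data$country_name[1L],
      country_conflict = dplyr::n_distinct(.data$country_name) > 1L,
      submissions = list(.data$receipt_date),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      oad = .data$n_submissions == 1L,
      location = classify_location(.data$first_country)
    ) |>
    dplyr::select(
      "newid", "last_name", "first_name", "firsub", "secdiff", "oad",
      "n_submissions", "location", "submissions", "country_conflict"
    ) |>
    dplyr::arrange(.data$newid)

  n_conflict <- sum(hist$country_conflict)
  if (n_conflict > 0L) {
    inform(sprintf(
      "%d investigator(s) have submissions with conflicting countries; the first submission's country was used.",
      n_conflict
    ))
  }
  out <- dplyr::select(hist, -"country_conflict")
  attr(out, "n_country_conflicts") <- n_conflict
  out
}
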