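# Fixture builders and independent first-principles oracles. The oracles
# deliberately avoid the package's pipeline functions: base-R loops, sets
# and sorts only, so they can disagree with the implementation.

make_records <- function(last, first = "A", country = "USA", date = "2000-01-01") {
  n <- max(length(last), length(first), length(country), length(date))
  tibble::tibble(
    last_name = rep_len(last, n),
    first_name = rep_len(first, n),
    country_name = rep_len(country, n),
    receipt_date = as.Date(rep_len(date, n))
  )
}

write_dump <- function(records, path = tempfile(fileext = ".txt"),
                       dialect = bmis_dialect()) {
  write_bmis(records, path, dialect)
  path
}

# Nearest-rank percentile by full sort, written independently of
# gap_threshold().
oracle_nearest_rank <- function(x, p) {
  s <- sort(x)
  s[[ceiling(p / 100 * length(s))]]
}

# Exhaustive re-derivation of phenotype labels from raw records: key by
# normalized name, sort each person's dates, subtract the first two, rank
# gaps, compare. Returns a data.frame keyed by normalized name.
oracle_classify <- function(records, percentile = 75) {
  key <- paste(
    toupper(gsub("\\s+", " ", trimws(records$last_name))),
    toupper(gsub("\\s+", " ", trimws(records$first_name))),
    sep = "/"
  )
  keys <- unique(key)
  gaps <- numeric(0)
  per_key <- list()
  for (k in keys) {
    dates <- sort(records$receipt_date[key == k])
    g <- if (length(dates) >= 2) as.numeric(dates[2] - dates[1]) else NA_real_
    per_key[[k]] <- g
    if (!is.na(g)) gaps <- c(gaps, g)
  }
  cutoff <- if (length(gaps)) oracle_nearest_rank(gaps, percentile) else NA_real_
  label <- vapply(keys, function(k) {
    g <- per_key[[k]]
    if (is.na(g)) "one_and_done" else if (g <= cutoff) "stayer" else "stop_and_go"
  }, character(1))
  data.frame(key = keys, label = unname(label), stringsAsFactors = FALSE)
}

# Random record streams for property tests: n_people with 1-3 submissions
# each, dates uniform in the window.
random_records <- function(n_people, seed, start = "1999-01-01", end = "2015-12-31") {
  withr::with_seed(seed, {
    d0 <- as.Date(start)
    span <- as.integer(as.Date(end) - d0)
    rows <- lapply(seq_len(n_people), function(i) {
      k <- sample(1:3, 1)
      tibble::tibble(
        last_name = sprintf("L%04d", i),
        first_name = sprintf("F%04d", i),
        country_name = sample(c("USA", "CANADA", "JAPAN"), 1),
        receipt_date = d0 + sample.int(span + 1L, k, replace = TRUE) - 1L
      )
    })
    recs <- do.call(rbind, rows)
    recs[sample.int(nrow(recs)), ]
  })
}

default_pipeline <- function(records, percentile = 75) {
  records |>
    exclude_invalid_names() |>
    assign_investigator_ids() |>
    build_histories() |>
    classify_phenotypes(percentile = percentile)
}
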