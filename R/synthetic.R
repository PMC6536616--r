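#' Gap-time distributions for the synthetic generator
#'
#' Distributions for the days between an investigator's first and second
#' submissions. `gap_lognormal()` is parameterized by its median and 75th
#' percentile; the default generator uses median 411 days and 75th
#' percentile 1013 days, the two documented quantiles of the reference
#' 1999-2015 gap distribution, so synthetic cohorts reproduce them by
#' construction. `gap_uniform()` and `gap_fixed()` support boundary and
#' geometry experiments.
#'
#' @param median_days,q75_days Median and 75th percentile, in days.
#' @return A gap-distribution spec (list with class `gap_dist`).
#' @examples
#' gap_lognormal() # the calibrated default
#' gap_fixed(0) # every second submission on the same day
#' @export
gap_lognormal <- function(median_days = 411, q75_days = 1013) {
  if (q75_days <= median_days) abort("`q75_days` must exceed `median_days`.")
  structure(
    list(
      dist = "lognormal",
      meanlog = log(median_days),
      sdlog = log(q75_days / median_days) / stats::qnorm(0.75)
    ),
    class = "gap_dist"
  )
}

#' @rdname gap_lognormal
#' @param min_days,max_days Bounds of the uniform gap distribution.
#' @export
gap_uniform <- function(min_days, max_days) {
  if (min_days > max_days || min_days < 0) abort("Need 0 <= min_days <= max_days.")
  structure(
    list(dist = "uniform", min = min_days, max = max_days),
    class = "gap_dist"
  )
}

#' @rdname gap_lognormal
#' @param days Fixed gap length in days.
#' @export
gap_fixed <- function(days) {
  if (days < 0) abort("`days` must be nonnegative.")
  structure(list(dist = "fixed", days = days), class = "gap_dist")
}

draw_gaps <- function(spec, n) {
  raw <- switch(spec$dist,
    lognormal = rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog),
    uniform = runif(n, spec$min, spec$max),
    fixed = rep(spec$days, n),
    abort(sprintf("Unknown gap distribution '%s'.", spec$dist))
  )
  pmax(0L, as.integer(round(raw)))
}

gap_quantile <- function(spec, p) {
  switch(spec$dist,
    lognormal = stats::qlnorm(p, meanlog = spec$meanlog, sdlog = spec$sdlog),
    uniform = spec$min + p * (spec$max - spec$min),
    fixed = spec$days
  )
}

#' Configuration for the synthetic BMIS generator
#'
#' Fixes every knob of the simulated registry. Defaults emulate the
#' reference 1999-2015 study conditions: a 49.6% single-submission share
#' (the reference one-and-done proportion), gap times lognormal with median
#' 411 and 75th percentile 1013 days, a 60/40 US / non-US mix, uniform
#' arrivals over the window, and clean names (no invalid-name records, no
#' engineered collisions) unless asked for.
#'
#' @param n_investigators Number of simulated people.
#' @param frac_single Fraction planned to submit exactly once.
#' @param gap_distribution A [gap_lognormal()] / [gap_uniform()] /
#'   [gap_fixed()] spec for the first-to-second submission gap.
#' @param extra_submission_rate Expected number of third-and-later
#'   submissions per uncensored multi-submission person (Poisson); these
#'   never affect gap times or phenotypes.
#' @param frac_us Fraction of people based in the U.S.
#' @param window_start,window_end Study-window years (inclusive).
#' @param invalid_name_rate Invalid-name records (`"??"` or empty last name)
#'   injected per valid record; they belong to no simulated person.
#' @param name_collision_rate Fraction of people (after the first) assigned
#'   the name key of an earlier person, so distinct people collapse under
#'   name-based deduplication.
#' @param arrival `"uniform"` first-submission dates over the window, or
#'   `"piecewise"` with per-year `arrival_intensity` weights (to mimic an
#'   uneven yearly inflow).
#' @param arrival_intensity Nonnegative weight per window year
#'   (recycled/checked to the window length) when `arrival = "piecewise"`.
#' @param seed Integer seed; identical config and seed give identical output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_investigators = 10000L,
                             frac_single = 0.496,
                             gap_distribution = gap_lognormal(),
                             extra_submission_rate = 0.5,
                             frac_us = 0.6,
                             window_start = 1999L,
                             window_end = 2015L,
                             invalid_name_rate = 0,
                             name_collision_rate = 0,
                             arrival = c("uniform", "piecewise"),
                             arrival_intensity = NULL,
                             seed = 1L) {
  arrival <- match.arg(arrival)
  stopifnot(is.numeric(n_investigators), length(n_investigators) == 1L)
  if (n_investigators < 1) abort("`n_investigators` must be positive.")
  for (f in c(frac_single, frac_us, invalid_name_rate, name_collision_rate)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      abort("Fractions and rates must lie in [0, 1].")
    }
  }
  if (window_start > window_end) abort("`window_start` must not exceed `window_end`.")
  if (!inherits(gap_distribution, "gap_dist")) {
    abort("`gap_distribution` must be built with gap_lognormal()/gap_uniform()/gap_fixed().")
  }
  if (extra_submission_rate < 0) abort("`extra_submission_rate` must be nonnegative.")
  n_years <- window_end - window_start + 1L
  if (arrival == "piecewise") {
    if (is.null(arrival_intensity) || length(arrival_intensity) != n_years ||
        any(arrival_intensity < 0) || sum(arrival_intensity) == 0) {
      abort(sprintf(
        "`arrival_intensity` must be %d nonnegative weights with a positive sum.",
        n_years
      ))
    }
  }
  structure(
    list(
      n_investigators = as.integer(n_investigators),
      frac_single = frac_single,
      gap_distribution = gap_distribution,
      extra_submission_rate = extra_submission_rate,
      frac_us = frac_us,
      window_start = as.integer(window_start),
      window_end = as.integer(window_end),
      invalid_name_rate = invalid_name_rate,
      name_collision_rate = name_collision_rate,
      arrival = arrival,
      arrival_intensity = arrival_intensity,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

non_us_pool <- function() {
  c(
    "CANADA", "GERMANY", "JAPAN", "BRAZIL", "INDIA",
    "UNITED KINGDOM", "FRANCE", "SOUTH AFRICA", "POLAND", "AUSTRALIA"
  )
}

#' Simulate a BMIS-like submission stream with ground truth
#'
#' Generates, deterministically under `config$seed`, a stream of submission
#' records shaped like a BMIS dump plus a per-person ground-truth table.
#' Each person receives a first-submission date over the window;
#' planned-multi people draw a gap for the second submission, which is
#' dropped - and recorded as window-censored - when it lands past the window
#' end. The ground-truth phenotype is the person's phenotype in an
#' uncensored, collision-free regime, using the gap distribution's
#' theoretical 75th-percentile cutoff (attached as attribute
#' `true_cutoff_days`); comparing it with the pipeline's output isolates
#' censoring and collision bias.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (tibble: `last_name`, `first_name`,
#'   `country_name`, `receipt_date`, sorted by date), `truth` (tibble, one
#'   row per simulated person), and `config`.
#' @seealso [generate_bmis_dump()], [censoring_experiment()]
#' @export
simulate_bmis <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, simulate_bmis_impl(config))
}

simulate_bmis_impl <- function(config) {
  n <- config$n_investigators
  d0 <- as.Date(sprintf("%d-01-01", config$window_start))
  d1 <- as.Date(sprintf("%d-12-31", config$window_end))
  n_days <- as.integer(d1 - d0) + 1L

  last <- sprintf("LAST%06d", seq_len(n))
  first <- sprintf("FIRST%06d", seq_len(n))
  if (config$name_collision_rate > 0 && n > 1L) {
    collide <- runif(n) < config$name_collision_rate
    collide[1L] <- FALSE
    for (i in which(collide)) {
      donor <- sample.int(i - 1L, 1L)
      last[i] <- last[donor]
      first[i] <- first[donor]
    }
  } else {
    collide <- rep(FALSE, n)
  }

  us <- runif(n) < config$frac_us
  country <- ifelse(us, "USA", sample(non_us_pool(), n, replace = TRUE))

  first_date <- if (config$arrival == "uniform") {
    d0 + (sample.int(n_days, n, replace = TRUE) - 1L)
  } else {
    years <- seq.int(config$window_start, config$window_end)
    yr <- sample(years, n, replace = TRUE, prob = config$arrival_intensity)
    y0 <- as.Date(sprintf("%d-01-01", yr))
    ylen <- as.integer(as.Date(sprintf("%d-12-31", yr)) - y0) + 1L
    y0 + (floor(runif(n) * ylen))
  }

  single <- runif(n) < config$frac_single
  gap <- rep(NA_integer_, n)
  n_multi <- sum(!single)
  if (n_multi > 0L) gap[!single] <- draw_gaps(config$gap_distribution, n_multi)
  second_date <- first_date + gap
  censored <- !single & !is.na(gap) & second_date > d1

  true_cutoff <- gap_quantile(config$gap_distribution, 0.75)
  true_phenotype <- dplyr::case_when(
    single ~ "one_and_done",
    gap <= true_cutoff ~ "stayer",
    .default = "stop_and_go"
  )

  truth <- tibble(
    person = seq_len(n),
    last_name = last,
    first_name = first,
    name_key = paste(normalize_name(last), normalize_name(first), sep = "\x1f"),
    country_name = country,
    location = classify_location(country),
    firsub = first_date,
    firsub_year = as.integer(format(first_date, "%Y")),
    single = single,
    gap_days = gap,
    censored = censored,
    collided = collide,
    true_phenotype = factor(true_phenotype, levels = phenotype_levels())
  )
  attr(truth, "true_cutoff_days") <- true_cutoff

  rec_first <- tibble(
    person = seq_len(n), obs_order = 1L,
    last_name = last, first_name = first,
    country_name = country, receipt_date = first_date
  )
  keep2 <- !single & !censored
  rec_second <- tibble(
    person = which(keep2), obs_order = 2L,
    last_name = last[keep2], first_name = first[keep2],
    country_name = country[keep2], receipt_date = second_date[keep2]
  )
  rec_extra <- NULL
  if (config$extra_submission_rate > 0 && nrow(rec_second) > 0L) {
    k <- rpois(nrow(rec_second), config$extra_submission_rate)
    idx <- rep(seq_len(nrow(rec_second)), k)
    if (length(idx)) {
      base <- rec_second$receipt_date[idx]
      room <- as.numeric(d1 - base)
      rec_extra <- tibble(
        person = rec_second$person[idx], obs_order = 3L,
        last_name = rec_second$last_name[idx],
        first_name = rec_second$first_name[idx],
        country_name = rec_second$country_name[idx],
        receipt_date = base + floor(runif(length(idx)) * (room + 1))
      )
    }
  }
  records <- dplyr::bind_rows(rec_first, rec_second, rec_extra)

  n_invalid <- round(config$invalid_name_rate * nrow(records))
  if (n_invalid > 0L) {
    records <- dplyr::bind_rows(records, tibble(
      person = NA_integer_, obs_order = 0L,
      last_name = sample(c("??", ""), n_invalid, replace = TRUE),
      first_name = sprintf("GHOST%05d", seq_len(n_invalid)),
      country_name = sample(c("USA", non_us_pool()), n_invalid, replace = TRUE),
      receipt_date = d0 + (sample.int(n_days, n_invalid, replace = TRUE) - 1L)
    ))
  }
  records <- records |>
    dplyr::arrange(.data$receipt_date, .data$person, .data$obs_order) |>
    dplyr::select("last_name", "first_name", "country_name", "receipt_date")

  list(records = records, truth = truth, config = config)
}

#' Write a synthetic dump plus ground truth to disk
#'
#' Materializes [simulate_bmis()] output as files: `bmis_dump.txt` in the
#' given dialect (readable by [read_bmis()]) and `ground_truth.csv`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param dialect Dump dialect, see [bmis_dialect()].
#' @return Invisibly, a list with `dump`, `truth` file paths and the
#'   simulated object.
#' @export
generate_bmis_dump <- function(config, dir, dialect = bmis_dialect()) {
  sim <- simulate_bmis(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump_path <- file.path(dir, "bmis_dump.txt")
  truth_path <- file.path(dir, "ground_truth.csv")
  write_bmis(sim$records, dump_path, dialect)
  truth_out <- dplyr::select(sim$truth, -"name_key")
  readr::write_csv(truth_out, truth_path, na = "")
  invisible(list(dump = dump_path, truth = truth_path, sim = sim))
}
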