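#' Quantify window-censoring misclassification by first-submission year
#'
#' A finite study window right-censors submission histories: a person whose
#' second submission would land past the window end is observed with a
#' single submission and classified one-and-done, inflating apparent
#' turnover in the late window years. This experiment simulates a registry
#' with known ground truth, runs the full pipeline (name filtering, id
#' assignment, history building, percentile classification) on the dump, and
#' reports, per first-submission year, the fraction of truly
#' multi-submission people the pipeline labels one-and-done.
#'
#' @param config A [synthetic_config()]; the generator's censoring flags are
#'   the ground truth.
#' @param percentile Percentile for the pipeline's gap cutoff.
#' @return A tibble with one row per window year: `year`, `n_true_multi`,
#'   `n_misclassified_oad`, `frac_misclassified` (`NA` for years with no
#'   truly-multi arrivals). The overall misclassified fraction is attached
#'   as attribute `overall_frac`.
#' @examples
#' cfg <- synthetic_config(
#'   n_investigators = 500, frac_single = 0,
#'   gap_distribution = gap_fixed(0), seed = 42
#' )
#' ce <- censoring_experiment(cfg)
#' sum(ce$n_misclassified_oad) # 0: same-day seconds are never censored
#' @export
censoring_experiment <- function(config, percentile = 75) {
  sim <- simulate_bmis(config)
  cohort <- sim$records |>
    exclude_invalid_names() |>
    assign_investigator_ids() |>
    build_histories() |>
    classify_phenotypes(percentile = percentile)

  key <- paste(
    normalize_name(cohort$last_name), normalize_name(cohort$first_name),
    sep = "\x1f"
  )
  observed <- setNames(as.character(cohort$phenotype), key)

  truth <- sim$truth |>
    dplyr::filter(!.data$single) |>
    dplyr::mutate(
      observed_phenotype = unname(observed[.data$name_key]),
      misclassified_oad = .data$observed_phenotype == "one_and_done"
    )

  years <- seq.int(config$window_start, config$window_end)
  out <- truth |>
    dplyr::count(
      year = .data$firsub_year,
      wt = NULL, name = "n_true_multi"
    ) |>
    dplyr::left_join(
      truth |>
        dplyr::filter(.data$misclassified_oad) |>
        dplyr::count(year = .data$firsub_year, name = "n_misclassified_oad"),
      by = "year"
    ) |>
    dplyr::right_join(tibble(year = years), by = "year") |>
    dplyr::arrange(.data$year) |>
    dplyr::mutate(
      n_true_multi = dplyr::coalesce(.data$n_true_multi, 0L),
      n_misclassified_oad = dplyr::coalesce(.data$n_misclassified_oad, 0L),
      frac_misclassified = ifelse(
        .data$n_true_multi > 0,
        .data$n_misclassified_oad / .data$n_true_multi,
        NA_real_
      )
    )
  attr(out, "overall_frac") <-
    sum(out$n_misclassified_oad) / max(sum(out$n_true_multi), 1L)
  out
}
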