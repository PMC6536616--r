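test_that("invalid last names ('??', empty, null) are excluded and counted", {
  recs <- make_records(c("SMITH", "??", "", "JONES"))
  got <- exclude_invalid_names(recs)
  expect_equal(got$last_name, c("SMITH", "JONES"))
  expect_equal(n_excluded(got), 2L)

  clean <- make_records(c("A", "B"))
  got2 <- exclude_invalid_names(clean)
  expect_equal(got2$last_name, clean$last_name)
  expect_equal(n_excluded(got2), 0L)

  # whitespace-only and NA last names are null-equivalent
  messy <- make_records(c("  ", NA, " ?? ", "OK"))
  expect_equal(n_excluded(exclude_invalid_names(messy)), 3L)
})

test_that("generator-injected invalid-name records equal the excluded count", {
  sim <- simulate_bmis(synthetic_config(
    n_investigators = 700, invalid_name_rate = 0.05, seed = 9
  ))
  n_valid_expected <- nrow(sim$records)
  got <- exclude_invalid_names(sim$records)
  n_injected <- round(0.05 * (n_valid_expected - n_excluded(got)))
  expect_equal(n_excluded(got), n_injected)
})

test_that("ids key on the normalized (last, first) combination", {
  recs <- make_records(
    last = c("SMITH", "smith", "SMITH"),
    first = c("ANN", " Ann ", "BOB")
  )
  got <- assign_investigator_ids(recs)
  expect_equal(got$newid, c(1L, 1L, 2L))

  distinct <- assign_investigator_ids(make_records(sprintf("N%02d", 1:7)))
  expect_equal(distinct$newid, 1:7)

  # strict mode keys on raw strings
  raw <- assign_investigator_ids(recs, normalize = FALSE)
  expect_equal(length(unique(raw$newid)), 3L)
})

test_that("distinct-id count matches an independent set-based scan under engineered collisions", {
  sim <- simulate_bmis(synthetic_config(
    n_investigators = 800, name_collision_rate = 0.15, seed = 13
  ))
  got <- assign_investigator_ids(sim$records)
  keys <- unique(paste(
    toupper(trimws(sim$records$last_name)),
    toupper(trimws(sim$records$first_name)),
    sep = "/"
  ))
  expect_equal(length(unique(got$newid)), length(keys))
  # collisions really did merge people
  expect_lt(length(keys), 800L)
})

test_that("histories derive firsub, secdiff and oad per the registry variable definitions", {
  recs <- make_records(
    last = c("A", "A"), date = c("2001-01-01", "2003-10-11")
  )
  h <- build_histories(assign_investigator_ids(recs))
  expect_equal(h$firsub, as.Date("2001-01-01"))
  expect_equal(h$secdiff, 1013L)
  expect_false(h$oad)

  single <- build_histories(assign_investigator_ids(make_records("B")))
  expect_true(single$oad)
  expect_true(is.na(single$secdiff))

  # third-and-later submissions are retained but never change secdiff
  recs3 <- make_records(
    last = rep("C", 3), date = c("2001-01-01", "2001-06-01", "2014-01-01")
  )
  h3 <- build_histories(assign_investigator_ids(recs3))
  expect_equal(h3$secdiff, 151L)
  expect_equal(h3$n_submissions, 3L)
  expect_equal(length(h3$submissions[[1]]), 3L)
})

test_that("secdiff equals a brute-force recomputation across 300 random investigators", {
  recs <- random_records(300, seed = 31)
  h <- build_histories(assign_investigator_ids(recs))
  key <- paste(recs$last_name, recs$first_name, sep = "/")
  for (i in seq_len(nrow(h))) {
    k <- paste(h$last_name[i], h$first_name[i], sep = "/")
    dates <- sort(recs$receipt_date[key == k])
    expected <- if (length(dates) >= 2) as.integer(dates[2] - dates[1]) else NA_integer_
    expect_identical(h$secdiff[i], expected)
    expect_identical(h$firsub[i], dates[1])
  }
})

test_that("same-day ties keep file order and a same-day second submission gives secdiff 0", {
  recs <- make_records(
    last = c("T", "T"), country = c("USA", "JAPAN"),
    date = c("2005-03-03", "2005-03-03")
  )
  h <- suppressMessages(build_histories(assign_investigator_ids(recs)))
  expect_equal(h$secdiff, 0L)
  expect_equal(as.character(h$location), "US") # first record in file order wins
})

test_that("location comes from the first submission's country, normalized", {
  expect_equal(as.character(classify_location(c("USA", "usa ", "CANADA"))), c("US", "US", "NON_US"))
  expect_equal(as.character(classify_location(c(NA, ""))), c("NON_US", "NON_US"))

  recs <- make_records(
    last = c("A", "A"), country = c("CANADA", "USA"),
    date = c("2001-01-01", "2002-01-01")
  )
  h <- suppressMessages(build_histories(assign_investigator_ids(recs)))
  expect_equal(as.character(h$location), "NON_US")
  expect_equal(attr(h, "n_country_conflicts"), 1L)
})

test_that("a configured 60/40 US mix is recovered within binomial tolerance at n = 5000", {
  sim <- simulate_bmis(synthetic_config(n_investigators = 5000, frac_us = 0.6, seed = 17))
  h <- build_histories(assign_investigator_ids(sim$records))
  frac_us <- mean(h$location == "US")
  expect_lt(abs(frac_us - 0.6), 0.02)
})

test_that("histories are invariant to input record order and conserve record counts", {
  recs <- random_records(150, seed = 41)
  h1 <- build_histories(assign_investigator_ids(recs))
  perm <- withr::with_seed(42, recs[sample.int(nrow(recs)), ])
  h2 <- build_histories(assign_investigator_ids(perm))

  norm <- function(h) {
    out <- h[order(h$last_name, h$first_name), c("last_name", "first_name", "firsub", "secdiff", "oad", "n_submissions", "location")]
    rownames(out) <- NULL
    out
  }
  expect_equal(norm(as.data.frame(h1)), norm(as.data.frame(h2)))

  # conservation: submissions across histories = input records
  expect_equal(sum(h1$n_submissions), nrow(recs))
  # oad <=> secdiff absent
  expect_equal(h1$oad, is.na(h1$secdiff))
})

test_that("rebuilding histories from a serialized cohort reproduces the derived variables", {
  cohort <- default_pipeline(random_records(120, seed = 51))
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  relabeled <- classify_phenotypes(back, percentile = 75)
  ord <- order(cohort$newid)
  expect_equal(relabeled$secdiff, cohort$secdiff[ord])
  expect_equal(relabeled$oad, cohort$oad[ord])
  expect_equal(as.character(relabeled$phenotype), as.character(cohort$phenotype[ord]))
})
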