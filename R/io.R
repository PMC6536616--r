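#' Describe the physical layout of a BMIS-style dump
#'
#' The public BMIS download is a delimited flat file whose exact layout has
#' varied across vintages. A dialect bundles everything needed to interpret
#' one: the field delimiter, an ordered list of date formats (first match
#' wins), a map from the four semantic fields to source column names (or
#' 1-based positions for headerless files), the text encoding, and whether a
#' header row is present.
#'
#' @param delimiter Single field-separator character. Pipe is the default,
#'   the common choice for FDA flat-file exports.
#' @param date_formats Character vector of `strptime` patterns tried in order
#'   when parsing receipt dates.
#' @param column_map Named character (or integer) vector with names
#'   `last_name`, `first_name`, `country_name`, `receipt_date` giving the
#'   source column for each semantic field. Integer values are 1-based column
#'   positions for headerless files.
#' @param encoding Source text encoding. Files that are not valid UTF-8 fall
#'   back to latin1 with a warning.
#' @param has_header Logical; does the first line name the columns?
#'
#' @return An object of class `bmis_dialect`.
#' @examples
#' bmis_dialect()
#' bmis_dialect(delimiter = ",", date_formats = "%m/%d/%Y")
#' @export
bmis_dialect <- function(delimiter = "|",
                         date_formats = c("%Y-%m-%d", "%m/%d/%Y"),
                         column_map = c(
                           last_name = "LAST_NAME",
                           first_name = "FIRST_NAME",
                           country_name = "COUNTRY_NAME",
                           receipt_date = "RECEIVED_DATE"
                         ),
                         encoding = "UTF-8",
                         has_header = TRUE) {
  if (!is.character(delimiter) || length(delimiter) != 1L || nchar(delimiter) != 1L) {
    abort("`delimiter` must be a single character.")
  }
  needed <- c("last_name", "first_name", "country_name", "receipt_date")
  if (!setequal(names(column_map), needed) || anyDuplicated(names(column_map))) {
    abort(paste0(
      "`column_map` must name each of ",
      paste(needed, collapse = ", "), " exactly once."
    ))
  }
  structure(
    list(
      delimiter = delimiter,
      date_formats = as.character(date_formats),
      column_map = column_map[needed],
      encoding = encoding,
      has_header = isTRUE(has_header)
    ),
    class = "bmis_dialect"
  )
}

#' @export
print.bmis_dialect <- function(x, ...) {
  cat("<bmis_dialect>\n")
  cat("  delimiter:    ", deparse(x$delimiter), "\n", sep = "")
  cat("  date formats: ", paste(x$date_formats, collapse = ", "), "\n", sep = "")
  cat("  header:       ", x$has_header, "\n", sep = "")
  map <- paste(names(x$column_map), "=", x$column_map, collapse = ", ")
  cat("  column map:   ", map, "\n", sep = "")
  invisible(x)
}

# Try each format in order; first successful parse wins.
parse_dates <- function(x, formats) {
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  for (fmt in formats) {
    idx <- which(is.na(out))
    if (length(idx) == 0L) break
    out[idx] <- as.Date(x[idx], format = fmt)
  }
  out
}

read_dump_lines <- function(path, encoding) {
  lines <- readLines(path, warn = FALSE, encoding = "bytes")
  bad <- !validUTF8(lines)
  if (identical(toupper(encoding), "UTF-8") && any(bad)) {
    warn(sprintf(
      "%d line(s) were not valid UTF-8; falling back to latin1.", sum(bad)
    ))
    lines[bad] <- iconv(lines[bad], from = "latin1", to = "UTF-8")
  }
  lines
}

#' Read a BMIS-style flat-file dump into submission records
#'
#' Each well-formed row becomes one submission record; malformed rows (wrong
#' field count, unparseable receipt date) are never silently dropped - they
#' are collected in a rejection log, retrievable with [rejections()], citing
#' the file row and the reason. Output order equals file order. Columns not
#' named in the dialect's `column_map` are carried along untouched as
#' passthrough columns; nothing downstream reads them.
#'
#' @param path Path to the delimited dump.
#' @param dialect A [bmis_dialect()] describing the file layout.
#'
#' @return A tibble with columns `last_name`, `first_name`, `country_name`,
#'   `receipt_date` (class `Date`) and any passthrough columns, one row per
#'   accepted record, with the rejection log attached as an attribute.
#'
#' @section Errors: A missing file, `column_map` names absent from the
#'   header, or more than half of the data rows rejected (taken as evidence
#'   of a dialect mismatch) are fatal.
#' @seealso [write_bmis()], [rejections()], [filter_window()]
#' @export
read_bmis <- function(path, dialect = bmis_dialect()) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'", path))
  }
  lines <- read_dump_lines(path, dialect$encoding)
  delim <- dialect$delimiter
  cmap <- dialect$column_map

  if (dialect$has_header) {
    if (length(lines) == 0L) abort("Empty file: header row expected.")
    header <- strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]]
    data_lines <- lines[-1L]
    first_row <- 2L
    if (is.numeric(cmap)) {
      pos <- as.integer(cmap)
    } else {
      pos <- match(cmap, header)
      if (anyNA(pos)) {
        abort(sprintf(
          "Column(s) not found in header: %s",
          paste(cmap[is.na(pos)], collapse = ", ")
        ))
      }
    }
    n_fields <- length(header)
  } else {
    header <- NULL
    data_lines <- lines
    first_row <- 1L
    pos <- as.integer(cmap)
    if (anyNA(pos)) {
      abort("Headerless files need integer column positions in `column_map`.")
    }
    n_fields <- if (length(data_lines)) {
      length(strsplit(data_lines[[1L]], delim, fixed = TRUE)[[1L]])
    } else {
      max(pos)
    }
  }
  names(pos) <- names(cmap)
  if (any(pos > n_fields)) {
    abort("`column_map` positions exceed the file's column count.")
  }

  fields <- strsplit(data_lines, delim, fixed = TRUE)
  counts <- lengths(fields)
  # trailing empty field is dropped by strsplit; tolerate one short when the
  # line ends with the delimiter
  ends_delim <- endsWith(data_lines, delim)
  counts[ends_delim & counts == n_fields - 1L] <- n_fields
  fields[ends_delim & lengths(fields) == n_fields - 1L] <-
    lapply(fields[ends_delim & lengths(fields) == n_fields - 1L], function(f) c(f, ""))

  ok_count <- counts == n_fields
  rej <- tibble(
    row = integer(), reason = character(), line = character()
  )
  if (any(!ok_count)) {
    bad <- which(!ok_count)
    rej <- dplyr::bind_rows(rej, tibble(
      row = bad + first_row - 1L,
      reason = sprintf("expected %d fields, found %d", n_fields, counts[bad]),
      line = data_lines[bad]
    ))
  }

  keep <- which(ok_count)
  mat <- if (length(keep)) {
    matrix(unlist(fields[keep]), nrow = length(keep), byrow = TRUE)
  } else {
    matrix(character(), nrow = 0L, ncol = n_fields)
  }

  raw_date <- mat[, pos[["receipt_date"]]]
  dates <- parse_dates(raw_date, dialect$date_formats)
  bad_date <- is.na(dates)
  if (any(bad_date)) {
    idx <- which(bad_date)
    rej <- dplyr::bind_rows(rej, tibble(
      row = keep[idx] + first_row - 1L,
      reason = sprintf("unparseable receipt date '%s'", raw_date[idx]),
      line = data_lines[keep[idx]]
    ))
  }
  rej <- dplyr::arrange(rej, .data$row)

  n_data <- length(data_lines)
  if (n_data > 0L && nrow(rej) / n_data > 0.5) {
    abort(sprintf(
      "%d of %d rows rejected (>50%%): the dialect probably does not match this file.",
      nrow(rej), n_data
    ))
  }

  acc <- !bad_date
  out <- tibble(
    last_name = mat[acc, pos[["last_name"]]],
    first_name = mat[acc, pos[["first_name"]]],
    country_name = mat[acc, pos[["country_name"]]],
    receipt_date = dates[acc]
  )
  extra <- setdiff(seq_len(n_fields), pos)
  if (length(extra)) {
    extra_names <- if (is.null(header)) paste0("V", extra) else header[extra]
    for (k in seq_along(extra)) {
      out[[extra_names[k]]] <- mat[acc, extra[k]]
    }
  }
  attr(out, "rejections") <- rej
  out
}

#' Retrieve the rejection log attached by [read_bmis()]
#'
#' @param x A tibble returned by [read_bmis()].
#' @return A tibble with columns `row`, `reason`, `line` (empty when every
#'   row was accepted).
#' @export
rejections <- function(x) {
  attr(x, "rejections") %||%
    tibble(row = integer(), reason = character(), line = character())
}

#' Restrict submission records to a study window
#'
#' Keeps exactly the records whose receipt-date year falls in
#' `[start_year, end_year]`, preserving order. The study this package models
#' used 1999-2015 inclusive.
#'
#' @param records Tibble of submission records with a `receipt_date` column.
#' @param start_year,end_year Integer years, inclusive bounds.
#' @return The filtered tibble, order preserved.
#' @export
filter_window <- function(records, start_year = 1999L, end_year = 2015L) {
  if (start_year > end_year) {
    abort("`start_year` must not exceed `end_year`.")
  }
  yr <- as.integer(format(records$receipt_date, "%Y"))
  records[!is.na(yr) & yr >= start_year & yr <= end_year, , drop = FALSE]
}

#' Write submission records as a BMIS-style dump
#'
#' Inverse of [read_bmis()] for the four semantic fields plus passthrough
#' columns; dates are formatted with the dialect's first date format. The
#' round trip `read_bmis(write_bmis(x))` is lossless for the semantic fields.
#'
#' @param records Tibble with `last_name`, `first_name`, `country_name`,
#'   `receipt_date` columns (and optional passthrough columns).
#' @param path Output path.
#' @param dialect A [bmis_dialect()].
#' @return `path`, invisibly.
#' @export
write_bmis <- function(records, path, dialect = bmis_dialect()) {
  delim <- dialect$delimiter
  cmap <- dialect$column_map
  semantic <- c("last_name", "first_name", "country_name", "receipt_date")
  missing_cols <- setdiff(semantic, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  passthrough <- setdiff(names(records), semantic)
  cols <- c(
    setNames(as.list(records[semantic]), unname(cmap)),
    setNames(as.list(records[passthrough]), passthrough)
  )
  cols[[cmap[["receipt_date"]]]] <-
    format(records$receipt_date, dialect$date_formats[[1L]])
  txt <- vapply(cols, as.character, character(nrow(records)))
  if (nrow(records) == 1L) txt <- matrix(txt, nrow = 1L)
  if (nrow(records) > 0L && any(grepl(delim, txt, fixed = TRUE))) {
    abort("A field contains the delimiter; choose a different delimiter.")
  }
  body <- if (nrow(records)) apply(txt, 1L, paste, collapse = delim) else character()
  out_lines <- c(
    if (dialect$has_header) paste(names(cols), collapse = delim),
    body
  )
  writeLines(out_lines, path, useBytes = FALSE)
  invisible(path)
}

#' Serialize a labeled investigator cohort
#'
#' Writes one CSV row per unique investigator: `newid`, `last_name`,
#' `first_name`, `location`, `firsub`, `secdiff` (empty for single-submission
#' investigators) and `phenotype`, ordered by `newid`. The file is re-read by
#' [read_cohort()].
#'
#' @param cohort A labeled cohort from [classify_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!"phenotype" %in% names(cohort)) {
    abort("Every history must carry a phenotype label; run classify_phenotypes() first.")
  }
  out <- cohort |>
    dplyr::select(
      "newid", "last_name", "first_name", "location",
      "firsub", "secdiff", "phenotype"
    ) |>
    dplyr::arrange(.data$newid)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a cohort file written by [write_cohort()]
#'
#' Restores the derived variables; `oad` is recovered as the absence of a
#' second-submission gap. The full submission sequence beyond the first two
#' dates is not serialized, so `n_submissions` is reported as 1 or 2.
#'
#' @param path Path to a cohort CSV.
#' @return A tibble in the shape produced by [classify_phenotypes()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      newid = readr::col_integer(),
      last_name = readr::col_character(),
      first_name = readr::col_character(),
      location = readr::col_character(),
      firsub = readr::col_date(),
      secdiff = readr::col_integer(),
      phenotype = readr::col_character()
    ),
    na = ""
  )
  out$last_name[is.na(out$last_name)] <- ""
  out$first_name[is.na(out$first_name)] <- ""
  out$location <- factor(out$location, levels = location_levels())
  out$phenotype <- factor(out$phenotype, levels = phenotype_levels())
  out$oad <- is.na(out$secdiff)
  out$n_submissions <- ifelse(out$oad, 1L, 2L)
  out
}
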