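#' Read delimited laboratory-test records
#'
#' Parses a delimited text file (or connection) of laboratory-test records of
#' the kind produced by clinical laboratory information systems: one row per
#' ordered test, with a header row naming at least the patient identifier,
#' the service date and the test code. All other columns (requisition number,
#' demographics, results, normal ranges, ...) are ignored.
#'
#' Rows missing any of the three required fields after whitespace trimming are
#' skipped; the number of skipped rows is attached as attribute `n_skipped`
#' and reported via a diagnostic message when `options(labrec.verbose = TRUE)`.
#' Rows whose service date does not parse under `date_format` are kept with an
#' `NA` date: the date is only needed when grouping by visit, and
#' [group_cases()] drops them (with a count) in that case.
#'
#' @param file path or connection to delimited text with a header row.
#' @param columns named character vector mapping the roles `patient`, `date`
#'   and `test` to column names in the header. Defaults to the common
#'   `PNUM` / `SDTE` / `TEST` layout.
#' @param date_format date format string for [base::as.Date()]; default
#'   ISO-8601 (`"%Y-%m-%d"`).
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A data frame with columns `patient_id` (character), `service_date`
#'   (`Date`, possibly `NA`) and `test_code` (character), one row per usable
#'   record, with attribute `n_skipped`.
#' @seealso [group_cases()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("SDTE,PNUM,TEST", "2024-01-05,p1,GLUF", "2024-01-05,p1,HBA1C"), f)
#' read_lab_records(f)
#' @export
read_lab_records <- function(file,
                             columns = c(patient = "PNUM", date = "SDTE", test = "TEST"),
                             date_format = "%Y-%m-%d",
                             sep = NULL) {
  stopifnot(all(c("patient", "date", "test") %in% names(columns)))
  if (is.character(file) && !file.exists(file))
    stop("cannot read input: no such file: ", file, call. = FALSE)
  lines <- tryCatch(readLines(file, warn = FALSE),
                    error = function(e) stop("cannot read input: ", conditionMessage(e),
                                             call. = FALSE))
  if (length(lines) == 0L) stop("input is empty", call. = FALSE)
  if (is.null(sep)) {
    sep <- if (lengths(regmatches(lines[1L], gregexpr("\t", lines[1L]))) >=
               lengths(regmatches(lines[1L], gregexpr(",", lines[1L])))) "\t" else ","
  }
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", fill = TRUE,
                          strip.white = TRUE)
  for (role in c("patient", "date", "test")) {
    if (!columns[[role]] %in% names(df))
      stop("missing column ", columns[[role]], call. = FALSE)
  }
  patient <- trimws(df[[columns[["patient"]]]])
  date_raw <- trimws(df[[columns[["date"]]]])
  test <- trimws(df[[columns[["test"]]]])
  keep <- !is.na(patient) & patient != "" &
          !is.na(test) & test != "" &
          !is.na(date_raw) & date_raw != ""
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    labrec_log(n_skipped, " row(s) skipped for missing required fields")
  out <- data.frame(
    patient_id   = patient[keep],
    service_date = as.Date(date_raw[keep], format = date_format),
    test_code    = test[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Construct a set of patient cases
#'
#' A *case* is the unit over which laboratory tests are considered taken
#' together: either one patient, or one patient-visit (patient plus service
#' date). Each case holds the deduplicated set of its test codes; the
#' *test universe* is the lexicographically sorted set of all codes observed.
#'
#' @param tests a named list of character vectors of test codes, one element
#'   per case (names become case ids; generated if absent). Duplicate codes
#'   within a case are collapsed.
#' @param patient_id optional character vector, the patient each case belongs
#'   to (used to keep a patient's cases on one side of a train/validation
#'   split); defaults to one patient per case.
#' @param universe optional character vector of test codes; defaults to the
#'   sorted union of codes in `tests`. Must cover every code used.
#' @param unit label for the grouping unit, `"visit"` or `"patient"`.
#' @return An object of class `case_set`: a list with elements `cases` (named
#'   list of sorted unique code vectors), `patient_id`, `universe` and `unit`.
#' @examples
#' cs <- case_set(list(v1 = c("A", "B"), v2 = c("A", "B"), v3 = c("A", "C"), v4 = "C"))
#' cs
#' case_sizes(cs)
#' @export
case_set <- function(tests, patient_id = NULL, universe = NULL, unit = "visit") {
  stopifnot(is.list(tests))
  if (length(tests) == 0L) stop("no cases given", call. = FALSE)
  tests <- lapply(tests, function(x) sort(unique(as.character(x))))
  if (is.null(names(tests)) || anyNA(names(tests)) || any(names(tests) == ""))
    names(tests) <- sprintf("case_%d", seq_along(tests))
  if (anyDuplicated(names(tests)))
    stop("case ids must be unique", call. = FALSE)
  if (is.null(patient_id)) patient_id <- names(tests)
  stopifnot(length(patient_id) == length(tests))
  observed <- sort(unique(unlist(tests, use.names = FALSE)))
  if (is.null(universe)) universe <- observed
  universe <- sort(unique(as.character(universe)))
  missing <- setdiff(observed, universe)
  if (length(missing) > 0L)
    stop("test code(s) outside universe: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(
    list(cases = tests, patient_id = as.character(patient_id),
         universe = universe, unit = unit),
    class = "case_set"
  )
}

#' Group laboratory records into cases
#'
#' Groups parsed records (see [read_lab_records()]) into analysis cases by
#' patient-visit (default) or by patient. Repeated test codes within a unit
#' are counted once: every probability downstream is a fraction of *cases*,
#' not of records.
#'
#' When `unit = "visit"`, rows with an unparseable (`NA`) service date cannot
#' be assigned to a visit and are dropped with a count (attribute
#' `n_skipped`); when `unit = "patient"` the date is unused and such rows are
#' kept.
#'
#' @param records data frame with columns `patient_id`, `service_date`,
#'   `test_code`, as returned by [read_lab_records()].
#' @param unit `"visit"` (patient + service date) or `"patient"`.
#' @return A [case_set()] whose universe is every test code observed.
#' @export
group_cases <- function(records, unit = c("visit", "patient")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(records),
            all(c("patient_id", "service_date", "test_code") %in% names(records)))
  if (nrow(records) == 0L) stop("no records to group", call. = FALSE)
  n_skipped <- 0L
  if (unit == "visit") {
    bad <- is.na(records$service_date)
    n_skipped <- sum(bad)
    if (n_skipped > 0L) {
      labrec_log(n_skipped, " row(s) dropped: unparseable date under unit=visit")
      records <- records[!bad, , drop = FALSE]
    }
    if (nrow(records) == 0L) stop("no records with usable dates", call. = FALSE)
    key <- paste(records$patient_id, format(records$service_date), sep = "@")
  } else {
    key <- records$patient_id
  }
  split_tests <- split(records$test_code, key)
  first <- !duplicated(key)
  patient_of <- setNames(records$patient_id[first], key[first])
  cs <- case_set(split_tests,
                 patient_id = unname(patient_of[names(split_tests)]),
                 unit = unit)
  attr(cs, "n_skipped") <- n_skipped
  cs
}

#' Number of tests taken in each case
#'
#' @param cs a [case_set()].
#' @return Named integer vector of case sizes (the `k` of each case).
#' @export
case_sizes <- function(cs) {
  stopifnot(inherits(cs, "case_set"))
  vapply(cs$cases, length, integer(1))
}

#' @export
length.case_set <- function(x) length(x$cases)

#' @export
`[.case_set` <- function(x, i) {
  structure(
    list(cases = x$cases[i], patient_id = x$patient_id[i],
         universe = x$universe, unit = x$unit),
    class = "case_set"
  )
}

#' @export
print.case_set <- function(x, ...) {
  k <- case_sizes(x)
  cat(sprintf("<case_set> %d case(s) (unit = %s), %d test(s) in universe\n",
              length(x), x$unit, length(x$universe)))
  cat(sprintf("  tests per case: min %d, median %.1f, max %d\n",
              min(k), stats::median(k), max(k)))
  invisible(x)
}

#' Write / read a normalized case file
#'
#' One line per case: `case_id<TAB>comma-separated test codes`.
#'
#' @param cs a [case_set()].
#' @param file path to write to / read from.
#' @return `write_case_file()` returns `file` invisibly; `read_case_file()`
#'   returns a [case_set()].
#' @export
write_case_file <- function(cs, file) {
  stopifnot(inherits(cs, "case_set"))
  writeLines(paste(names(cs$cases),
                   vapply(cs$cases, paste, "", collapse = ","), sep = "\t"),
             file)
  invisible(file)
}

#' @rdname write_case_file
#' @export
read_case_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed case file: expected `case_id<TAB>codes`", call. = FALSE)
  tests <- lapply(parts, function(p) strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  names(tests) <- vapply(parts, `[`, "", 1L)
  case_set(tests)
}
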