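#' @title Reading and filtering prescription records
#' @description
#' A prescription record is one dispensed-drug event: a patient identifier,
#' the patient's sex (F/M) and birth year, the dispensation date and a
#' level-5 ATC code. Records are held as a plain `data.frame` with columns
#' `patient_id`, `sex`, `birth_year`, `date`, `atc5`. Cleaning mirrors the
#' practice of administrative dispensation databases: rows with a missing
#' mandatory field, an unparseable ATC code or an unparseable date are
#' counted as incomplete/ambiguous and dropped; patients are then restricted
#' to a plausible birth-year window (default 1919-2019).
#' @name records_ingest
NULL

.RECORD_COLS <- c("patient_id", "sex", "birth_year", "date", "atc5")

# empty filter report
.emptyReport <- function(records_in = 0L, patients_in = 0L) {
  list(records_in = records_in, records_out = records_in,
       patients_in = patients_in, patients_out = patients_in,
       dropped_by_rule = integer(0))
}

.reportDrop <- function(report, rule, n_records, records_out, patients_out) {
  report$dropped_by_rule[rule] <- sum(report$dropped_by_rule[rule], n_records,
                                      na.rm = TRUE)
  report$records_out <- records_out
  report$patients_out <- patients_out
  report
}

#' Read prescription records from delimited text
#'
#' Reads a delimited file with a header, maps its columns onto the record
#' schema, and applies the incomplete/ambiguous exclusion: any row with a
#' missing mandatory field, an ATC string that fails validation, an
#' unparseable date, or a sex outside F/M is dropped and counted.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param columns named character vector mapping schema names
#'   (`patient_id`, `sex`, `birth_year`, `date`, `atc5`) to column names in
#'   the file. Defaults to identity.
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @return a list with `records` (data.frame of clean records, with `atc5`
#'   uppercased and `date` as `Date`) and `report` (a filter report: counts
#'   in/out and drops per rule).
#' @export
loadRecords <- function(path, columns = NULL, sep = ",") {
  if (!file.exists(path)) stop("cannot read records file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = TRUE)
  if (is.null(columns)) columns <- stats::setNames(.RECORD_COLS, .RECORD_COLS)
  missing_map <- setdiff(.RECORD_COLS, names(columns))
  if (length(missing_map)) {
    stop("column mapping incomplete, missing: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(columns[.RECORD_COLS]), names(raw))
  if (length(absent)) {
    stop("schema error: file has no column(s) ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    patient_id = raw[[columns[["patient_id"]]]],
    sex = toupper(trimws(raw[[columns[["sex"]]]])),
    birth_year = suppressWarnings(as.integer(raw[[columns[["birth_year"]]]])),
    date = raw[[columns[["date"]]]],
    atc5 = toupper(trimws(raw[[columns[["atc5"]]]])),
    stringsAsFactors = FALSE
  )
  report <- .emptyReport(nrow(df), length(unique(df$patient_id)))
  if (nrow(df) == 0L) {
    df$date <- as.Date(character(0))
    return(list(records = df, report = report))
  }

  parsed_date <- as.Date(df$date, format = "%Y-%m-%d")
  ok <- !is.na(df$patient_id) & nzchar(trimws(df$patient_id)) &
    df$sex %in% c("F", "M") &
    !is.na(df$birth_year) &
    !is.na(parsed_date) &
    isValidATC(df$atc5) & nchar(df$atc5) == 7L
  dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  df$date <- parsed_date[ok]
  rownames(df) <- NULL
  report <- .reportDrop(report, "incomplete_or_ambiguous", dropped,
                        nrow(df), length(unique(df$patient_id)))
  list(records = df, report = report)
}

#' Restrict records to a plausible birth-year window
#'
#' Keeps records whose patient birth year lies in `[min_year, max_year]`,
#' both bounds inclusive. The default window 1919-2019 corresponds to ages
#' 0-100 at a mid-2019 index date.
#'
#' @param records record data.frame as returned by [loadRecords].
#' @param min_year,max_year inclusive birth-year bounds.
#' @return a list with filtered `records` and a filter `report`; the report's
#'   `dropped_by_rule[["birth_year_out_of_range"]]` counts dropped records and
#'   `patients_dropped` the distinct patients removed.
#' @export
filterBirthYear <- function(records, min_year = 1919L, max_year = 2019L) {
  stopifnot(min_year <= max_year)
  report <- .emptyReport(nrow(records), length(unique(records$patient_id)))
  keep <- records$birth_year >= min_year & records$birth_year <= max_year
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- .reportDrop(report, "birth_year_out_of_range", sum(!keep),
                        nrow(out), length(unique(out$patient_id)))
  report$patients_dropped <- report$patients_in - report$patients_out
  list(records = out, report = report)
}

#' Build the patient-by-drug incidence at an ATC level
#'
#' Projects every record's level-5 code to `level` and forms, per patient,
#' the set of distinct codes prescribed. Repeat prescriptions of the same
#' drug (or of two drugs merging at the coarser level) contribute a single
#' membership: the incidence is the base for patient counts Pi, not
#' prescription counts.
#'
#' @param records record data.frame.
#' @param level ATC level 1-5.
#' @return an incidence map: a sparse logical patient-by-code matrix
#'   (class [Matrix::lgCMatrix-class]) with patients as rows, codes at
#'   `level` as columns, plus attributes `level` and `n_patients`.
#' @export
buildIncidence <- function(records, level) {
  level <- as.integer(level)
  stopifnot(length(level) == 1L, level >= 1L, level <= 5L)
  if (nrow(records) == 0L) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = logical(0),
                              dims = c(0L, 0L))
    attr(m, "level") <- level
    return(m)
  }
  code <- substr(records$atc5, 1L, .ATC_LEVEL_NCHAR[level])
  pid <- factor(records$patient_id)
  cid <- factor(code)
  m <- Matrix::sparseMatrix(
    i = as.integer(pid), j = as.integer(cid), x = TRUE,
    dims = c(nlevels(pid), nlevels(cid)),
    dimnames = list(levels(pid), levels(cid)),
    use.last.ij = TRUE
  )
  m <- methods::as(m, "lMatrix")
  attr(m, "level") <- level
  m
}

#' Age at a fixed index date, from birth year
#'
#' @param birth_year integer vector.
#' @param index_date the end of the observation window (`Date` or string).
#' @return integer ages (index year minus birth year).
#' @export
ageAtIndex <- function(birth_year, index_date) {
  as.integer(format(as.Date(index_date), "%Y")) - as.integer(birth_year)
}

#' Demography of a record set
#'
#' Cross-tabulates distinct patients and prescription events by sex and age
#' stratum. Age is computed once at the index date (the final day of the
#' observation window), matching the single static age pyramid reported for
#' administrative cohorts. Records implying a negative age at the index date
#' are excluded and counted.
#'
#' @param records record data.frame.
#' @param index_date index date for age computation.
#' @param age_breaks lower bounds of the age strata; the default
#'   `c(0, 22, 65)` gives strata 0-21, 22-64 and 65+.
#' @return a list with `patients` and `prescriptions` tables (counts and
#'   percentages by sex within age stratum; percentages sum to 100), and
#'   `excluded_negative_age` (record count).
#' @export
demographyTable <- function(records, index_date = "2019-06-30",
                            age_breaks = c(0, 22, 65)) {
  age <- ageAtIndex(records$birth_year, index_date)
  neg <- age < 0
  records <- records[!neg, , drop = FALSE]
  age <- age[!neg]
  labs <- c(paste0(age_breaks[-length(age_breaks)], "-",
                   age_breaks[-1] - 1L),
            paste0(age_breaks[length(age_breaks)], "+"))
  stratum <- cut(age, breaks = c(age_breaks, Inf), labels = labs,
                 right = FALSE)
  tab <- function(counted) {
    t <- as.data.frame(table(sex = counted$sex, stratum = counted$stratum))
    names(t)[3] <- "n"
    t$pct <- if (sum(t$n) > 0) 100 * t$n / sum(t$n) else rep(0, nrow(t))
    t
  }
  per_patient <- !duplicated(records$patient_id)
  patients <- tab(data.frame(sex = records$sex[per_patient],
                             stratum = stratum[per_patient]))
  prescriptions <- tab(data.frame(sex = records$sex, stratum = stratum))
  list(patients = patients, prescriptions = prescriptions,
       excluded_negative_age = sum(neg))
}
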