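#' @title Claims data model and delimited IO
#' @description Readers and writers for the claims format consumed by the
#'   whole pipeline, plus day-index date helpers. Dates are stored internally
#'   as integer day indices (days since 1970-01-01): every temporal rule in
#'   the case-finding algorithm (3-day reaction window, next-day stop, 30-day
#'   washout) is day-granular, so all window arithmetic is integer
#'   subtraction.
#' @name claims_io
NULL

CLAIMS_COLUMNS <- c("participant_id", "age", "gender", "date", "drug",
                    "setting", "hospital_level")
SETTINGS <- c("outpatient", "inpatient")
HOSPITAL_LEVELS <- c("tertiary", "secondary", "primary_healthcare")
GENDERS <- c("male", "female")

#' Convert ISO-8601 dates to integer day indices
#'
#' @param x Character vector of `YYYY-MM-DD` dates, or `Date`.
#' @return Integer vector of days since 1970-01-01; invalid dates become `NA`.
#' @export
to_day_index <- function(x) {
  if (inherits(x, "Date")) return(as.integer(x))
  d <- as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
  # as.Date accepts out-of-range components by rolling over in some locales;
  # require exact round-trip so "2015-13-40" is rejected.
  ok <- !is.na(d) & format(d, "%Y-%m-%d") == as.character(x)
  ifelse(ok, as.integer(d), NA_integer_)
}

#' Convert integer day indices back to ISO-8601 date strings
#'
#' @param n Integer vector of day indices (days since 1970-01-01).
#' @return Character vector of `YYYY-MM-DD` dates.
#' @export
from_day_index <- function(n) {
  format(as.Date(as.integer(n), origin = "1970-01-01"), "%Y-%m-%d")
}

#' Read a claims file
#'
#' Reads a UTF-8 comma-delimited claims file with header
#' `participant_id,age,gender,date,drug,setting,hospital_level` into a record
#' table and a per-participant profile table. One row is one prescription of
#' one drug on one calendar date. Drug names are normalized against the
#' vocabulary; names outside the vocabulary are retained verbatim but flagged
#' with a message (they are ignored by downstream exposure coding).
#'
#' Profiles are derived one per participant: age and gender from the first
#' row, the visit setting and hospital level of the first index-drug
#' prescription (used as propensity covariates), and the observation window as
#' the span of the participant's prescription dates.
#'
#' @param path Path to the claims file.
#' @param vocabulary A [drug_vocabulary()].
#' @return A list with elements `records` (data.frame: `participant_id`,
#'   `drug`, `date` (integer day index), `setting`, `hospital_level`) and
#'   `profiles` (data.frame: `participant_id`, `age`, `gender`,
#'   `first_xyp_setting`, `first_xyp_hospital_level`, `observation_start`,
#'   `observation_end`).
#' @export
read_claims <- function(path, vocabulary = drug_vocabulary()) {
  if (!file.exists(path)) stop("claims file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(raw), CLAIMS_COLUMNS))
    stop("claims header must be exactly: ",
         paste(CLAIMS_COLUMNS, collapse = ","),
         " (got: ", paste(names(raw), collapse = ","), ")")
  if (nrow(raw) == 0) {
    return(list(records = empty_records(), profiles = empty_profiles()))
  }
  day <- to_day_index(raw$date)
  if (anyNA(day)) {
    bad <- which(is.na(day))[1]
    stop("malformed date '", raw$date[bad], "' at data line ", bad,
         " (file line ", bad + 1L, ")")
  }
  age <- suppressWarnings(as.numeric(raw$age))
  if (anyNA(age) || any(age < 0)) {
    bad <- which(is.na(age) | age < 0)[1]
    stop("invalid age '", raw$age[bad], "' at data line ", bad)
  }
  check_enum(raw$gender, GENDERS, "gender")
  check_enum(raw$setting, SETTINGS, "setting")
  check_enum(raw$hospital_level, HOSPITAL_LEVELS, "hospital_level")
  drug <- normalize_drug(raw$drug)
  if (any(!nzchar(drug))) stop("empty drug name at data line ",
                               which(!nzchar(drug))[1])
  known <- c(vocabulary$xyp_name, vocabulary$marker_drugs,
             vocabulary$target_concomitants)
  unknown <- setdiff(unique(drug), known)
  if (length(unknown))
    message("read_claims: ", length(unknown),
            " drug name(s) outside the vocabulary retained verbatim: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  records <- data.frame(participant_id = raw$participant_id, drug = drug,
                        date = day, setting = raw$setting,
                        hospital_level = raw$hospital_level,
                        stringsAsFactors = FALSE)
  profiles <- derive_profiles(records, age, raw$gender, vocabulary)
  list(records = records, profiles = profiles)
}

check_enum <- function(x, levels, what) {
  bad <- !(x %in% levels)
  if (any(bad))
    stop("invalid ", what, " '", x[which(bad)[1]], "' at data line ",
         which(bad)[1], " (expected one of: ",
         paste(levels, collapse = ", "), ")")
  invisible(TRUE)
}

empty_records <- function() {
  data.frame(participant_id = character(), drug = character(),
             date = integer(), setting = character(),
             hospital_level = character(), stringsAsFactors = FALSE)
}

empty_profiles <- function() {
  data.frame(participant_id = character(), age = numeric(),
             gender = character(), first_xyp_setting = character(),
             first_xyp_hospital_level = character(),
             observation_start = integer(), observation_end = integer(),
             stringsAsFactors = FALSE)
}

derive_profiles <- function(records, age, gender, vocabulary) {
  ord <- order(records$participant_id, records$date)
  rec <- records[ord, , drop = FALSE]
  age <- age[ord]
  gender <- gender[ord]
  first_row <- !duplicated(rec$participant_id)
  ids <- rec$participant_id[first_row]
  # propensity covariates come from the first index-drug prescription row;
  # participants with no index-drug row fall back to their first row
  is_xyp <- rec$drug == vocabulary$xyp_name
  xyp_first <- !duplicated(rec$participant_id[is_xyp])
  xyp_rows <- which(is_xyp)[xyp_first]
  m <- match(ids, rec$participant_id[xyp_rows])
  cov_row <- ifelse(is.na(m), which(first_row), xyp_rows[m])
  data.frame(participant_id = ids,
             age = age[first_row],
             gender = gender[first_row],
             first_xyp_setting = rec$setting[cov_row],
             first_xyp_hospital_level = rec$hospital_level[cov_row],
             observation_start = as.integer(tapply(rec$date, rec$participant_id, min)[ids]),
             observation_end = as.integer(tapply(rec$date, rec$participant_id, max)[ids]),
             stringsAsFactors = FALSE)
}

#' Write an estimates table
#'
#' Writes effect estimates in the report shape: columns `drug`,
#' `n_cases_exposed`, `n_controls_exposed`, `OR`, `CI_low`, `CI_high`,
#' `p_value`, `estimator`. Odds ratios and interval limits are rounded to two
#' decimals; undefined estimates (zero cells without continuity correction)
#' are rendered as an em dash.
#'
#' @param rows Estimates data.frame as produced by the estimator functions
#'   (columns `drug`, `n_cases_exposed`, `n_controls_exposed`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `estimator`).
#' @param path Output file path.
#' @return Invisibly, the formatted data.frame that was written.
#' @export
write_estimates <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("rows must be a non-empty estimates data.frame")
  fmt <- function(x) ifelse(is.na(x), "—", sprintf("%.2f", x))
  out <- data.frame(drug = rows$drug,
                    n_cases_exposed = rows$n_cases_exposed,
                    n_controls_exposed = rows$n_controls_exposed,
                    OR = fmt(rows$or),
                    CI_low = fmt(rows$ci_low),
                    CI_high = fmt(rows$ci_high),
                    p_value = fmt(rows$p_value),
                    estimator = rows$estimator,
                    stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(out)
}

#' Read back an estimates table written by [write_estimates()]
#'
#' @param path Path to an estimates file.
#' @return Data.frame with the numeric columns restored (`or`, `ci_low`,
#'   `ci_high`, `p_value`; em dashes become `NA`).
#' @export
read_estimates <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "—", NA, x)))
  data.frame(drug = raw$drug,
             n_cases_exposed = as.integer(raw$n_cases_exposed),
             n_controls_exposed = as.integer(raw$n_controls_exposed),
             or = num(raw$OR), ci_low = num(raw$CI_low),
             ci_high = num(raw$CI_high), p_value = num(raw$p_value),
             estimator = raw$estimator, stringsAsFactors = FALSE)
}

#' Write claims records to the delimited claims format
#'
#' Inverse of [read_claims()]: serializes records plus per-participant
#' age/gender into the seven-column claims file.
#'
#' @param records Records data.frame (`participant_id`, `drug`, `date`,
#'   `setting`, `hospital_level`).
#' @param profiles Profiles data.frame supplying `age` and `gender` per
#'   participant.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_claims <- function(records, profiles, path) {
  m <- match(records$participant_id, profiles$participant_id)
  if (anyNA(m)) stop("records contain participants missing from profiles")
  out <- data.frame(participant_id = records$participant_id,
                    age = profiles$age[m],
                    gender = profiles$gender[m],
                    date = from_day_index(records$date),
                    drug = records$drug,
                    setting = records$setting,
                    hospital_level = records$hospital_level,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
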