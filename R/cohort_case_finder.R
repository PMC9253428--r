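#' @title Cohort construction and case ascertainment
#' @description Builds the index-drug user cohort and applies the
#'   marker-drug surrogate case-finding algorithm. A participant is a
#'   suspected-reaction case when their first incident marker prescription
#'   (30 marker-free observed days required before it) falls 1-3 days after
#'   their first index-drug prescription; the expanded (sensitivity)
#'   definition additionally admits same-day markers when the index drug is
#'   not re-prescribed the next day. All other marker timings exclude the
#'   participant from both arms; never-marker members form the control pool.
#' @name cohort_case_finder
NULL

CLASSIFICATIONS <- c("primary", "expanded_same_day", "no_marker",
                     "marker_before_xyp", "same_day_continued",
                     "marker_gt_3_days")

#' Build the index-drug user cohort
#'
#' One cohort member per participant with at least one index-drug
#' prescription; the index date is the earliest such prescription and the
#' propensity covariates (setting, hospital level) are taken from that row,
#' with age/gender and the observation window from the profile.
#'
#' @param records Prescription records (see [read_claims()]).
#' @param profiles Participant profiles.
#' @param vocab A [drug_vocabulary()].
#' @return Data.frame with columns `participant_id`, `index_date`, `age`,
#'   `gender`, `setting`, `hospital_level`, `observation_start`,
#'   `observation_end`.
#' @export
build_cohort <- function(records, profiles, vocab = drug_vocabulary()) {
  xyp <- records[records$drug == vocab$xyp_name, , drop = FALSE]
  if (nrow(xyp) == 0) return(empty_cohort())
  xyp <- xyp[order(xyp$participant_id, xyp$date), , drop = FALSE]
  first <- xyp[!duplicated(xyp$participant_id), , drop = FALSE]
  m <- match(first$participant_id, profiles$participant_id)
  if (anyNA(m))
    stop("index-drug users missing from profiles: ",
         paste(utils::head(first$participant_id[is.na(m)], 5), collapse = ", "))
  out <- data.frame(participant_id = first$participant_id,
                    index_date = first$date,
                    age = profiles$age[m],
                    gender = profiles$gender[m],
                    setting = first$setting,
                    hospital_level = first$hospital_level,
                    observation_start = profiles$observation_start[m],
                    observation_end = profiles$observation_end[m],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_cohort <- function() {
  data.frame(participant_id = character(), index_date = integer(),
             age = numeric(), gender = character(), setting = character(),
             hospital_level = character(), observation_start = integer(),
             observation_end = integer(), stringsAsFactors = FALSE)
}

#' Find a cohort member's incident marker prescription
#'
#' The incident marker is the earliest marker-drug prescription date `m` such
#' that (a) at least `washout_days` observed days precede it
#' (`m - observation_start >= washout_days`) and (b) no marker prescription
#' falls in the `washout_days` days immediately before it. Returns `NA` when
#' no marker prescription qualifies.
#'
#' @param records Prescription records.
#' @param member One cohort row (from [build_cohort()]).
#' @param vocab A [drug_vocabulary()].
#' @param washout_days Washout length in days (default 30, the day-granular
#'   reading of a one-month marker-free run-in).
#' @return A list with `date` (integer day or `NA`) and `drug` (marker name
#'   or `NA`).
#' @export
find_incident_marker <- function(records, member, vocab = drug_vocabulary(),
                                 washout_days = 30L) {
  mk <- records[records$participant_id == member$participant_id &
                  records$drug %in% vocab$marker_drugs, , drop = FALSE]
  if (nrow(mk) == 0) return(list(date = NA_integer_, drug = NA_character_))
  mk <- mk[order(mk$date), , drop = FALSE]
  dates <- unique(mk$date)
  prev_gap <- c(Inf, diff(dates))
  ok <- (dates - member$observation_start >= washout_days) &
    (prev_gap > washout_days)
  if (!any(ok)) return(list(date = NA_integer_, drug = NA_character_))
  d <- dates[which(ok)[1]]
  list(date = d, drug = mk$drug[mk$date == d][1])
}

#' Classify one cohort member
#'
#' Total six-way classification by the offset `d` between the incident marker
#' and the index date: no marker (control-eligible), marker before the index
#' date (excluded), same-day marker with the index drug stopped the next day
#' (expanded-definition case), same-day marker with the index drug continued
#' (excluded), marker 1-3 days after (primary case), marker more than 3 days
#' after (excluded).
#'
#' @param member One cohort row.
#' @param incident_marker Result of [find_incident_marker()].
#' @param records Prescription records (needed for the next-day index-drug
#'   check).
#' @param vocab A [drug_vocabulary()].
#' @return A list with `category` (one of the six classifications),
#'   `marker_date`, `marker_drug`.
#' @export
classify_case <- function(member, incident_marker, records,
                          vocab = drug_vocabulary()) {
  res <- function(cat) list(category = cat,
                            marker_date = incident_marker$date,
                            marker_drug = incident_marker$drug)
  if (is.na(incident_marker$date)) return(res("no_marker"))
  d <- incident_marker$date - member$index_date
  if (d < 0) return(res("marker_before_xyp"))
  if (d == 0) {
    next_day_xyp <- any(records$participant_id == member$participant_id &
                          records$drug == vocab$xyp_name &
                          records$date == member$index_date + 1L)
    return(res(if (next_day_xyp) "same_day_continued" else "expanded_same_day"))
  }
  if (d <= 3) return(res("primary"))
  res("marker_gt_3_days")
}

#' Classify every cohort member
#'
#' Vectorized application of [find_incident_marker()] and [classify_case()]
#' across the cohort.
#'
#' @inheritParams find_incident_marker
#' @param cohort Cohort data.frame from [build_cohort()].
#' @return Data.frame with columns `participant_id`, `index_date`,
#'   `category`, `marker_date`, `marker_drug`.
#' @export
classify_cohort <- function(records, cohort, vocab = drug_vocabulary(),
                            washout_days = 30L) {
  n <- nrow(cohort)
  marker_date <- rep(NA_integer_, n)
  marker_drug <- rep(NA_character_, n)
  category <- rep("no_marker", n)
  if (n == 0)
    return(data.frame(participant_id = character(), index_date = integer(),
                      category = character(), marker_date = integer(),
                      marker_drug = character(), stringsAsFactors = FALSE))

  mk <- records[records$drug %in% vocab$marker_drugs &
                  records$participant_id %in% cohort$participant_id, ,
                drop = FALSE]
  mk <- mk[order(mk$participant_id, mk$date), , drop = FALSE]
  obs_start <- cohort$observation_start[match(mk$participant_id,
                                              cohort$participant_id)]
  keep <- !duplicated(paste(mk$participant_id, mk$date))  # unique dates
  mk <- mk[keep, , drop = FALSE]; obs_start <- obs_start[keep]
  new_pid <- !duplicated(mk$participant_id)
  prev_gap <- c(Inf, diff(mk$date))
  prev_gap[new_pid] <- Inf
  ok <- (mk$date - obs_start >= washout_days) & (prev_gap > washout_days)
  okm <- mk[ok, , drop = FALSE]
  inc <- okm[!duplicated(okm$participant_id), , drop = FALSE]
  hit <- match(cohort$participant_id, inc$participant_id)
  marker_date <- inc$date[hit]
  marker_drug <- inc$drug[hit]

  d <- marker_date - cohort$index_date
  # same-day members: does the index drug recur on index_date + 1?
  xyp <- records[records$drug == vocab$xyp_name, , drop = FALSE]
  next_day <- !is.na(match(paste(cohort$participant_id, cohort$index_date + 1L),
                           paste(xyp$participant_id, xyp$date)))
  category <- ifelse(is.na(d), "no_marker",
              ifelse(d < 0, "marker_before_xyp",
              ifelse(d == 0 & !next_day, "expanded_same_day",
              ifelse(d == 0, "same_day_continued",
              ifelse(d <= 3, "primary", "marker_gt_3_days")))))
  data.frame(participant_id = cohort$participant_id,
             index_date = cohort$index_date,
             category = category,
             marker_date = marker_date,
             marker_drug = marker_drug,
             stringsAsFactors = FALSE)
}

#' Select the analysis case set and control pool
#'
#' Primary mode keeps only primary-definition cases; sensitivity mode expands
#' the case set with the same-day-stopped cases. The control pool is the
#' never-marker cohort members; members excluded for timing reasons appear in
#' neither set.
#'
#' @param cohort Cohort data.frame.
#' @param classifications Output of [classify_cohort()].
#' @param mode `"primary"` or `"sensitivity"`.
#' @return A list with `cases` (data.frame: `participant_id`, `index_date`,
#'   `first_marker_date`, `marker_drug`, `definition`) and `control_pool`
#'   (cohort rows).
#' @export
select_analysis_sets <- function(cohort, classifications,
                                 mode = c("primary", "sensitivity")) {
  mode <- match.arg(mode)
  wanted <- if (mode == "primary") "primary"
            else c("primary", "expanded_same_day")
  cl <- classifications
  case_rows <- cl[cl$category %in% wanted, , drop = FALSE]
  if (nrow(case_rows) == 0)
    stop("case ascertainment produced no cases in mode '", mode,
         "'; pipeline halted")
  cases <- data.frame(participant_id = case_rows$participant_id,
                      index_date = case_rows$index_date,
                      first_marker_date = case_rows$marker_date,
                      marker_drug = case_rows$marker_drug,
                      definition = case_rows$category,
                      stringsAsFactors = FALSE)
  pool_ids <- cl$participant_id[cl$category == "no_marker"]
  control_pool <- cohort[cohort$participant_id %in% pool_ids, , drop = FALSE]
  rownames(cases) <- rownames(control_pool) <- NULL
  list(cases = cases, control_pool = control_pool)
}
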