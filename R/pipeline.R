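#' @title Pipeline orchestration, run manifest and attrition flowchart
#' @description One reproducible run: simulate (or read) claims, ascertain
#'   cases, match controls by propensity score, code exposures, estimate all
#'   effects, and write result tables plus a machine-readable manifest and a
#'   human-readable attrition flowchart. Identical config and seed give
#'   identical outputs.
#' @name cli_report
NULL

#' Construct a run manifest
#'
#' The manifest carries the attrition counts of the selection flowchart:
#' cohort size, never-marker members, marker users without an incident
#' marker, incident cases, timing exclusions (before / same-day-continued /
#' late), final cases and matched pairs. Counts must be monotone
#' non-increasing along the path cohort -> incident -> final cases -> pairs.
#'
#' @param counts Named list/vector with `cohort`, `no_marker`,
#'   `non_incident_marker`, `incident_cases`, `excluded_timing`,
#'   `final_cases`, `matched_pairs` (missing entries default to 0, except the
#'   required `cohort`, `incident_cases`, `final_cases`).
#' @param seed Seed(s) used.
#' @param config_hash Hash of the run configuration.
#' @param mode Analysis mode.
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(counts, seed = NA_integer_, config_hash = "",
                         mode = "primary") {
  counts <- as.list(counts)
  for (k in c("no_marker", "non_incident_marker", "excluded_timing",
              "matched_pairs"))
    if (is.null(counts[[k]])) counts[[k]] <- 0L
  need <- c("cohort", "incident_cases", "final_cases")
  if (!all(need %in% names(counts)))
    stop("manifest counts need: ", paste(need, collapse = ", "))
  with(counts, {
    if (!(cohort >= incident_cases && incident_cases >= final_cases &&
            final_cases >= matched_pairs))
      stop("attrition counts must be monotone non-increasing along the ",
           "selection path")
  })
  structure(list(counts = lapply(counts, as.integer), seed = seed,
                 config_hash = config_hash, mode = mode,
                 version = as.character(utils::packageVersion("nccclaims")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

pct1 <- function(n, base) {
  if (base <= 0) return("0.0")
  sprintf("%.1f", 100 * n / base)
}

#' Render the attrition flowchart as text
#'
#' Indented text mirroring the patient-selection flowchart: each inclusion or
#' exclusion with its count and percentage of the stated base (exclusions as
#' a percentage of the cohort; final cases as a percentage of incident
#' cases - the flowchart's mixed-base convention, annotated per line).
#'
#' @param manifest A [run_manifest()].
#' @return Character scalar (multi-line).
#' @export
render_flowchart <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  ct <- manifest$counts
  lines <- c(
    sprintf("Study cohort (index-drug users): %d", ct$cohort),
    sprintf("  Excluded, no anti-allergic marker prescription: %d (%s%% of cohort)",
            ct$no_marker, pct1(ct$no_marker, ct$cohort)),
    sprintf("  Excluded, marker user without incident (washout-passing) marker: %d (%s%% of cohort)",
            ct$non_incident_marker, pct1(ct$non_incident_marker, ct$cohort)),
    sprintf("  Incident cases (washout-passing first marker): %d (%s%% of cohort)",
            ct$incident_cases, pct1(ct$incident_cases, ct$cohort)),
    sprintf("    Excluded, marker before / same-day-continued / >3 days after index: %d (%s%% of cohort)",
            ct$excluded_timing, pct1(ct$excluded_timing, ct$cohort)),
    sprintf("    Final cases: %d (%s%% of incident cases)",
            ct$final_cases, pct1(ct$final_cases, ct$incident_cases)),
    sprintf("      Matched pairs: %d (%s%% of final cases)",
            ct$matched_pairs, pct1(ct$matched_pairs, ct$final_cases)))
  paste(lines, collapse = "\n")
}

config_digest <- function(config) {
  config$outdir <- NULL  # output location never changes the analysis
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config[order(names(config))], f)
  unname(tools::md5sum(f))
}

#' Read a pipeline run configuration
#'
#' YAML keys: either `scenario` (a [scenario_config()] parameter list) or
#' `input` (path to a claims file); plus optional `mode`
#' (primary|sensitivity), `washout_days`, `seed`, `alpha`, `univariate`
#' (crude|discordant|both), `zero_cell` (dash|haldane), `outdir`.
#'
#' @param path YAML file path.
#' @return Named list of run settings with defaults filled in.
#' @export
read_run_config <- function(path) {
  fill_run_defaults(yaml::read_yaml(path))
}

fill_run_defaults <- function(cfg) {
  defaults <- list(mode = "primary", washout_days = 30L, seed = 1L,
                   alpha = 0.05, univariate = "both", zero_cell = "dash",
                   outdir = "results")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$scenario) && is.null(cfg$input))
    stop("config must name either a simulation `scenario` or an `input` claims file")
  cfg
}

#' Run the whole pipeline
#'
#' Executes simulate (or read) -> cohort -> case ascertainment -> propensity
#' matching -> exposure coding -> estimation, writing `univariate.csv`,
#' `multivariable.csv`, `counts.csv`, `subgroups.csv`, `pairs.csv`,
#' `cases.csv`, `balance.csv`, `manifest.json` and `flowchart.txt` to the
#' output directory.
#'
#' @param config A config list (see [read_run_config()]) or a YAML path.
#' @return Invisibly, a list with the manifest and all in-memory results.
#' @export
run_pipeline <- function(config) {
  config <- if (is.character(config)) read_run_config(config)
            else fill_run_defaults(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vocab <- drug_vocabulary()
  haldane <- identical(config$zero_cell, "haldane")

  if (!is.null(config$scenario)) {
    sc <- config$scenario
    if (is.null(sc$seed)) sc$seed <- config$seed
    scfg <- do.call(scenario_config, sc)
    sim <- generate_cohort(scfg, vocab)
    records <- sim$records; profiles <- sim$profiles
  } else {
    claims <- read_claims(config$input, vocab)
    records <- claims$records; profiles <- claims$profiles
  }

  cohort <- build_cohort(records, profiles, vocab)
  cls <- classify_cohort(records, cohort, vocab,
                         washout_days = config$washout_days)
  sets <- select_analysis_sets(cohort, cls, mode = config$mode)
  cases <- sets$cases; pool <- sets$control_pool

  case_cov <- cohort[match(cases$participant_id, cohort$participant_id), ,
                     drop = FALSE]
  model <- fit_propensity(case_cov, pool)
  pairs <- greedy_match(case_cov, pool, model, seed = config$seed)
  exposures <- code_exposures(pairs, records, vocab, cases)

  uni <- univariate_estimates(exposures, which = config$univariate,
                              haldane = haldane)
  multi <- backward_select(exposures, alpha = config$alpha)
  counts <- concomitant_count_analysis(exposures, haldane = haldane)
  sub_age <- subgroup_analysis(exposures, profiles, "age_band",
                               alpha = config$alpha)
  sub_gender <- subgroup_analysis(exposures, profiles, "gender",
                                  alpha = config$alpha)
  balance <- balance_table(pairs, case_cov, pool)

  # attrition accounting: the cohort partitions exactly into selected cases,
  # never-marker pool and every exclusion bucket
  tab <- table(factor(cls$category, levels = CLASSIFICATIONS))
  marker_users <- length(unique(
    records$participant_id[records$drug %in% vocab$marker_drugs &
                             records$participant_id %in%
                             cohort$participant_id]))
  incident <- sum(tab[c("primary", "expanded_same_day", "marker_before_xyp",
                        "same_day_continued", "marker_gt_3_days")])
  selected <- if (config$mode == "primary") tab[["primary"]]
              else tab[["primary"]] + tab[["expanded_same_day"]]
  stopifnot(nrow(cohort) == selected + (incident - selected) +
              tab[["no_marker"]])
  manifest <- run_manifest(
    counts = list(cohort = nrow(cohort),
                  no_marker = nrow(cohort) - marker_users,
                  non_incident_marker = marker_users - incident,
                  incident_cases = incident,
                  excluded_timing = incident - selected,
                  final_cases = selected,
                  matched_pairs = nrow(pairs)),
    seed = config$seed, config_hash = config_digest(config),
    mode = config$mode)

  write_estimates(rbind(uni, counts$estimate), file.path(outdir, "univariate.csv"))
  if (nrow(multi)) write_estimates(multi, file.path(outdir, "multivariable.csv"))
  utils::write.csv(counts$distribution, file.path(outdir, "counts.csv"),
                   row.names = FALSE)
  sub_rows <- list()
  for (g in names(sub_age)) if (!is.null(sub_age[[g]]$univariate))
    sub_rows[[paste0("age:", g)]] <-
      cbind(subgroup = paste0("age:", g), sub_age[[g]]$univariate)
  for (g in names(sub_gender)) if (!is.null(sub_gender[[g]]$univariate))
    sub_rows[[paste0("gender:", g)]] <-
      cbind(subgroup = paste0("gender:", g), sub_gender[[g]]$univariate)
  if (length(sub_rows))
    utils::write.csv(do.call(rbind, sub_rows),
                     file.path(outdir, "subgroups.csv"), row.names = FALSE)
  utils::write.csv(pairs, file.path(outdir, "pairs.csv"), row.names = FALSE)
  out_cases <- cases
  out_cases$index_date <- from_day_index(out_cases$index_date)
  out_cases$first_marker_date <- from_day_index(out_cases$first_marker_date)
  utils::write.csv(out_cases, file.path(outdir, "cases.csv"),
                   row.names = FALSE)
  utils::write.csv(balance, file.path(outdir, "balance.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(manifest[c("counts", "seed", "config_hash", "mode",
                                  "version")],
                       file.path(outdir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(render_flowchart(manifest), file.path(outdir, "flowchart.txt"))

  invisible(list(manifest = manifest, cohort = cohort,
                 classifications = cls, cases = cases, pairs = pairs,
                 exposures = exposures, univariate = uni,
                 multivariable = multi, counts = counts, balance = balance,
                 subgroups = list(age_band = sub_age, gender = sub_gender)))
}
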