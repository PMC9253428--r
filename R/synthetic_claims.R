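#' @title Synthetic claims generator
#' @description Seeded generator of per-participant prescription streams with
#'   known ground truth. Each participant receives the index drug once; target
#'   concomitants are co-prescribed the same day with covariate-dependent
#'   probability; an allergic reaction is drawn from a logistic model in the
#'   true exposure effects and, when present, triggers a marker-drug
#'   prescription 0-3 days after the index date; background (non-allergy)
#'   marker prescriptions are sprinkled across the whole observation window so
#'   all timing exclusions are exercised.
#' @name synthetic_claims
NULL

#' Scenario configuration for the synthetic generator
#'
#' @param n_participants Number of participants (>= 2).
#' @param seed Integer seed; all randomness flows from it.
#' @param baseline_allergy_logodds Log-odds of an allergic reaction for a
#'   participant with no target exposures. Default `qlogis(0.10)`: a 10%
#'   baseline reaction-signal rate, a deliberate calibration choice giving
#'   case counts comparable in proportion to marker-positive rates seen in
#'   claims cohorts.
#' @param true_log_or Named numeric vector of true log odds ratios for any
#'   subset of the target concomitants (unnamed drugs have effect 0).
#' @param coprescription_prevalence Named numeric vector of same-day
#'   co-prescription probabilities per target drug. The default covers all 25
#'   panel drugs with prevalences from about 0.3 (common mucolytics and
#'   vitamins) down to below 0.01 (carbapenems), mirroring the qualitative
#'   frequency ordering seen in claims data.
#' @param covariate_effects_on_coprescription Named numeric vector of log-odds
#'   effects of baseline covariates on every drug's co-prescription; allowed
#'   names: `age10` (per decade of age, centered at 30y), `male`, `inpatient`,
#'   `secondary`, `primary_healthcare`. Nonzero values induce confounding
#'   through covariates also used in the propensity model. Default: no
#'   confounding.
#' @param background_marker_rate Per-day probability of a non-allergy marker
#'   prescription (default 0.001/day).
#' @param same_day_marker_fraction Optional override for the probability that
#'   an allergic reaction's marker is prescribed on the index day itself; if
#'   `NULL` (default) the mass at offset 0 of `marker_delay_distribution` is
#'   used as-is, otherwise offsets 1-3 are rescaled around the override.
#' @param marker_delay_distribution Probabilities over day offsets 0:3 for the
#'   allergy marker prescription. Default `c(0.35, 0.35, 0.20, 0.10)`:
#'   reactions mostly within 24 h of administration.
#' @param xyp_continuation_probability Probability that the index drug is
#'   re-prescribed the day after a same-day marker (default 0.5); such
#'   participants are excluded by the case-finding rules in both analyses.
#' @param observation_days Length of the follow-up window in days
#'   (default 365, one calendar year).
#' @param age_mixture_weights Weights of the child (<18y), adult (18-64y) and
#'   elderly (>=65y) age components (default `c(0.42, 0.38, 0.20)`, the
#'   pediatric-heavy mix typical of this drug's users).
#' @return An object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(n_participants,
                            seed,
                            baseline_allergy_logodds = stats::qlogis(0.10),
                            true_log_or = numeric(),
                            coprescription_prevalence = default_prevalence(),
                            covariate_effects_on_coprescription = numeric(),
                            background_marker_rate = 0.001,
                            same_day_marker_fraction = NULL,
                            marker_delay_distribution = c(0.35, 0.35, 0.20, 0.10),
                            xyp_continuation_probability = 0.5,
                            observation_days = 365L,
                            age_mixture_weights = c(0.42, 0.38, 0.20)) {
  cfg <- list(n_participants = as.integer(n_participants),
              seed = as.integer(seed),
              baseline_allergy_logodds = baseline_allergy_logodds,
              true_log_or = unlist(true_log_or),
              coprescription_prevalence = unlist(coprescription_prevalence),
              covariate_effects_on_coprescription =
                unlist(covariate_effects_on_coprescription),
              background_marker_rate = background_marker_rate,
              same_day_marker_fraction = same_day_marker_fraction,
              marker_delay_distribution = marker_delay_distribution,
              xyp_continuation_probability = xyp_continuation_probability,
              observation_days = as.integer(observation_days),
              age_mixture_weights = age_mixture_weights)
  validate_scenario(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario <- function(cfg) {
  if (is.na(cfg$n_participants) || cfg$n_participants < 2)
    stop("n_participants must be >= 2")
  if (length(cfg$marker_delay_distribution) != 4 ||
      abs(sum(cfg$marker_delay_distribution) - 1) > 1e-8 ||
      any(cfg$marker_delay_distribution < 0))
    stop("marker_delay_distribution must be 4 probabilities over offsets 0:3 summing to 1")
  probs <- c(cfg$coprescription_prevalence, cfg$background_marker_rate,
             cfg$xyp_continuation_probability, cfg$same_day_marker_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (cfg$observation_days < 60)
    stop("observation_days must allow a washout runway (>= 60)")
  bad_cov <- setdiff(names(cfg$covariate_effects_on_coprescription),
                     c("age10", "male", "inpatient", "secondary",
                       "primary_healthcare"))
  if (length(bad_cov)) stop("unknown covariate effect name(s): ",
                            paste(bad_cov, collapse = ", "))
  invisible(cfg)
}

#' Default co-prescription prevalences for the 25-drug panel
#'
#' @return Named numeric vector of same-day co-prescription probabilities.
#' @export
default_prevalence <- function() {
  c("ambroxol" = 0.255, "vitamin c" = 0.214, "potassium chloride" = 0.168,
    "vitamin b6" = 0.124, "ribavirin" = 0.111, "penicillin" = 0.090,
    "levofloxacin" = 0.079, "azithromycin" = 0.079, "bromhexine" = 0.078,
    "pantoprazole" = 0.071, "heparin" = 0.067, "cefuroxime" = 0.058,
    "sodium bicarbonate" = 0.055, "cefathiamidine" = 0.055,
    "lidocaine" = 0.040, "aminophylline" = 0.035, "cefazolin" = 0.034,
    "amoxicillin-clavulanate" = 0.025, "ceftazidime" = 0.024,
    "gentamicin" = 0.021, "ceftriaxone" = 0.018, "moxifloxacin" = 0.014,
    "cefoperazone-sulbactam" = 0.005, "amikacin" = 0.005,
    "meropenem" = 0.003)
}

resolved_delay_distribution <- function(cfg) {
  p <- cfg$marker_delay_distribution
  if (!is.null(cfg$same_day_marker_fraction)) {
    f <- cfg$same_day_marker_fraction
    rest <- p[2:4]
    rest <- if (sum(rest) > 0) rest / sum(rest) else c(1, 0, 0) / 1
    p <- c(f, (1 - f) * rest)
  }
  p
}

#' Generate a synthetic claims cohort
#'
#' Draws, for each participant, baseline covariates (three-component age
#' mixture populating the child/adult/elderly bands, gender, visit setting,
#' hospital level), an index-drug date inside the observation window, same-day
#' target co-prescriptions from a logistic model with configurable covariate
#' effects, allergy status from a logistic model in the true exposure
#' effects, an allergy marker prescription at an offset of 0-3 days, and
#' background marker prescriptions across the window (including before the
#' index date and more than 3 days after, so every exclusion rule fires).
#' For same-day allergy markers the index drug is re-prescribed on the next
#' day with the configured continuation probability.
#'
#' @param config A [scenario_config()].
#' @param vocabulary A [drug_vocabulary()].
#' @return A list with `records`, `profiles` (as from [read_claims()]) and
#'   `truth`, a data.frame with each participant's true allergy status, true
#'   exposure indicators (`exp_*` columns) and marker offset (`NA` when not
#'   allergic).
#' @export
generate_cohort <- function(config, vocabulary = drug_vocabulary()) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario(config)
  n <- config$n_participants
  rng <- new_rng(config$seed)
  ids <- sprintf("P%06d", seq_len(n))

  # --- baseline covariates -------------------------------------------------
  comp <- rng$sample(1:3, n, replace = TRUE, prob = config$age_mixture_weights)
  age <- numeric(n)
  age[comp == 1] <- rng$runif(sum(comp == 1), 0, 18)
  age[comp == 2] <- rng$runif(sum(comp == 2), 18, 65)
  age[comp == 3] <- rng$runif(sum(comp == 3), 65, 90)
  age <- round(age, 1)
  gender <- ifelse(rng$runif(n) < 0.53, "male", "female")
  setting <- ifelse(rng$runif(n) < 0.76, "inpatient", "outpatient")
  hospital <- rng$sample(HOSPITAL_LEVELS, n, replace = TRUE,
                         prob = c(0.26, 0.52, 0.22))
  xyp_day <- rng$sample(40:(config$observation_days - 10), n, replace = TRUE)

  # --- same-day co-prescriptions ------------------------------------------
  drugs <- vocabulary$target_concomitants
  prev <- config$coprescription_prevalence
  prev <- prev[names(prev) %in% drugs]
  eff <- config$covariate_effects_on_coprescription
  lin <- rep(0, n)
  if (length(eff)) {
    covs <- cbind(age10 = (age - 30) / 10, male = as.numeric(gender == "male"),
                  inpatient = as.numeric(setting == "inpatient"),
                  secondary = as.numeric(hospital == "secondary"),
                  primary_healthcare = as.numeric(hospital == "primary_healthcare"))
    lin <- as.vector(covs[, names(eff), drop = FALSE] %*% eff)
  }
  expo <- matrix(0L, n, length(prev), dimnames = list(NULL, names(prev)))
  for (d in names(prev)) {
    p <- stats::plogis(stats::qlogis(prev[[d]]) + lin)
    expo[, d] <- as.integer(rng$runif(n) < p)
  }

  # --- allergy outcome and marker prescriptions ---------------------------
  beta <- config$true_log_or
  beta <- beta[names(beta) %in% colnames(expo)]
  eta <- rep(config$baseline_allergy_logodds, n)
  if (length(beta))
    eta <- eta + as.vector(expo[, names(beta), drop = FALSE] %*% beta)
  allergic <- rng$runif(n) < stats::plogis(eta)
  delay_p <- resolved_delay_distribution(config)
  offset <- rep(NA_integer_, n)
  offset[allergic] <- rng$sample(0:3, sum(allergic), replace = TRUE,
                                 prob = delay_p)
  marker_drug <- rep(NA_character_, n)
  marker_drug[allergic] <- rng$sample(vocabulary$marker_drugs, sum(allergic),
                                      replace = TRUE)
  continue <- rng$runif(n) < config$xyp_continuation_probability

  # --- background marker prescriptions ------------------------------------
  bg_n <- rng$rbinom(n, config$observation_days, config$background_marker_rate)
  bg_pid <- rep(ids, bg_n)
  bg_total <- sum(bg_n)
  bg_day <- if (bg_total) rng$sample(0:(config$observation_days - 1),
                                     bg_total, replace = TRUE) else integer()
  bg_drug <- if (bg_total) rng$sample(vocabulary$marker_drugs, bg_total,
                                      replace = TRUE) else character()

  # --- assemble records ----------------------------------------------------
  idx <- function(pid) match(pid, ids)
  rows <- list(
    data.frame(participant_id = ids, drug = vocabulary$xyp_name,
               date = xyp_day, stringsAsFactors = FALSE))
  for (d in colnames(expo)) {
    on <- expo[, d] == 1L
    if (any(on))
      rows[[length(rows) + 1L]] <-
        data.frame(participant_id = ids[on], drug = d, date = xyp_day[on],
                   stringsAsFactors = FALSE)
  }
  al <- which(allergic)
  if (length(al))
    rows[[length(rows) + 1L]] <-
      data.frame(participant_id = ids[al], drug = marker_drug[al],
                 date = xyp_day[al] + offset[al], stringsAsFactors = FALSE)
  cont <- which(allergic & offset == 0L & continue)
  if (length(cont))
    rows[[length(rows) + 1L]] <-
      data.frame(participant_id = ids[cont], drug = vocabulary$xyp_name,
                 date = xyp_day[cont] + 1L, stringsAsFactors = FALSE)
  if (bg_total)
    rows[[length(rows) + 1L]] <-
      data.frame(participant_id = bg_pid, drug = bg_drug, date = bg_day,
                 stringsAsFactors = FALSE)
  records <- do.call(rbind, rows)
  pi <- idx(records$participant_id)
  records$setting <- setting[pi]
  records$hospital_level <- hospital[pi]
  records <- records[order(records$participant_id, records$date,
                           records$drug), ]
  rownames(records) <- NULL

  profiles <- data.frame(participant_id = ids, age = age, gender = gender,
                         first_xyp_setting = setting,
                         first_xyp_hospital_level = hospital,
                         observation_start = 0L,
                         observation_end = config$observation_days - 1L,
                         stringsAsFactors = FALSE)

  truth <- data.frame(participant_id = ids, allergic = allergic,
                      xyp_day = xyp_day, marker_offset = offset,
                      stringsAsFactors = FALSE)
  for (d in colnames(expo)) truth[[paste0("exp_", drug_key(d))]] <- expo[, d]

  list(records = records, profiles = profiles, truth = truth)
}

#' Simulate exposure data for 1:1 matched pairs
#'
#' Generates matched-pair exposure indicators directly under the conditional
#' logistic model: the two members of each pair draw exposure vectors
#' independently from the per-drug prevalences, and one member is labelled
#' the case with probability `exp(beta'x1) / (exp(beta'x1) + exp(beta'x2))` -
#' exactly the 1:1 conditional likelihood, so the planted log odds ratios are
#' the true estimands. Used for estimator parameter-recovery checks where the
#' full cohort machinery is not under test.
#'
#' @param n_pairs Number of matched pairs.
#' @param log_or Named numeric vector of true log odds ratios per drug.
#' @param prevalence Named numeric vector of exposure prevalences (same drugs).
#' @param seed Integer seed.
#' @return An exposure matrix data.frame as produced by [code_exposures()]:
#'   columns `pair_id`, `participant_id`, `arm`, one indicator per drug
#'   (key-named), and `n_exposures`.
#' @export
simulate_matched_pairs <- function(n_pairs, log_or, prevalence, seed) {
  stopifnot(length(log_or) == length(prevalence),
            all(names(log_or) %in% names(prevalence)))
  prevalence <- prevalence[names(log_or)]
  rng <- new_rng(seed)
  k <- length(log_or)
  draw <- function() {
    m <- matrix(0L, n_pairs, k, dimnames = list(NULL, names(log_or)))
    for (j in seq_len(k))
      m[, j] <- as.integer(rng$runif(n_pairs) < prevalence[[j]])
    m
  }
  x1 <- draw(); x2 <- draw()
  s1 <- exp(as.vector(x1 %*% log_or)); s2 <- exp(as.vector(x2 %*% log_or))
  one_is_case <- rng$runif(n_pairs) < s1 / (s1 + s2)
  xcase <- ifelse(matrix(one_is_case, n_pairs, k), x1, x2)
  xctrl <- ifelse(matrix(one_is_case, n_pairs, k), x2, x1)
  colnames(xcase) <- colnames(xctrl) <- drug_key(names(log_or))
  build <- function(x, arm, tag) {
    df <- data.frame(pair_id = seq_len(n_pairs),
                     participant_id = sprintf("%s%05d", tag, seq_len(n_pairs)),
                     arm = arm, stringsAsFactors = FALSE)
    for (j in colnames(x)) df[[j]] <- as.integer(x[, j])
    df$n_exposures <- as.integer(rowSums(x))
    df
  }
  out <- rbind(build(xcase, "case", "C"), build(xctrl, "control", "K"))
  out <- out[order(out$pair_id, out$arm), ]
  rownames(out) <- NULL
  attr(out, "drugs") <- names(log_or)
  out
}

#' Hand-constructed worked fixture
#'
#' A twelve-participant cohort covering every branch of the case-finding
#' algorithm: a primary case with the marker one day after the index drug, a
#' boundary primary case at +3 days, a late-marker exclusion at +4 days, a
#' marker-before-index exclusion, a same-day case whose index drug stops the
#' next day (admitted only under the expanded definition), a same-day
#' participant who continues the index drug (excluded in both analyses), a
#' washout-violating marker user, a marker user whose incident marker falls
#' long after the index date, a participant whose second marker is blocked by
#' the washout, and never-marker controls carrying target exposures.
#'
#' @param vocabulary A [drug_vocabulary()].
#' @return A list with `records` and `profiles`, dated within calendar 2015
#'   (observation window 2015-01-01 to 2015-12-31).
#' @export
make_worked_fixture <- function(vocabulary = drug_vocabulary()) {
  base <- to_day_index("2015-01-01")
  xyp <- vocabulary$xyp_name
  rows <- list()
  add <- function(id, drug, day, setting = "inpatient",
                  hospital = "secondary") {
    rows[[length(rows) + 1L]] <<- data.frame(
      participant_id = id, drug = drug, date = base + day,
      setting = setting, hospital_level = hospital, stringsAsFactors = FALSE)
  }
  # P01: primary case, marker at +1
  add("P01", xyp, 100); add("P01", "gentamicin", 100)
  add("P01", "promethazine", 101)
  # P02: boundary primary case, marker at +3
  add("P02", xyp, 100, "outpatient", "tertiary")
  add("P02", "ribavirin", 100, "outpatient", "tertiary")
  add("P02", "dexamethasone", 103, "outpatient", "tertiary")
  # P03: excluded, marker at +4
  add("P03", xyp, 100); add("P03", "adrenaline", 104)
  # P04: excluded, marker before the index date
  add("P04", "calcium gluconate", 80); add("P04", xyp, 100)
  # P05: same-day marker, index drug stopped next day -> expanded case
  add("P05", xyp, 100, "inpatient", "primary_healthcare")
  add("P05", "lidocaine", 100, "inpatient", "primary_healthcare")
  add("P05", "dexamethasone", 100, "inpatient", "primary_healthcare")
  # P06: same-day marker, index drug continued next day -> excluded
  add("P06", xyp, 100); add("P06", "promethazine", 100); add("P06", xyp, 101)
  # P07: washout violation - marker at day 10 has no 30-day runway
  add("P07", xyp, 100); add("P07", "dexamethasone", 10)
  # P08: never-marker control with a target exposure
  add("P08", xyp, 100); add("P08", "gentamicin", 100)
  # P09: never-marker control, outpatient
  add("P09", xyp, 120, "outpatient", "tertiary")
  add("P09", "vitamin c", 120, "outpatient", "tertiary")
  # P10: never-marker control, no exposures
  add("P10", xyp, 150)
  # P11: two markers; the first (day 40) is incident but precedes the index
  #      date; the second (day 60) is blocked by the washout
  add("P11", "promethazine", 40); add("P11", "promethazine", 60)
  add("P11", xyp, 200)
  # P12: incident marker far (+150 days) after the index date -> excluded
  add("P12", xyp, 100); add("P12", "ambroxol", 100)
  add("P12", "adrenaline", 250)
  records <- do.call(rbind, rows)
  profiles <- data.frame(
    participant_id = sprintf("P%02d", 1:12),
    age = c(5, 34, 70, 45, 8, 28, 61, 12, 36, 79, 3, 50),
    gender = c("male", "female", "male", "female", "male", "male",
               "female", "male", "female", "male", "female", "male"),
    first_xyp_setting = c("inpatient", "outpatient", "inpatient", "inpatient",
                          "inpatient", "inpatient", "inpatient", "inpatient",
                          "outpatient", "inpatient", "inpatient", "inpatient"),
    first_xyp_hospital_level = c("secondary", "tertiary", "secondary",
                                 "secondary", "primary_healthcare",
                                 "secondary", "secondary", "secondary",
                                 "tertiary", "secondary", "secondary",
                                 "secondary"),
    observation_start = base,
    observation_end = base + 364L,
    stringsAsFactors = FALSE)
  list(records = records, profiles = profiles)
}

# Self-contained RNG stream: all draws come from one L'Ecuyer-CMRG stream so
# generation never touches (or depends on) the global random state.
new_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  local_do <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) {
      suppressWarnings(set.seed(seed, kind = "Mersenne-Twister"))
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    f(...)
  }
  list(
    runif = function(n, min = 0, max = 1) local_do(stats::runif, n, min, max),
    rbinom = function(n, size, prob) local_do(stats::rbinom, n, size, prob),
    sample = function(x, size, replace = FALSE, prob = NULL)
      local_do(sample, x, size, replace, prob)
  )
}
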