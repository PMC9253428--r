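# Shared fixtures and small oracles used across test files.

# Published univariate exposure counts (cases / controls of 949 each) for the
# drugs whose printed odds ratio equals the crude cross-product computation.
table3_counts <- function() {
  data.frame(
    drug = c("ambroxol", "cefathiamidine", "penicillin", "vitamin b6",
             "bromhexine", "amoxicillin-clavulanate", "cefazolin",
             "azithromycin", "cefuroxime"),
    cases = c(274L, 18L, 77L, 114L, 65L, 43L, 44L, 86L, 60L),
    controls = c(242L, 52L, 85L, 118L, 74L, 24L, 32L, 75L, 55L),
    stringsAsFactors = FALSE)
}

# Write a minimal claims CSV from parallel vectors.
write_tiny_claims <- function(path, id, age, gender, date, drug, setting,
                              hospital) {
  df <- data.frame(participant_id = id, age = age, gender = gender,
                   date = date, drug = drug, setting = setting,
                   hospital_level = hospital, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Lean single-replicate run of the matched pipeline on a null scenario;
# returns the 25 crude univariate p-values.
null_replicate_pvalues <- function(seed, n_participants = 2600) {
  v <- drug_vocabulary()
  prev <- stats::setNames(rep(c(0.12, 0.15, 0.20, 0.25, 0.30), 5),
                          default_concomitants())
  sc <- scenario_config(n_participants = n_participants, seed = seed,
                        baseline_allergy_logodds = stats::qlogis(0.15),
                        coprescription_prevalence = prev)
  sim <- generate_cohort(sc, v)
  coh <- build_cohort(sim$records, sim$profiles, v)
  cls <- classify_cohort(sim$records, coh, v)
  sets <- select_analysis_sets(coh, cls, "primary")
  cc <- coh[match(sets$cases$participant_id, coh$participant_id), ]
  mod <- fit_propensity(cc, sets$control_pool)
  pairs <- greedy_match(cc, sets$control_pool, mod)
  ex <- code_exposures(pairs, sim$records, v, sets$cases)
  univariate_estimates(ex, which = "crude")$p_value
}

# Independent conditional log likelihood used by optimizer/grid oracles.
oracle_cloglik <- function(beta, z) sum(stats::plogis(z %*% beta, log.p = TRUE))
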