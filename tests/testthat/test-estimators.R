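pair_fixture <- function(case_rows, control_rows, drugs) {
  # build a tiny exposure matrix by hand; rows are 0/1 vectors per drug
  n <- length(case_rows)
  build <- function(rows, arm, tag) {
    df <- data.frame(pair_id = seq_len(n),
                     participant_id = sprintf("%s%03d", tag, seq_len(n)),
                     arm = arm, stringsAsFactors = FALSE)
    m <- do.call(rbind, rows)
    colnames(m) <- drug_key(drugs)
    for (j in colnames(m)) df[[j]] <- m[, j]
    df$n_exposures <- as.integer(rowSums(m))
    df
  }
  out <- rbind(build(case_rows, "case", "C"), build(control_rows, "control", "K"))
  attr(out, "drugs") <- drugs
  out
}

test_that("exposures are coded by the same-date rule with markers excluded", {
  v <- drug_vocabulary()
  records <- rbind(
    data.frame(participant_id = "C1", drug = c("xiyanping", "gentamicin",
                                               "promethazine"),
               date = c(100L, 100L, 101L), setting = "inpatient",
               hospital_level = "secondary", stringsAsFactors = FALSE),
    data.frame(participant_id = "K1", drug = c("xiyanping", "gentamicin"),
               date = c(50L, 51L), setting = "inpatient",
               hospital_level = "secondary", stringsAsFactors = FALSE),
    data.frame(participant_id = "K2", drug = c("xiyanping", "dexamethasone"),
               date = c(60L, 60L), setting = "inpatient",
               hospital_level = "secondary", stringsAsFactors = FALSE))
  pairs <- data.frame(pair_id = 1:2, case_id = c("C1", "C1x"),
                      control_id = c("K1", "K2"), ps_case = 0.5,
                      ps_control = 0.5, ps_diff = 0,
                      stringsAsFactors = FALSE)
  # second case shares C1's data under another id to keep the pair count at 2
  rec2 <- records[records$participant_id == "C1", ]
  rec2$participant_id <- "C1x"
  records <- rbind(records, rec2)
  cases <- data.frame(participant_id = c("C1", "C1x"), index_date = 100L,
                      first_marker_date = 101L, marker_drug = "promethazine",
                      definition = "primary", stringsAsFactors = FALSE)
  ex <- code_exposures(pairs, records, v, cases)
  expect_equal(ex$gentamicin[ex$participant_id == "C1"], 1L)
  expect_equal(ex$gentamicin[ex$participant_id == "K1"], 0L)  # next-day, not same-date
  ek2 <- ex[ex$participant_id == "K2", ]
  expect_equal(ek2$n_exposures, 0L)  # marker drugs are never exposures
  expect_equal(ex$n_exposures,
               as.integer(rowSums(ex[, drug_key(v$target_concomitants)])))
  bad <- pairs; bad$control_id[1] <- "GHOST"
  expect_error(code_exposures(bad, records, v, cases), "missing from claims")
})

test_that("crude odds ratio matches the cross-product with Woolf interval", {
  est <- crude_or(two_by_two(10L, 10L, 10L, 10L))
  expect_equal(est$or, 1)
  expect_equal(log(est$ci_high), -log(est$ci_low))  # symmetric on log scale
  expect_equal(est$p_value, 1)
  # invariant to scaling both arms
  e1 <- crude_or(two_by_two(20L, 80L, 10L, 90L))
  e2 <- crude_or(two_by_two(200L, 800L, 100L, 900L))
  expect_equal(e1$or, e2$or)
  # zero cells: dash by default, Haldane on request
  z <- crude_or(two_by_two(10L, 939L, 0L, 949L))
  expect_true(is.na(z$or) && is.na(z$ci_low) && is.na(z$p_value))
  zh <- crude_or(two_by_two(10L, 939L, 0L, 949L), haldane = TRUE)
  expect_gt(zh$or, 1)
  expect_error(two_by_two(-1L, 2L, 3L, 4L), "non-negative")
})

test_that("discordant-pair estimator reduces to n10/n01 with exact McNemar p", {
  drugs <- "gentamicin"
  mk <- function(n10, n01, n00 = 5, n11 = 5) {
    pair_fixture(
      c(replicate(n10, 1, simplify = FALSE), replicate(n01, 0, simplify = FALSE),
        replicate(n00, 0, simplify = FALSE), replicate(n11, 1, simplify = FALSE)),
      c(replicate(n10, 0, simplify = FALSE), replicate(n01, 1, simplify = FALSE),
        replicate(n00, 0, simplify = FALSE), replicate(n11, 1, simplify = FALSE)),
      drugs)
  }
  est <- discordant_pair_or(mk(20, 10), "gentamicin")
  expect_equal(est$or, 2)
  expect_equal(est$p_value,
               min(1, 2 * pbinom(10, 30, 0.5)))
  sym <- discordant_pair_or(mk(12, 12), "gentamicin")
  expect_equal(sym$or, 1)
  expect_equal(sym$p_value, 1)
  none <- discordant_pair_or(mk(0, 0), "gentamicin")
  expect_true(is.na(none$or))
  expect_equal(attr(none, "note"), "no discordant pairs")
})

test_that("single-drug conditional fit equals ln(n10/n01) to 1e-8", {
  ex <- simulate_matched_pairs(400, log_or = c(gentamicin = log(2.5)),
                               prevalence = c(gentamicin = 0.3), seed = 17)
  dp <- discordant_pair_or(ex, "gentamicin")
  fit <- conditional_logit_fit(ex, "gentamicin")
  expect_equal(fit$coefficients[["gentamicin"]], log(dp$or),
               tolerance = 1e-8)
})

test_that("degenerate exposure patterns are refused with the drug named", {
  concordant <- pair_fixture(
    replicate(10, c(1, 1), simplify = FALSE),
    replicate(10, c(1, 0), simplify = FALSE),
    c("vitamin c", "ambroxol"))
  expect_error(conditional_logit_fit(concordant, c("vitamin c", "ambroxol")),
               "unidentified.*vitamin c")
  expect_error(conditional_logit_fit(concordant, "ambroxol"),
               "quasi-separation.*ambroxol")
})

test_that("multivariable maximizer beats a surrounding grid and an independent optimizer", {
  ex <- simulate_matched_pairs(
    500, log_or = c(gentamicin = log(3), `vitamin c` = log(1.3)),
    prevalence = c(gentamicin = 0.2, `vitamin c` = 0.3), seed = 23)
  fit <- conditional_logit_fit(ex, c("gentamicin", "vitamin c"))
  z <- as.matrix(ex[ex$arm == "case", drug_key(c("gentamicin", "vitamin c"))]) -
    as.matrix(ex[ex$arm == "control", drug_key(c("gentamicin", "vitamin c"))])
  b <- unname(fit$coefficients)
  ll_hat <- oracle_cloglik(b, z)
  grid <- seq(-0.5, 0.5, length.out = 41)
  for (d1 in grid) for (d2 in grid)
    if (oracle_cloglik(b + c(d1, d2), z) > ll_hat + 1e-10)
      fail(sprintf("grid point beats the maximizer at (%.3f, %.3f)", d1, d2))
  succeed()
  opt <- optim(c(0, 0), function(bb) -oracle_cloglik(bb, z),
               method = "BFGS", control = list(reltol = 1e-15))
  expect_equal(b, opt$par, tolerance = 1e-6)
})

test_that("conditional fit matches survival::clogit and flips sign with arms", {
  skip_if_not_installed("survival")
  ex <- simulate_matched_pairs(
    300, log_or = c(gentamicin = log(2), lidocaine = log(0.6)),
    prevalence = c(gentamicin = 0.25, lidocaine = 0.2), seed = 29)
  fit <- conditional_logit_fit(ex, c("gentamicin", "lidocaine"))
  df <- data.frame(y = as.integer(ex$arm == "case"),
                   g = ex$gentamicin, l = ex$lidocaine, s = ex$pair_id)
  cl <- survival::coxph(survival::Surv(rep(1, nrow(df)), y) ~ g + l +
                          survival::strata(s), data = df, method = "exact")
  expect_equal(unname(fit$coefficients), unname(coef(cl)), tolerance = 1e-6)
  swapped <- ex
  swapped$arm <- ifelse(ex$arm == "case", "control", "case")
  attr(swapped, "drugs") <- attr(ex, "drugs")
  fit2 <- conditional_logit_fit(swapped, c("gentamicin", "lidocaine"))
  expect_equal(unname(fit2$coefficients), -unname(fit$coefficients),
               tolerance = 1e-8)
})

test_that("backward selection keeps true effects and respects alpha", {
  ex <- simulate_matched_pairs(
    1200,
    log_or = c(gentamicin = log(4), ambroxol = 0, heparin = 0),
    prevalence = c(gentamicin = 0.2, ambroxol = 0.25, heparin = 0.2),
    seed = 37)
  sel <- backward_select(ex, alpha = 0.05)
  expect_true("gentamicin" %in% sel$drug)
  expect_true(all(sel$p_value <= 0.05))
  expect_equal(sel$or, sort(sel$or, decreasing = TRUE))
  full <- backward_select(ex, alpha = 1.0)
  expect_setequal(full$drug, c("gentamicin", "ambroxol", "heparin"))
  expect_length(attr(full, "eliminated"), 0)
})

test_that("selection retains a planted strong effect across seeds", {
  kept <- vapply(1:20, function(seed) {
    ex <- simulate_matched_pairs(
      800, log_or = c(gentamicin = log(4), ambroxol = 0, heparin = 0),
      prevalence = c(gentamicin = 0.2, ambroxol = 0.25, heparin = 0.2),
      seed = seed)
    "gentamicin" %in% backward_select(ex, alpha = 0.05)$drug
  }, logical(1))
  expect_gte(mean(kept), 0.9)
})

test_that("concomitant-count analysis tabulates both arms and the >=1-vs-0 contrast", {
  ex <- simulate_matched_pairs(
    200, log_or = c(gentamicin = log(2), ambroxol = 0),
    prevalence = c(gentamicin = 0.3, ambroxol = 0.4), seed = 41)
  res <- concomitant_count_analysis(ex)
  expect_equal(sum(res$distribution$cases_pct), 100, tolerance = 1e-9)
  expect_equal(sum(res$distribution$controls_pct), 100, tolerance = 1e-9)
  expect_equal(sum(res$distribution$cases), 200)
  expect_equal(res$estimate$estimator, "crude")
  zero <- pair_fixture(replicate(5, 0, simplify = FALSE),
                       replicate(5, 0, simplify = FALSE), "gentamicin")
  rz <- concomitant_count_analysis(zero)
  expect_true(is.na(rz$estimate$or))
  expect_equal(nrow(rz$distribution), 1)
})

test_that("subgroups stratify by the case member and partition the pairs", {
  v <- drug_vocabulary()
  sim <- generate_cohort(scenario_config(2000, seed = 43,
                                         baseline_allergy_logodds =
                                           qlogis(0.15)), v)
  coh <- build_cohort(sim$records, sim$profiles, v)
  cls <- classify_cohort(sim$records, coh, v)
  sets <- select_analysis_sets(coh, cls, "primary")
  cc <- coh[match(sets$cases$participant_id, coh$participant_id), ]
  mod <- fit_propensity(cc, sets$control_pool)
  pairs <- greedy_match(cc, sets$control_pool, mod)
  ex <- code_exposures(pairs, sim$records, v, sets$cases)
  by_gender <- subgroup_analysis(ex, sim$profiles, "gender")
  expect_setequal(names(by_gender), c("male", "female"))
  expect_equal(sum(vapply(by_gender, `[[`, numeric(1), "n_pairs")),
               nrow(pairs))
  by_age <- subgroup_analysis(ex, sim$profiles, "age_band")
  expect_true(all(names(by_age) %in% c("<18", "18-64", ">=65")))
  expect_equal(sum(vapply(by_age, `[[`, numeric(1), "n_pairs")),
               nrow(pairs))
  expect_error(subgroup_analysis(ex, sim$profiles, "height"))
})

test_that("age bands use the <18 / 18-64 / >=65 boundaries", {
  b <- nccclaims:::age_band(c(17.9, 18, 64.9, 65, 0.3))
  expect_equal(as.character(b), c("<18", "18-64", "18-64", ">=65", "<18"))
})
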