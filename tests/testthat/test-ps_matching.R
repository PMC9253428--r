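fake_units <- function(n, case = FALSE, seed = 1) {
  withr::local_seed(seed)
  data.frame(participant_id = sprintf("%s%03d", if (case) "C" else "K",
                                      seq_len(n)),
             age = round(runif(n, 1, 80), 1),
             gender = sample(c("male", "female"), n, replace = TRUE),
             setting = sample(c("inpatient", "outpatient"), n,
                              replace = TRUE),
             hospital_level = sample(c("tertiary", "secondary",
                                       "primary_healthcare"), n,
                                     replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("identical covariates collapse the model to the case fraction", {
  ca <- fake_units(30, case = TRUE)
  co <- fake_units(70)
  ca[, c("age", "gender", "setting", "hospital_level")] <-
    list(40, "male", "inpatient", "secondary")
  co[, c("age", "gender", "setting", "hospital_level")] <-
    list(40, "male", "inpatient", "secondary")
  mod <- fit_propensity(ca, co)
  expect_equal(mod$predict(ca), rep(0.3, 30), tolerance = 1e-8)
  expect_equal(length(mod$coefficients), 6)
})

test_that("logistic coefficients match an independent optimizer to 1e-6", {
  ca <- fake_units(60, case = TRUE, seed = 2)
  co <- fake_units(140, seed = 3)
  mod <- fit_propensity(ca, co)
  X <- cbind(1, ca$age, as.numeric(ca$gender == "male"),
             as.numeric(ca$setting == "inpatient"),
             as.numeric(ca$hospital_level == "secondary"),
             as.numeric(ca$hospital_level == "primary_healthcare"))
  Xk <- cbind(1, co$age, as.numeric(co$gender == "male"),
              as.numeric(co$setting == "inpatient"),
              as.numeric(co$hospital_level == "secondary"),
              as.numeric(co$hospital_level == "primary_healthcare"))
  X <- rbind(X, Xk)
  y <- rep(c(1, 0), c(60, 140))
  nll <- function(b) -sum(y * (X %*% b) - log1p(exp(X %*% b)))
  gr <- function(b) -as.vector(crossprod(X, y - plogis(X %*% b)))
  opt <- optim(rep(0, 6), nll, gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(unname(mod$coefficients), opt$par, tolerance = 1e-6)
  expect_lt(mod$convergence_info$gradient_norm, 1e-6)
})

test_that("perfect separation raises an error naming the covariate", {
  ca <- fake_units(20, case = TRUE, seed = 4)
  co <- fake_units(20, seed = 5)
  ca$setting <- "inpatient"; co$setting <- "outpatient"
  ca$age <- co$age <- 30; ca$gender <- co$gender <- "male"
  ca$hospital_level <- co$hospital_level <- "secondary"
  expect_error(fit_propensity(ca, co), "separation.*inpatient")
})

test_that("greedy matching picks nearest unused controls deterministically", {
  ca <- fake_units(1, case = TRUE)
  co <- fake_units(2)
  mod <- structure(list(fitted = TRUE), class = "propensity_model")
  mod$predict <- function(df) {
    if (identical(df$participant_id, ca$participant_id)) return(0.309)
    c(0.30, 0.31)
  }
  pairs <- greedy_match(ca, co, mod)
  expect_equal(pairs$control_id, "K002")  # ps 0.31 is nearer to 0.309
  # identical scores: matching falls back to ascending id, reproducibly
  mod$predict <- function(df) rep(0.5, nrow(df))
  p1 <- greedy_match(ca, co, mod)
  p2 <- greedy_match(ca, co, mod)
  expect_identical(p1$control_id, "K001")
  expect_identical(p1, p2)
})

test_that("greedy result equals rule enumeration and is no better than optimal", {
  ca <- fake_units(3, case = TRUE, seed = 6)
  co <- fake_units(5, seed = 7)
  score <- c(C001 = 0.62, C002 = 0.35, C003 = 0.55,
             K001 = 0.30, K002 = 0.60, K003 = 0.40, K004 = 0.56,
             K005 = 0.33)
  mod <- structure(list(fitted = TRUE), class = "propensity_model")
  mod$predict <- function(df) unname(score[df$participant_id])
  pairs <- greedy_match(ca, co, mod)
  ps_c <- mod$predict(ca); ps_k <- mod$predict(co)
  # brute-force application of the documented greedy rule
  used <- rep(FALSE, 5)
  expected <- character(3)
  for (i in order(-ps_c, ca$participant_id)) {
    d <- abs(ps_k - ps_c[i]); d[used] <- Inf
    ord <- order(d, co$participant_id)
    j <- ord[1]
    used[j] <- TRUE
    expected[i] <- co$participant_id[j]
  }
  expect_equal(pairs$control_id[match(ca$participant_id, pairs$case_id)],
               expected)
  # exhaustive optimal assignment can only be at least as tight
  perms <- expand.grid(a = 1:5, b = 1:5, c = 1:5)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 3), ]
  totals <- apply(perms, 1, function(r)
    sum(abs(ps_c - ps_k[as.integer(r)])))
  expect_gte(sum(pairs$ps_diff) + 1e-12, min(totals))
})

test_that("matching is without replacement and order-insensitive", {
  sim <- generate_cohort(scenario_config(1200, seed = 31))
  v <- drug_vocabulary()
  coh <- build_cohort(sim$records, sim$profiles, v)
  cls <- classify_cohort(sim$records, coh, v)
  sets <- select_analysis_sets(coh, cls, "primary")
  cc <- coh[match(sets$cases$participant_id, coh$participant_id), ]
  mod <- fit_propensity(cc, sets$control_pool)
  pairs <- greedy_match(cc, sets$control_pool, mod)
  expect_lte(nrow(pairs), min(nrow(cc), nrow(sets$control_pool)))
  expect_false(anyDuplicated(pairs$case_id) > 0)
  expect_false(anyDuplicated(pairs$control_id) > 0)
  withr::local_seed(2)
  shuf_c <- cc[sample(nrow(cc)), ]
  shuf_k <- sets$control_pool[sample(nrow(sets$control_pool)), ]
  pairs2 <- greedy_match(shuf_c, shuf_k, mod)
  expect_equal(pairs2[order(pairs2$case_id),
                      c("case_id", "control_id", "ps_diff")],
               pairs[order(pairs$case_id),
                     c("case_id", "control_id", "ps_diff")],
               ignore_attr = TRUE)
  # a tight caliper leaves distant cases unmatched but never drops invariants
  tight <- greedy_match(cc, sets$control_pool, mod, caliper = 0.001)
  expect_lte(nrow(tight), nrow(pairs))
  expect_equal(nrow(tight) + length(attr(tight, "unmatched")), nrow(cc))
})

test_that("balance table reports matched-group summaries and zero self-SMD", {
  fx <- make_worked_fixture()
  v <- drug_vocabulary()
  coh <- build_cohort(fx$records, fx$profiles, v)
  self <- covariate_balance(coh, coh)
  expect_true(all(abs(self$smd) < 1e-12))
  expect_match(self[self$covariate == "age", "cases"],
               "^\\d+\\.\\d{2} ± \\d+\\.\\d{2}$")
})

test_that("matching reduces covariate imbalance under confounded co-prescription", {
  v <- drug_vocabulary()
  deltas <- vapply(1:6, function(seed) {
    sc <- scenario_config(1500, seed = seed,
                          true_log_or = c(ambroxol = log(2)),
                          covariate_effects_on_coprescription =
                            c(age10 = 0.25, inpatient = 0.6))
    sim <- generate_cohort(sc, v)
    coh <- build_cohort(sim$records, sim$profiles, v)
    cls <- classify_cohort(sim$records, coh, v)
    sets <- select_analysis_sets(coh, cls, "primary")
    cc <- coh[match(sets$cases$participant_id, coh$participant_id), ]
    mod <- fit_propensity(cc, sets$control_pool)
    pairs <- greedy_match(cc, sets$control_pool, mod)
    pre <- covariate_balance(cc, sets$control_pool)
    post <- balance_table(pairs, cc, sets$control_pool)
    mean(abs(pre$smd)) - mean(abs(post$smd))
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
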