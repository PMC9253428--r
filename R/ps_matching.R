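#' @title Propensity-score estimation and greedy 1:1 matching
#' @description The propensity model is a four-covariate logistic regression
#'   (age, gender, visit setting, hospital level with tertiary reference)
#'   for case status, fitted by iteratively reweighted least squares; controls
#'   are matched 1:1 without replacement by a deterministic greedy
#'   nearest-neighbor pass over cases in descending propensity score.
#' @name ps_matching
NULL

ps_design <- function(df) {
  cbind(`(Intercept)` = 1,
        age = df$age,
        male = as.numeric(df$gender == "male"),
        inpatient = as.numeric(df$setting == "inpatient"),
        secondary = as.numeric(df$hospital_level == "secondary"),
        primary_healthcare = as.numeric(df$hospital_level ==
                                          "primary_healthcare"))
}

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of case status on age (continuous),
#' gender, setting and hospital level (two indicators, tertiary reference);
#' six coefficients in all. Perfect separation raises an error naming the
#' separating covariate rather than returning divergent coefficients.
#'
#' @param cases Cohort rows for cases (must carry `age`, `gender`, `setting`,
#'   `hospital_level`).
#' @param control_pool Cohort rows for the control pool.
#' @return An object of class `propensity_model`: list with `coefficients`
#'   (length 6), `convergence_info` (`iterations`, `gradient_norm`),
#'   `fitted` flag, and a `predict(df)` closure returning probabilities.
#' @export
fit_propensity <- function(cases, control_pool) {
  if (nrow(cases) < 1 || nrow(control_pool) < 1)
    stop("need at least one case and one control")
  df <- rbind(cases[, c("age", "gender", "setting", "hospital_level")],
              control_pool[, c("age", "gender", "setting", "hospital_level")])
  y <- rep(c(1, 0), c(nrow(cases), nrow(control_pool)))
  X <- ps_design(df)
  keep <- colnames(X)[-1][apply(X[, -1, drop = FALSE], 2,
                                function(v) length(unique(v)) > 1)]
  dropped <- setdiff(colnames(X)[-1], keep)
  Xf <- X[, c("(Intercept)", keep), drop = FALSE]
  check_separation(Xf[, keep, drop = FALSE], y)
  fit <- suppressWarnings(
    stats::glm.fit(Xf, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  beta[names(fit$coefficients)] <- fit$coefficients
  p <- as.vector(stats::plogis(X %*% beta))
  score <- as.vector(crossprod(Xf, y - p[seq_along(y)]))
  if (max(abs(score)) > 1e-6 || any(abs(beta) > 30))
    check_separation(Xf[, keep, drop = FALSE], y, force = TRUE)
  model <- list(coefficients = beta,
                dropped_constant = dropped,
                fitted = TRUE,
                convergence_info = list(iterations = fit$iter,
                                        gradient_norm = max(abs(score))))
  model$predict <- function(df) as.vector(stats::plogis(ps_design(df) %*% beta))
  class(model) <- "propensity_model"
  model
}

# Complete-separation screen: a single covariate whose case range and control
# range do not overlap separates the outcome perfectly.
check_separation <- function(X, y, force = FALSE) {
  for (j in colnames(X)) {
    v1 <- X[y == 1, j]; v0 <- X[y == 0, j]
    if (min(v1) > max(v0) || max(v1) < min(v0))
      stop("perfect separation on covariate '", j,
           "': case and control values do not overlap")
  }
  if (force)
    stop("propensity model did not converge (quasi-separation suspected)")
  invisible(TRUE)
}

#' Greedy 1:1 nearest-neighbor matching without replacement
#'
#' Cases are processed in descending propensity score (ties broken by
#' ascending participant id); each case takes the not-yet-used control with
#' the smallest absolute propensity-score difference (ties by ascending
#' control id). Input row order never matters: units are canonically sorted
#' before matching, so the result is fully deterministic.
#'
#' @param cases Cohort rows for cases.
#' @param control_pool Cohort rows for candidate controls.
#' @param model A fitted [fit_propensity()] model.
#' @param caliper Optional maximum |ps difference| expressed in SDs of the
#'   logit of the propensity score (the usual caliper unit); cases with no
#'   control inside the caliper stay unmatched and are reported via the
#'   `unmatched` attribute. Default `NULL`: no caliper.
#' @param order_by `"descending"` (default) or `"random"` case processing
#'   order; the random order uses `seed`.
#' @param scale Match on the `"probability"` (default) or `"logit"` scale.
#' @param seed Seed for `order_by = "random"`.
#' @return Data.frame of matched pairs: `pair_id`, `case_id`, `control_id`,
#'   `ps_case`, `ps_control`, `ps_diff`; attribute `unmatched` lists case ids
#'   left unmatched.
#' @export
greedy_match <- function(cases, control_pool, model, caliper = NULL,
                         order_by = c("descending", "random"),
                         scale = c("probability", "logit"), seed = 1L) {
  order_by <- match.arg(order_by)
  scale <- match.arg(scale)
  stopifnot(inherits(model, "propensity_model"), isTRUE(model$fitted))
  ps_case <- model$predict(cases)
  ps_ctrl <- model$predict(control_pool)
  met_case <- if (scale == "logit") stats::qlogis(ps_case) else ps_case
  met_ctrl <- if (scale == "logit") stats::qlogis(ps_ctrl) else ps_ctrl
  cal <- Inf
  if (!is.null(caliper)) {
    sd_logit <- stats::sd(stats::qlogis(c(ps_case, ps_ctrl)))
    cal <- caliper * if (scale == "logit") sd_logit else
      stats::sd(c(ps_case, ps_ctrl))
  }
  if (nrow(control_pool) < nrow(cases))
    warning("control pool (", nrow(control_pool), ") smaller than case set (",
            nrow(cases), "); matching will be partial")
  ord <- order(-met_case, cases$participant_id)
  if (order_by == "random") {
    rng <- new_rng(seed)
    ord <- rng$sample(seq_len(nrow(cases)), nrow(cases))
  }
  # canonical control order so ties resolve by ascending id
  ctrl_ord <- order(control_pool$participant_id)
  ctrl_id <- control_pool$participant_id[ctrl_ord]
  ctrl_met <- met_ctrl[ctrl_ord]
  ctrl_ps <- ps_ctrl[ctrl_ord]
  used <- rep(FALSE, length(ctrl_id))
  out <- vector("list", length(ord))
  unmatched <- character()
  for (k in seq_along(ord)) {
    i <- ord[k]
    dist <- abs(ctrl_met - met_case[i])
    dist[used] <- Inf
    j <- which.min(dist)  # first minimum = lowest id among ties
    if (!length(j) || !is.finite(dist[j]) || dist[j] > cal) {
      unmatched <- c(unmatched, cases$participant_id[i])
      next
    }
    used[j] <- TRUE
    out[[k]] <- data.frame(case_id = cases$participant_id[i],
                           control_id = ctrl_id[j],
                           ps_case = ps_case[i], ps_control = ctrl_ps[j],
                           ps_diff = abs(ps_case[i] - ctrl_ps[j]),
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pairs)) pairs <- data.frame(case_id = character(),
                                          control_id = character(),
                                          ps_case = numeric(),
                                          ps_control = numeric(),
                                          ps_diff = numeric())
  stopifnot(!anyDuplicated(pairs$case_id), !anyDuplicated(pairs$control_id))
  pairs <- data.frame(pair_id = seq_len(nrow(pairs)), pairs,
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  attr(pairs, "unmatched") <- unmatched
  pairs
}

#' Covariate balance between two groups
#'
#' Standardized mean differences for the four propensity covariates: the age
#' SMD uses the pooled-SD denominator; categorical covariates get one row per
#' level with the proportion-based SMD.
#'
#' @param g1,g2 Cohort-like data.frames (`age`, `gender`, `setting`,
#'   `hospital_level`).
#' @param labels Group labels for the formatted columns.
#' @return Data.frame with `covariate`, `level`, formatted per-group summary
#'   strings (mean ± SD or n (%)), and `smd`.
#' @export
covariate_balance <- function(g1, g2, labels = c("cases", "controls")) {
  rows <- list()
  m1 <- mean(g1$age); s1 <- stats::sd(g1$age)
  m2 <- mean(g2$age); s2 <- stats::sd(g2$age)
  pool <- sqrt((s1^2 + s2^2) / 2)
  rows[[1]] <- data.frame(covariate = "age", level = "",
                          a = sprintf("%.2f ± %.2f", m1, s1),
                          b = sprintf("%.2f ± %.2f", m2, s2),
                          smd = if (pool > 0) (m1 - m2) / pool else 0,
                          stringsAsFactors = FALSE)
  cat_rows <- function(var, levels) {
    lapply(levels, function(lv) {
      p1 <- mean(g1[[var]] == lv); p2 <- mean(g2[[var]] == lv)
      den <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
      data.frame(covariate = var, level = lv,
                 a = sprintf("%d (%.2f)", sum(g1[[var]] == lv), 100 * p1),
                 b = sprintf("%d (%.2f)", sum(g2[[var]] == lv), 100 * p2),
                 smd = if (den > 0) (p1 - p2) / den else 0,
                 stringsAsFactors = FALSE)
    })
  }
  rows <- c(rows, cat_rows("gender", GENDERS), cat_rows("setting", SETTINGS),
            cat_rows("hospital_level", HOSPITAL_LEVELS))
  out <- do.call(rbind, rows)
  names(out)[3:4] <- labels
  rownames(out) <- NULL
  out
}

#' Balance table for matched pairs
#'
#' Compares matched cases with their matched controls on the four propensity
#' covariates, in the baseline-table style (mean ± SD for age, n (%) for
#' categorical levels) plus standardized mean differences.
#'
#' @param pairs Matched pairs from [greedy_match()].
#' @param cases,controls Cohort rows covering at least the matched ids.
#' @return See [covariate_balance()].
#' @export
balance_table <- function(pairs, cases, controls) {
  if (nrow(pairs) < 1) stop("need at least one matched pair")
  g1 <- cases[match(pairs$case_id, cases$participant_id), , drop = FALSE]
  g2 <- controls[match(pairs$control_id, controls$participant_id), ,
                 drop = FALSE]
  if (anyNA(g1$age) || anyNA(g2$age))
    stop("matched ids missing from the supplied case/control tables")
  covariate_balance(g1, g2)
}
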