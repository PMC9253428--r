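#' @title Exposure coding and effect estimators
#' @description Codes the 25 binary concomitant exposures (same-date rule)
#'   for matched participants and computes every reported statistic: crude
#'   2x2 odds ratios with Woolf intervals, matched discordant-pair odds
#'   ratios with exact McNemar p-values, multivariable conditional logistic
#'   regression for 1:1 pairs by Newton-Raphson on pair differences, backward
#'   variable selection at a Wald threshold, the concomitant-count contrast,
#'   and age-band / gender subgroup estimates.
#' @name estimators
NULL

new_estimate <- function(drug, or, ci_low, ci_high, p, estimator,
                         n_case = NA_integer_, n_ctrl = NA_integer_) {
  data.frame(drug = drug, n_cases_exposed = n_case,
             n_controls_exposed = n_ctrl, or = or, ci_low = ci_low,
             ci_high = ci_high, p_value = p, estimator = estimator,
             stringsAsFactors = FALSE)
}

#' Code concomitant exposures for matched participants
#'
#' A participant is exposed to a target drug iff they have a prescription of
#' that drug dated exactly on their own index (first index-drug) date. For
#' case arms the exposure date must also be no later than the first marker
#' date; under same-date coding this holds automatically (the incident marker
#' never precedes the index date for a case) and is asserted. Marker drugs
#' are never exposures.
#'
#' @param pairs Matched pairs from [greedy_match()].
#' @param records Prescription records.
#' @param vocab A [drug_vocabulary()].
#' @param cases Case records (for the marker-date assertion).
#' @return Data.frame with `pair_id`, `participant_id`, `arm`
#'   (`case`/`control`), one 0/1 column per target drug (key-named), and
#'   `n_exposures`; attribute `drugs` maps keys back to vocabulary names.
#' @export
code_exposures <- function(pairs, records, vocab = drug_vocabulary(), cases) {
  ids <- c(pairs$case_id, pairs$control_id)
  miss <- setdiff(ids, records$participant_id)
  if (length(miss))
    stop("matched participants missing from claims: ",
         paste(utils::head(miss, 5), collapse = ", "))
  xyp <- records[records$drug == vocab$xyp_name, , drop = FALSE]
  xyp <- xyp[order(xyp$participant_id, xyp$date), , drop = FALSE]
  index_date <- xyp$date[!duplicated(xyp$participant_id)]
  names(index_date) <- xyp$participant_id[!duplicated(xyp$participant_id)]
  if (anyNA(index_date[ids]))
    stop("matched participants without an index-drug prescription")
  long <- data.frame(pair_id = rep(pairs$pair_id, 2),
                     participant_id = ids,
                     arm = rep(c("case", "control"), each = nrow(pairs)),
                     stringsAsFactors = FALSE)
  long$index_date <- index_date[long$participant_id]
  # case arms anchor on the ascertained index date; assert consistency
  mcase <- match(pairs$case_id, cases$participant_id)
  stopifnot(!anyNA(mcase),
            all(cases$index_date[mcase] == index_date[pairs$case_id]),
            all(cases$first_marker_date[mcase] >= cases$index_date[mcase]))
  tgt <- records[records$drug %in% vocab$target_concomitants, , drop = FALSE]
  key <- paste(tgt$participant_id, tgt$date)
  for (d in vocab$target_concomitants) {
    hit <- key[tgt$drug == d]
    long[[drug_key(d)]] <-
      as.integer(paste(long$participant_id, long$index_date) %in% hit)
  }
  kcols <- drug_key(vocab$target_concomitants)
  long$n_exposures <- as.integer(rowSums(long[, kcols, drop = FALSE]))
  long$index_date <- NULL
  long <- long[order(long$pair_id, long$arm), , drop = FALSE]
  rownames(long) <- NULL
  attr(long, "drugs") <- vocab$target_concomitants
  long
}

#' 2x2 exposure table
#'
#' @param a Exposed cases. @param b Unexposed cases.
#' @param c Exposed controls. @param d Unexposed controls.
#' @return A `two_by_two` list.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("2x2 cells must be non-negative integers")
  structure(as.list(cells), class = "two_by_two")
}

#' Crude (unadjusted) odds ratio from a 2x2 table
#'
#' OR = ad/bc with the Woolf confidence interval
#' `exp(ln OR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` and a two-sided Wald p on
#' the log odds ratio. Any zero cell leaves the estimate undefined (reported
#' as an em dash) unless the Haldane-Anscombe +0.5 correction is enabled.
#'
#' @param t A [two_by_two()] table.
#' @param drug Label for the output row.
#' @param haldane Add 0.5 to every cell when any cell is zero (default off).
#' @return One-row estimates data.frame (`estimator = "crude"`).
#' @export
crude_or <- function(t, drug = "", haldane = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (any(c(a, b, c, d) == 0)) {
    if (!haldane)
      return(new_estimate(drug, NA_real_, NA_real_, NA_real_, NA_real_,
                          "crude", a, c))
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  p <- 2 * stats::pnorm(-abs(lor / se))
  new_estimate(drug, exp(lor), exp(lor - 1.96 * se), exp(lor + 1.96 * se),
               p, "crude", t$a, t$c)
}

# Discordant-pair counts for one drug key: n10 case-only exposed, n01
# control-only exposed.
discordant_counts <- function(exposures, key) {
  ca <- exposures[exposures$arm == "case", ]
  co <- exposures[exposures$arm == "control", ]
  co <- co[match(ca$pair_id, co$pair_id), ]
  xc <- ca[[key]]; xk <- co[[key]]
  c(n10 = sum(xc == 1 & xk == 0), n01 = sum(xc == 0 & xk == 1),
    n_case = sum(xc), n_ctrl = sum(xk))
}

#' Matched discordant-pair odds ratio
#'
#' OR = n10/n01 over the discordant pairs, with the usual log-scale interval
#' `exp(ln OR ± 1.96 sqrt(1/n10 + 1/n01))` and the exact McNemar p-value
#' (doubled binomial(n10+n01, 1/2) tail, capped at 1).
#'
#' @param exposures Exposure matrix from [code_exposures()].
#' @param drug Vocabulary drug name.
#' @return One-row estimates data.frame (`estimator = "discordant_pair"`).
#' @export
discordant_pair_or <- function(exposures, drug) {
  dc <- discordant_counts(exposures, drug_key(drug))
  n10 <- dc[["n10"]]; n01 <- dc[["n01"]]
  if (n10 + n01 == 0) {
    out <- new_estimate(drug, NA_real_, NA_real_, NA_real_, NA_real_,
                        "discordant_pair", dc[["n_case"]], dc[["n_ctrl"]])
    attr(out, "note") <- "no discordant pairs"
    return(out)
  }
  if (n10 == 0 || n01 == 0) {
    p <- min(1, 2 * stats::pbinom(min(n10, n01), n10 + n01, 0.5))
    out <- new_estimate(drug, NA_real_, NA_real_, NA_real_, p,
                        "discordant_pair", dc[["n_case"]], dc[["n_ctrl"]])
    attr(out, "note") <- "one-sided discordance; OR unbounded"
    return(out)
  }
  lor <- log(n10 / n01)
  se <- sqrt(1 / n10 + 1 / n01)
  p <- min(1, 2 * stats::pbinom(min(n10, n01), n10 + n01, 0.5))
  new_estimate(drug, exp(lor), exp(lor - 1.96 * se), exp(lor + 1.96 * se),
               p, "discordant_pair", dc[["n_case"]], dc[["n_ctrl"]])
}

# Pair-difference matrix z = x_case - x_control for the selected drug keys.
pair_differences <- function(exposures, keys) {
  ca <- exposures[exposures$arm == "case", , drop = FALSE]
  co <- exposures[exposures$arm == "control", , drop = FALSE]
  co <- co[match(ca$pair_id, co$pair_id), , drop = FALSE]
  as.matrix(ca[, keys, drop = FALSE]) - as.matrix(co[, keys, drop = FALSE])
}

conditional_loglik <- function(beta, z) {
  eta <- as.vector(z %*% beta)
  sum(stats::plogis(eta, log.p = TRUE))
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximizes the matched-pair conditional likelihood
#' `prod_j 1 / (1 + exp(-beta' (x_case_j - x_control_j)))` by Newton-Raphson
#' on the pair-difference representation (gradient `sum z (1 - p)`, observed
#' information `sum z z' p (1 - p)`), starting at zero, converged when the
#' maximum absolute gradient component is below `tol` within `max_iter`
#' iterations. Drugs with no discordant pairs (unidentified coefficient) or
#' with one-sided discordance (quasi-separation, infinite MLE) raise an error
#' naming them; unconverged estimates are never returned silently.
#'
#' @param exposures Exposure matrix from [code_exposures()] or
#'   [simulate_matched_pairs()].
#' @param drugs Vocabulary drug names to include.
#' @param tol Gradient convergence tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 200).
#' @return List with `coefficients` (named log odds ratios), `covariance`
#'   (inverse observed information), `loglik`, `iterations`, `n_pairs`.
#' @export
conditional_logit_fit <- function(exposures, drugs, tol = 1e-8,
                                  max_iter = 200L) {
  keys <- drug_key(drugs)
  z <- pair_differences(exposures, keys)
  if (nrow(z) < 1) stop("no pairs available")
  zero <- colSums(z != 0) == 0
  if (any(zero))
    stop("coefficient(s) unidentified (no discordant pairs): ",
         paste(drugs[zero], collapse = ", "))
  mono <- apply(z, 2, function(v) all(v >= 0) || all(v <= 0))
  if (any(mono))
    stop("quasi-separation (one-sided discordance) for: ",
         paste(drugs[mono], collapse = ", "))
  beta <- rep(0, ncol(z))
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(as.vector(z %*% beta))
    grad <- as.vector(crossprod(z, 1 - p))
    if (max(abs(grad)) < tol) break
    info <- crossprod(z * sqrt(p * (1 - p)))
    step <- tryCatch(solve(info, grad),
                     error = function(e) stop("singular information matrix; ",
                                              "collinear exposures"))
    # halve the step while it worsens the conditional log likelihood
    ll0 <- conditional_loglik(beta, z)
    for (h in 0:20) {
      cand <- beta + step / 2^h
      if (conditional_loglik(cand, z) >= ll0 - 1e-12) break
    }
    beta <- cand
  }
  p <- stats::plogis(as.vector(z %*% beta))
  grad <- as.vector(crossprod(z, 1 - p))
  if (max(abs(grad)) >= tol)
    stop("conditional logistic fit did not converge in ", max_iter,
         " iterations (max |gradient| = ", format(max(abs(grad))), ")")
  info <- crossprod(z * sqrt(p * (1 - p)))
  list(coefficients = stats::setNames(beta, drugs),
       covariance = solve(info), loglik = conditional_loglik(beta, z),
       iterations = it, n_pairs = nrow(z))
}

fit_to_estimates <- function(fit, exposures, estimator) {
  drugs <- names(fit$coefficients)
  se <- sqrt(diag(fit$covariance))
  rows <- lapply(seq_along(drugs), function(i) {
    dc <- discordant_counts(exposures, drug_key(drugs[i]))
    b <- fit$coefficients[i]
    new_estimate(drugs[i], exp(b), exp(b - 1.96 * se[i]),
                 exp(b + 1.96 * se[i]), 2 * stats::pnorm(-abs(b / se[i])),
                 estimator, dc[["n_case"]], dc[["n_ctrl"]])
  })
  do.call(rbind, rows)
}

#' Backward variable selection on the conditional model
#'
#' Fits the full conditional-logistic model on the supplied drugs (drugs with
#' zero or one-sided discordance are pre-dropped and reported via the
#' `dropped` attribute), then iteratively removes the single variable with
#' the largest Wald p-value above `alpha` and refits, stopping when every
#' remaining variable has p <= alpha. Final-model odds ratios are returned
#' sorted by descending OR.
#'
#' @param exposures Exposure matrix.
#' @param alpha Two-sided retention threshold (default 0.05).
#' @param drugs Candidate drugs (default: all coded drugs).
#' @return Estimates data.frame (`estimator = "conditional_multivariable"`),
#'   attributes `dropped` (pre-dropped drugs with reasons) and `eliminated`
#'   (removal order). Empty result (zero rows) if everything is eliminated.
#' @export
backward_select <- function(exposures, alpha = 0.05,
                            drugs = attr(exposures, "drugs")) {
  if (is.null(drugs)) stop("exposure matrix carries no drug list")
  keys <- drug_key(drugs)
  z <- pair_differences(exposures, keys)
  zero <- colSums(z != 0) == 0
  mono <- !zero & apply(z, 2, function(v) all(v >= 0) || all(v <= 0))
  drop_idx <- which(zero | mono)
  dropped <- data.frame(drug = drugs[drop_idx],
                        reason = ifelse(zero[drop_idx], "no_discordant_pairs",
                                        "one_sided_discordance"),
                        stringsAsFactors = FALSE)
  current <- drugs[!(zero | mono)]
  eliminated <- character()
  while (length(current)) {
    fit <- conditional_logit_fit(exposures, current)
    se <- sqrt(diag(fit$covariance))
    p <- 2 * stats::pnorm(-abs(fit$coefficients / se))
    if (max(p) <= alpha) break
    worst <- names(which.max(p))
    eliminated <- c(eliminated, worst)
    current <- setdiff(current, worst)
  }
  if (!length(current)) {
    out <- new_estimate(character(), numeric(), numeric(), numeric(),
                        numeric(), character())[0, ]
    message("backward_select: all variables eliminated at alpha = ", alpha)
  } else {
    out <- fit_to_estimates(fit, exposures, "conditional_multivariable")
    out <- out[order(-out$or), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "dropped") <- dropped
  attr(out, "eliminated") <- eliminated
  out
}

#' Concomitant-count distribution and the >=1-vs-0 contrast
#'
#' Tabulates the number of target concomitant medications per participant in
#' each arm (counts and percentages) and estimates the crude odds ratio for
#' using at least one target concomitant versus none.
#'
#' @param exposures Exposure matrix.
#' @param haldane Passed to [crude_or()].
#' @return List with `distribution` (data.frame: `n_concomitants`,
#'   `cases`, `cases_pct`, `controls`, `controls_pct`) and `estimate`
#'   (one-row estimates data.frame for >=1 vs 0).
#' @export
concomitant_count_analysis <- function(exposures, haldane = FALSE) {
  ca <- exposures$n_exposures[exposures$arm == "case"]
  co <- exposures$n_exposures[exposures$arm == "control"]
  lev <- 0:max(exposures$n_exposures)
  dist <- data.frame(n_concomitants = lev,
                     cases = as.integer(table(factor(ca, levels = lev))),
                     controls = as.integer(table(factor(co, levels = lev))))
  dist$cases_pct <- 100 * dist$cases / max(1L, length(ca))
  dist$controls_pct <- 100 * dist$controls / max(1L, length(co))
  dist <- dist[, c("n_concomitants", "cases", "cases_pct",
                   "controls", "controls_pct")]
  t <- two_by_two(sum(ca >= 1), sum(ca == 0), sum(co >= 1), sum(co == 0))
  est <- crude_or(t, drug = ">=1 concomitant vs 0", haldane = haldane)
  list(distribution = dist, estimate = est)
}

#' Univariate estimates for every target drug
#'
#' For each drug: the crude 2x2 odds ratio across arms and/or the matched
#' discordant-pair odds ratio.
#'
#' @param exposures Exposure matrix.
#' @param which `"crude"`, `"discordant"`, or `"both"` (default).
#' @param haldane Passed to [crude_or()].
#' @param drugs Drugs to report (default: all coded).
#' @return Estimates data.frame, drugs in panel order, crude rows first.
#' @export
univariate_estimates <- function(exposures, which = c("both", "crude",
                                                      "discordant"),
                                 haldane = FALSE,
                                 drugs = attr(exposures, "drugs")) {
  which <- match.arg(which)
  n_case <- sum(exposures$arm == "case")
  n_ctrl <- sum(exposures$arm == "control")
  out <- list()
  if (which %in% c("both", "crude")) {
    out$crude <- do.call(rbind, lapply(drugs, function(d) {
      dc <- discordant_counts(exposures, drug_key(d))
      crude_or(two_by_two(dc[["n_case"]], n_case - dc[["n_case"]],
                          dc[["n_ctrl"]], n_ctrl - dc[["n_ctrl"]]),
               drug = d, haldane = haldane)
    }))
  }
  if (which %in% c("both", "discordant")) {
    out$disc <- do.call(rbind, lapply(drugs, discordant_pair_or,
                                      exposures = exposures))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

age_band <- function(age) {
  cut(age, breaks = c(-Inf, 18, 65, Inf), right = FALSE,
      labels = c("<18", "18-64", ">=65"))
}

#' Subgroup analysis by age band or gender
#'
#' Stratifies matched pairs by the case member's subgroup (pairs are
#' near-homogeneous after matching) and re-runs the univariate and
#' multivariable machinery within each stratum. Age bands are `<18`,
#' `18-64`, `>=65`. Strata whose total discordance for a drug falls below
#' `min_discordant` report no estimate for it, and the multivariable step is
#' skipped (with a note) when it cannot be fitted.
#'
#' @param exposures Exposure matrix.
#' @param profiles Participant profiles (for the case member's age/gender).
#' @param grouping `"age_band"` or `"gender"`.
#' @param alpha Passed to [backward_select()].
#' @param min_discordant Minimum discordant pairs per drug (default 5).
#' @return Named list (one element per subgroup) of lists with `n_pairs`,
#'   `univariate`, `multivariable` (or a `note`).
#' @export
subgroup_analysis <- function(exposures, profiles,
                              grouping = c("age_band", "gender"),
                              alpha = 0.05, min_discordant = 5L) {
  grouping <- match.arg(grouping)
  ca <- exposures[exposures$arm == "case", , drop = FALSE]
  m <- match(ca$participant_id, profiles$participant_id)
  if (anyNA(m)) stop("case participants missing from profiles")
  grp <- if (grouping == "age_band") as.character(age_band(profiles$age[m]))
         else profiles$gender[m]
  drugs <- attr(exposures, "drugs")
  res <- list()
  for (g in sort(unique(grp))) {
    pid <- ca$pair_id[grp == g]
    sub <- exposures[exposures$pair_id %in% pid, , drop = FALSE]
    attr(sub, "drugs") <- drugs
    disc <- vapply(drugs, function(d) {
      dc <- discordant_counts(sub, drug_key(d))
      dc[["n10"]] + dc[["n01"]]
    }, numeric(1))
    keep <- drugs[disc >= min_discordant]
    uni <- if (length(keep)) univariate_estimates(sub, drugs = keep)
           else NULL
    multi <- tryCatch(
      if (length(keep)) backward_select(sub, alpha = alpha, drugs = keep)
      else NULL,
      error = function(e) NULL)
    res[[g]] <- list(n_pairs = length(pid), univariate = uni,
                     multivariable = multi,
                     insufficient = setdiff(drugs, keep),
                     note = if (!length(keep)) "insufficient data" else NULL)
  }
  res
}
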