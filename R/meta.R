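#' Study-level records
#'
#' A study-record table holds one row per (study, outcome): the number of
#' treated cases `n`, the number with the outcome `events`, and study-level
#' covariates (follow-up, demographics) used by the meta-regressions.
#'
#' @param study_id,treatment,outcome character vectors.
#' @param n,events integer vectors; `0 <= events <= n`.
#' @param follow_up_months positive numeric.
#' @param mean_age,pct_female,pct_prior optional numeric covariates
#'   (proportions for the percentage columns).
#' @return data.frame of class `study_records`.
#' @export
study_records <- function(study_id, treatment, outcome, n, events,
                          follow_up_months,
                          mean_age = NA_real_, pct_female = NA_real_,
                          pct_prior = NA_real_) {
  d <- data.frame(study_id = as.character(study_id),
                  treatment = as.character(treatment),
                  outcome = as.character(outcome),
                  n = as.integer(n), events = as.integer(events),
                  follow_up_months = as.numeric(follow_up_months),
                  mean_age = as.numeric(mean_age),
                  pct_female = as.numeric(pct_female),
                  pct_prior = as.numeric(pct_prior),
                  stringsAsFactors = FALSE)
  if (any(d$n <= 0)) stop("study n must be positive")
  if (any(d$events < 0 | d$events > d$n)) stop("events must lie in [0, n]")
  if (any(!d$treatment %in% c("MVD", "SRS"))) {
    stop("treatment must be 'MVD' or 'SRS'")
  }
  if (any(!is.na(d$follow_up_months) & d$follow_up_months <= 0)) {
    stop("follow_up_months must be positive")
  }
  class(d) <- c("study_records", "data.frame")
  d
}

#' Load study records from CSV, applying the prior-procedure inclusion rule
#'
#' Reads the study-record CSV schema (columns `study_id, treatment, outcome,
#' n, events, follow_up_months, mean_age, pct_female, pct_prior`) and drops
#' studies in which more than `max_prior` (default 35%) of cases had a
#' previous MVD or SRS, messaging the number excluded.
#'
#' @param path CSV file path.
#' @param max_prior exclusion threshold on the prior-procedure proportion.
#' @return a [study_records()] data.frame.
#' @export
load_study_records <- function(path, max_prior = 0.35) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "treatment", "outcome", "n", "events",
            "follow_up_months")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("study-record CSV missing columns: ",
                         paste(miss, collapse = ", "))
  for (opt in c("mean_age", "pct_female", "pct_prior")) {
    if (!opt %in% names(d)) d[[opt]] <- NA_real_
  }
  rec <- study_records(d$study_id, d$treatment, d$outcome, d$n, d$events,
                       d$follow_up_months, d$mean_age, d$pct_female,
                       d$pct_prior)
  drop <- !is.na(rec$pct_prior) & rec$pct_prior > max_prior
  if (any(drop)) {
    message(sprintf(
      "excluding %d record(s) from %d study(ies) with > %.0f%% prior procedures",
      sum(drop), length(unique(rec$study_id[drop])), 100 * max_prior))
    rec <- rec[!drop, , drop = FALSE]
  }
  rec
}

# Per-study proportion and sampling variance on the raw scale, with a 0.5
# continuity correction at the 0 / n boundaries (otherwise the variance is 0
# and the study would get infinite weight).
study_proportions <- function(n, events) {
  boundary <- events == 0L | events == n
  x <- ifelse(boundary, events + 0.5, as.numeric(events))
  m <- ifelse(boundary, n + 1, as.numeric(n))
  p <- x / m
  list(p = p, v = p * (1 - p) / m)
}

#' Random-effects pooled proportion (DerSimonian-Laird)
#'
#' Inverse-variance pooling of study proportions on the raw-proportion scale.
#' Between-study variance `tau2` is the DerSimonian-Laird method-of-moments
#' estimate truncated at zero; the pooled mean uses random-effects weights
#' `1 / (v_i + tau2)`.  Cochran's Q (fixed-effect weights) and its
#' chi-square(k-1) p-value quantify heterogeneity.  Proportions at the 0 or n
#' boundary receive a 0.5 continuity correction.  Logit-scale pooling
#' (pool, then back-transform the mean via the inverse logit) is available as
#' an option for rates near the boundary.
#'
#' @param records a [study_records()] data.frame, all rows sharing one
#'   outcome label.
#' @param scale `"proportion"` (default) or `"logit"`.
#' @return list of class `pooled_estimate`: `mean`, `se`, `tau2`, `q`,
#'   `p_het`, `k`.
#' @export
pool_proportion <- function(records, scale = c("proportion", "logit")) {
  scale <- match.arg(scale)
  if (nrow(records) == 0L) stop("no study records to pool")
  if (length(unique(records$outcome)) != 1L) {
    stop("records mix outcome labels: ",
         paste(unique(records$outcome), collapse = ", "))
  }
  sp <- study_proportions(records$n, records$events)
  if (scale == "logit") {
    # delta-method variance of logit(p)
    yi <- stats::qlogis(sp$p)
    vi <- sp$v / (sp$p * (1 - sp$p))^2
  } else {
    yi <- sp$p
    vi <- sp$v
  }
  k <- length(yi)
  wi <- 1 / vi
  mu_fe <- sum(wi * yi) / sum(wi)
  q <- sum(wi * (yi - mu_fe)^2)
  if (k > 1L) {
    c_dl <- sum(wi) - sum(wi^2) / sum(wi)
    tau2 <- max(0, (q - (k - 1)) / c_dl)
    p_het <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  } else {
    tau2 <- 0
    p_het <- NA_real_
  }
  wr <- 1 / (vi + tau2)
  mu <- sum(wr * yi) / sum(wr)
  se <- sqrt(1 / sum(wr))
  if (scale == "logit") {
    mu_p <- stats::plogis(mu)
    se <- se * mu_p * (1 - mu_p)  # delta method back to the proportion scale
    mu <- mu_p
  }
  structure(list(mean = mu, se = se, tau2 = tau2, q = q, p_het = p_het, k = k,
                 scale = scale),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled proportion %.4f (se %.4f), k = %d, tau2 = %.5f, Q = %.3f (p = %.3g)\n",
              x$mean, x$se, x$k, x$tau2, x$q, x$p_het))
  invisible(x)
}

#' Cochran heterogeneity test
#'
#' Q statistic with fixed-effect inverse-variance weights and its
#' chi-square(k-1) p-value.
#'
#' @inheritParams pool_proportion
#' @return list with `q` and `p_het`.
#' @export
heterogeneity_test <- function(records) {
  if (nrow(records) < 2L) stop("heterogeneity test requires at least 2 studies")
  est <- pool_proportion(records)
  list(q = est$q, p_het = est$p_het)
}

#' Random-effects meta-regression of a proportion on one covariate
#'
#' Regresses study proportions (raw scale, continuity-corrected) on a single
#' study-level covariate under a random-effects model, via
#' [metafor::rma()] with `method = "DL"` and normal-approximation slope
#' tests.  The reported `r2` is the conventional meta-regression coefficient
#' of determination: the proportion of between-study variance explained,
#' `(tau2_null - tau2_model) / tau2_null`, truncated to \[0, 1\].
#'
#' @param records a [study_records()] data.frame, one outcome label.
#' @param covariate name of the covariate column (e.g.
#'   `"follow_up_months"`).
#' @return list of class `meta_regression`: `intercept`, `slope`, `slope_se`,
#'   `p_slope`, `r2`, `tau2`, `k`.
#' @export
meta_regress <- function(records, covariate) {
  if (nrow(records) < 3L) stop("meta-regression requires at least 3 studies")
  if (length(unique(records$outcome)) != 1L) {
    stop("records mix outcome labels")
  }
  if (!covariate %in% names(records)) stop("unknown covariate: ", covariate)
  x <- records[[covariate]]
  if (any(is.na(x))) stop("covariate '", covariate, "' has missing values")
  if (stats::sd(x) == 0) stop("covariate '", covariate, "' is constant")
  sp <- study_proportions(records$n, records$events)
  fit <- metafor::rma(yi = sp$p, vi = sp$v, mods = ~x, method = "DL",
                      test = "z")
  null_fit <- metafor::rma(yi = sp$p, vi = sp$v, method = "DL")
  r2 <- if (null_fit$tau2 > 0) {
    min(1, max(0, (null_fit$tau2 - fit$tau2) / null_fit$tau2))
  } else {
    0
  }
  structure(list(intercept = unname(fit$beta[1]),
                 slope = unname(fit$beta[2]),
                 slope_se = unname(fit$se[2]),
                 p_slope = unname(fit$pval[2]),
                 r2 = r2, tau2 = fit$tau2, k = fit$k),
            class = "meta_regression")
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf("meta-regression (k = %d): slope %.4g (se %.4g), p = %.3g, R2 = %.3f\n",
              x$k, x$slope, x$slope_se, x$p_slope, x$r2))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sided t-test, used to compare expected utilities
#' (e.g. per-trial mean QALYs) between the two arms.
#'
#' @param sample_a,sample_b numeric vectors with at least 2 values each.
#' @return list with `t`, `p`, `df`, and the two sample means.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(sample_a), mean_b = mean(sample_b))
}
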