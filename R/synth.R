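#' Specification for a synthetic study corpus
#'
#' Describes a literature evidence base with the statistical structure of the
#' 57-publication corpus behind the pooled defaults: per-treatment study
#' counts, study sizes spanning the real corpus's range, per-outcome true
#' event rates (defaulting to the pooled table means), truncated-normal
#' follow-up durations and demographic distributions, and optional
#' logit-scale covariate effects on the event rates so meta-regressions can
#' be exercised against known truth.
#'
#' @param n_studies named integer vector: studies per treatment (default
#'   17 MVD, 40 SRS — the real corpus's split, with the three dual-arm
#'   publications counted on the SRS side).
#' @param size_range study-size range for the uniform size draw (15-500,
#'   spanning the real corpus's extremes aside from two registry-scale
#'   outliers).
#' @param true_rates list (by treatment) of named true outcome proportions;
#'   defaults to the pooled table means for `BNI_I` ... `retreat`.
#' @param follow_up list (by treatment) of `c(mean, sd)` follow-up months,
#'   truncated below at `follow_up_min`.
#' @param follow_up_min truncation bound in months (6).
#' @param demographics list (by treatment) of `mean_age = c(mean, sd)`,
#'   `pct_female = c(mean, sd)` and `pct_prior = c(mean, sd)` (proportions).
#' @param slopes named numeric vector of logit-scale effects per 1-SD change
#'   of a covariate (`follow_up_months`, `mean_age`, `pct_female`,
#'   `pct_prior`); applied to every outcome's rate, then clipped to \[0, 1\].
#'   Default all zero.
#' @param seed integer seed.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_studies = c(MVD = 17L, SRS = 40L),
                        size_range = c(15L, 500L),
                        true_rates = default_true_rates(),
                        follow_up = list(MVD = c(43.2, 27.6),
                                         SRS = c(31.7, 19.2)),
                        follow_up_min = 6,
                        demographics = default_demographics(),
                        slopes = c(follow_up_months = 0, mean_age = 0,
                                   pct_female = 0, pct_prior = 0),
                        seed = 1L) {
  stopifnot(setequal(names(n_studies), c("MVD", "SRS")), all(n_studies >= 1),
            length(size_range) == 2L, size_range[1L] > 0,
            size_range[2L] >= size_range[1L],
            follow_up_min > 0)
  for (tr in c("MVD", "SRS")) {
    r <- unlist(true_rates[[tr]])
    if (any(r < 0 | r > 1)) stop("true rates must lie in [0, 1]")
  }
  structure(list(n_studies = n_studies[c("MVD", "SRS")],
                 size_range = size_range,
                 true_rates = true_rates, follow_up = follow_up,
                 follow_up_min = follow_up_min, demographics = demographics,
                 slopes = slopes, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' @rdname corpus_spec
#' @export
default_true_rates <- function() {
  list(
    MVD = c(BNI_I = 0.528, BNI_II = 0.262, BNI_III = 0.133, BNI_IV_V = 0.077,
            complication = 0.176, recurrence = 0.159, retreat = 0.080),
    SRS = c(BNI_I = 0.388, BNI_II = 0.209, BNI_III = 0.255, BNI_IV_V = 0.148,
            complication = 0.193, recurrence = 0.226, retreat = 0.455))
}

#' @rdname corpus_spec
#' @export
default_demographics <- function() {
  list(
    MVD = list(mean_age = c(57.5, 3.3), pct_female = c(0.627, 0.080),
               pct_prior = c(0.149, 0.108)),
    SRS = list(mean_age = c(67.6, 4.5), pct_female = c(0.609, 0.080),
               pct_prior = c(0.211, 0.104)))
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Generate a synthetic study corpus
#'
#' Draws, for each study: a size uniform over the spec's range; follow-up and
#' demographics from the spec's (truncated-normal) distributions; then, for
#' every outcome in the spec's rate table, a binomial event count at the true
#' rate adjusted on the logit scale by the covariate slopes applied to the
#' study's standardized covariates.  Adjusted rates falling outside \[0, 1\]
#' after back-transformation are clipped with a warning; boundary true rates
#' (0 or 1) pass through unadjusted.  Reproducible from `spec$seed`.
#'
#' @param spec a [corpus_spec()].
#' @return a [study_records()] data.frame, one row per (study, outcome).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  out <- list()
  for (tr in c("MVD", "SRS")) {
    k <- spec$n_studies[[tr]]
    n <- sample(seq(spec$size_range[1L], spec$size_range[2L]), k,
                replace = TRUE)
    fu <- rnorm_trunc(k, spec$follow_up[[tr]][1L], spec$follow_up[[tr]][2L],
                      lower = spec$follow_up_min)
    dg <- spec$demographics[[tr]]
    age <- stats::rnorm(k, dg$mean_age[1L], dg$mean_age[2L])
    fem <- rnorm_trunc(k, dg$pct_female[1L], dg$pct_female[2L], 0, 1)
    prior <- rnorm_trunc(k, dg$pct_prior[1L], dg$pct_prior[2L], 0, 1)
    z <- cbind(
      follow_up_months = (fu - spec$follow_up[[tr]][1L]) / spec$follow_up[[tr]][2L],
      mean_age = (age - dg$mean_age[1L]) / dg$mean_age[2L],
      pct_female = (fem - dg$pct_female[1L]) / dg$pct_female[2L],
      pct_prior = (prior - dg$pct_prior[1L]) / dg$pct_prior[2L])
    shift <- as.numeric(z[, names(spec$slopes), drop = FALSE] %*% spec$slopes)
    for (outcome in names(spec$true_rates[[tr]])) {
      rate <- spec$true_rates[[tr]][[outcome]]
      p <- if (rate <= 0 || rate >= 1) {
        rep(rate, k)
      } else {
        stats::plogis(stats::qlogis(rate) + shift)
      }
      if (any(p < 0 | p > 1)) {
        warning("adjusted rate clipped to [0, 1] for outcome ", outcome)
        p <- pmin(pmax(p, 0), 1)
      }
      events <- stats::rbinom(k, n, p)
      out[[length(out) + 1L]] <- study_records(
        study_id = sprintf("%s_%02d", tr, seq_len(k)),
        treatment = tr, outcome = outcome, n = n, events = events,
        follow_up_months = fu, mean_age = age, pct_female = fem,
        pct_prior = prior)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("study_records", "data.frame")
  rownames(res) <- NULL
  res
}

#' End-to-end fixture: synthetic corpus and the parameters pooled from it
#'
#' Generates a corpus, pools every outcome per treatment by
#' [pool_proportion()] (pooled standard errors become the estimates' sds),
#' and assembles [treatment_params()] for both arms ready for
#' [expected_qalys()] or [run_two_level_psa()] — exercising the full
#' corpus -> meta-analysis -> decision-model pipeline.  Components the corpus
#' does not inform (utilities, itemized complication profile, medication
#' model, timing) come from the packaged defaults.
#'
#' @param spec a [corpus_spec()]; its rate table must cover `BNI_I` ...
#'   `retreat` for both arms.
#' @return list with `corpus` and `params` (named list `MVD`, `SRS`; each
#'   with a `pooled` attribute holding the per-outcome [pool_proportion()]
#'   results).
#' @export
end_to_end_fixture <- function(spec = corpus_spec()) {
  need <- c("BNI_I", "BNI_II", "BNI_III", "BNI_IV_V", "complication",
            "recurrence", "retreat")
  for (tr in c("MVD", "SRS")) {
    miss <- setdiff(need, names(spec$true_rates[[tr]]))
    if (length(miss)) {
      stop("corpus spec missing outcome(s) for ", tr, ": ",
           paste(miss, collapse = ", "))
    }
  }
  corpus <- generate_corpus(spec)
  params <- lapply(c(MVD = "MVD", SRS = "SRS"), function(tr) {
    pooled <- lapply(need, function(oc) {
      pool_proportion(corpus[corpus$treatment == tr & corpus$outcome == oc, ])
    })
    names(pooled) <- need
    est <- function(oc, label) {
      prob_estimate(pooled[[oc]]$mean, pooled[[oc]]$se, label)
    }
    defaults <- default_parameters(tr)
    # pooled BNI means deviate from 1 by sampling noise; renormalization is
    # expected here, so the deviation warning is suppressed
    p <- suppressWarnings(treatment_params(
      treatment = tr,
      bni_dist = list(I = est("BNI_I", "BNI I"), II = est("BNI_II", "BNI II"),
                      III = est("BNI_III", "BNI III"),
                      IV_V = est("BNI_IV_V", "BNI IV-V")),
      complication_rate = est("complication", "complications"),
      recurrence_rate_7y = est("recurrence", "7-year recurrence"),
      retreat_fraction = est("retreat", "recurrences re-treated"),
      complications = defaults$complications,
      bni_utility = defaults$bni_utility,
      medication = defaults$medication,
      response_delay_months = defaults$response_delay_months,
      retreat_delay_months = defaults$retreat_delay_months,
      complication_onset_months = defaults$complication_onset_months,
      retreat_modality_mix = defaults$retreat_modality_mix))
    attr(p, "pooled") <- pooled
    p
  })
  list(corpus = corpus, params = params)
}
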