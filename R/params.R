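#' @keywords internal
"_PACKAGE"

#' Barrow Neurological Institute pain levels used by the model
#'
#' The model works on four pain states: BNI I (no pain, no medication),
#' BNI II (occasional pain, no medication), BNI III (pain controlled with
#' medication) and the merged BNI IV-V state (pain inadequately controlled or
#' unrelieved).  Levels III and IV-V imply maintenance medication.
#'
#' @format Character vector of the four level codes.
#' @export
BNI_LEVELS <- c("I", "II", "III", "IV_V")

#' Does a BNI level imply maintenance medication?
#'
#' @param level character vector of BNI level codes (see [BNI_LEVELS]).
#' @return logical vector; `TRUE` for levels III and IV_V.
#' @export
bni_medicated <- function(level) {
  stopifnot(all(level %in% BNI_LEVELS))
  level %in% c("III", "IV_V")
}

#' Probability estimate with uncertainty
#'
#' A pooled probability as a proportion in \[0, 1\] with its standard
#' deviation, the unit every chance-node input and every beta-distributed
#' PSA parameter is stored in.  Printed-percent table values are divided by
#' 100 exactly once, at the I/O boundary.
#'
#' @param mean proportion in \[0, 1\].
#' @param sd nonnegative standard deviation (0 for point estimates).
#' @param label short description.
#' @return object of class `tn_estimate`.
#' @export
prob_estimate <- function(mean, sd = 0, label = "") {
  new_estimate(mean, sd, label, kind = "probability")
}

#' Utility estimate with uncertainty
#'
#' A health-state preference weight on the 0 (death) to 1 (perfect health)
#' scale.  Utilities whose dispersion the source tables do not report carry
#' `sd = 0` and behave as point masses in the probabilistic sensitivity
#' analysis.
#'
#' @inheritParams prob_estimate
#' @param source citation text for the utility value.
#' @return object of class `tn_estimate`.
#' @export
utility_estimate <- function(mean, sd = 0, source = "") {
  new_estimate(mean, sd, source, kind = "utility")
}

new_estimate <- function(mean, sd, label, kind) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (mean < 0 || mean > 1) {
    stop(sprintf("%s '%s': mean %.4g outside [0, 1]", kind, label, mean))
  }
  if (sd < 0) stop(sprintf("%s '%s': negative sd", kind, label))
  structure(list(mean = mean, sd = sd, label = label, kind = kind),
            class = "tn_estimate")
}

#' @export
print.tn_estimate <- function(x, ...) {
  cat(sprintf("<%s> %s: %.4g (sd %.4g)\n", x$kind, x$label, x$mean, x$sd))
  invisible(x)
}

#' Check that an estimate admits a beta distribution
#'
#' A beta distribution with the given mean exists only when
#' `sd^2 < mean * (1 - mean)`.  Estimates with `sd = 0` are degenerate point
#' masses and always feasible.
#'
#' @param est a [prob_estimate()] or [utility_estimate()].
#' @return `TRUE` invisibly, or an error naming the estimate.
#' @export
assert_beta_feasible <- function(est) {
  stopifnot(inherits(est, "tn_estimate"))
  if (est$sd > 0 && est$sd^2 >= est$mean * (1 - est$mean)) {
    stop(sprintf(
      "estimate '%s': sd^2 = %.4g exceeds beta-feasible bound mean*(1-mean) = %.4g",
      est$label, est$sd^2, est$mean * (1 - est$mean)))
  }
  invisible(TRUE)
}

#' Complication catalogue entry
#'
#' One periprocedural complication: its incidence among treated patients and
#' the utility multiplier it imposes.  `compound_with` lists other
#' complications whose utilities multiply into this one; in the default
#' parameter set only corneal keratitis compounds (with facial numbness and
#' facial palsy), reflecting the assumption that keratitis patients also carry
#' trigeminal and facial nerve deficits.
#'
#' @param name complication name.
#' @param incidence a [prob_estimate()].
#' @param utility a [utility_estimate()].
#' @param compound_with character vector of other complication names.
#' @return object of class `complication_entry`.
#' @export
complication_entry <- function(name, incidence, utility,
                               compound_with = character()) {
  stopifnot(is.character(name), inherits(incidence, "tn_estimate"),
            inherits(utility, "tn_estimate"), is.character(compound_with))
  structure(list(name = name, incidence = incidence, utility = utility,
                 compound_with = compound_with),
            class = "complication_entry")
}

#' Three-severity medication side-effect model
#'
#' Maintenance anticonvulsant therapy carries side-effect risk.  The model
#' distributes medicated patients over three severity categories (none,
#' mild-moderate, severe), each with its own utility.  Category probabilities
#' are renormalized to sum to one (the source table prints values summing to
#' 1.001); the pre-normalization sum is kept as attribute `raw_sum`.
#'
#' @param probs named list of three [prob_estimate()]s
#'   (`none`, `mild_moderate`, `severe`).
#' @param utilities named list of three [utility_estimate()]s, same names.
#' @return object of class `medication_model`.
#' @export
medication_model <- function(probs, utilities) {
  cats <- c("none", "mild_moderate", "severe")
  stopifnot(setequal(names(probs), cats), setequal(names(utilities), cats))
  probs <- probs[cats]
  utilities <- utilities[cats]
  raw_sum <- sum(vapply(probs, `[[`, 0, "mean"))
  if (raw_sum <= 0) stop("medication category probabilities sum to zero")
  probs <- lapply(probs, function(p) {
    prob_estimate(p$mean / raw_sum, p$sd, p$label)
  })
  structure(list(probs = probs, utilities = utilities, raw_sum = raw_sum),
            class = "medication_model")
}

#' Default medication side-effect model
#'
#' Probabilities and utilities of no / mild-moderate / severe medication
#' side effects, as used to value the medicated BNI III and IV-V states.
#'
#' @return a [medication_model()].
#' @export
default_medication_model <- function() {
  medication_model(
    probs = list(
      none          = prob_estimate(0.176, 0.092, "no medication complications"),
      mild_moderate = prob_estimate(0.514, 0.144, "mild-moderate medication complications"),
      severe        = prob_estimate(0.311, 0.126, "severe medication complications")),
    utilities = list(
      none          = utility_estimate(0.940, 0.010, "Spatz 2007"),
      mild_moderate = utility_estimate(0.912, 0.037, "Spatz 2007"),
      severe        = utility_estimate(0.774, 0.148, "Spatz 2007")))
}

#' Utility catalogue for periprocedural complications
#'
#' All complication utilities known to the model, including three entries
#' (acute subdural hematoma, diplopia, stroke) that carry no incidence in the
#' default MVD/SRS profiles and participate only if a user supplies one.
#' Utilities reported without dispersion (CSF leak, corneal keratitis,
#' stroke) have `sd = 0`.
#'
#' @return data.frame with columns `name`, `mean`, `sd`, `source`.
#' @export
complication_utility_catalogue <- function() {
  data.frame(
    name = c("no_complications", "csf_leak", "facial_palsy",
             "corneal_keratitis", "facial_numbness", "meningitis",
             "unilateral_deafness", "acute_subdural_hematoma", "diplopia",
             "stroke", "perioperative_death"),
    mean = c(1.0, 0.985, 0.983, 0.963, 0.960, 0.930, 0.929, 0.868, 0.762,
             0.5, 0),
    sd = c(0, 0, 0.018, 0, 0.014, 0.030, 0.110, 0.017, 0.104, 0, 0),
    source = c("Hunink 2001", "estimate", "Whitmore 2011", "van de Graaf 2010",
               "Whitmore 2011", "Whitmore 2011", "Whitmore 2011", "Lega 2010",
               "Hatt 2010", "Samsa 1999", "Hunink 2001"),
    stringsAsFactors = FALSE)
}

catalogue_utility <- function(name) {
  cat <- complication_utility_catalogue()
  row <- cat[cat$name == name, ]
  if (nrow(row) != 1L) stop("unknown complication utility: ", name)
  utility_estimate(row$mean, row$sd, row$source)
}

#' Default itemized complication profiles
#'
#' Pooled incidences of the complications retained for each procedure,
#' paired with utilities from [complication_utility_catalogue()].  Residual
#' "other" categories have no utility of their own in the catalogue and carry
#' utility 1 unless `other_utility` overrides it.  For SRS, corneal keratitis
#' compounds with facial numbness and facial palsy.
#'
#' @param treatment `"MVD"` or `"SRS"`.
#' @param other_utility utility multiplier for the residual category
#'   (default 1).
#' @return list of [complication_entry()]s.
#' @export
default_complications <- function(treatment = c("MVD", "SRS"),
                                  other_utility = 1.0) {
  treatment <- match.arg(treatment)
  other <- utility_estimate(other_utility, 0, "residual category (model choice)")
  if (treatment == "MVD") {
    list(
      complication_entry("facial_numbness",
                         prob_estimate(0.044, 0.020, "facial_numbness"),
                         catalogue_utility("facial_numbness")),
      complication_entry("facial_palsy",
                         prob_estimate(0.011, 0.017, "facial_palsy"),
                         catalogue_utility("facial_palsy")),
      complication_entry("perioperative_death",
                         prob_estimate(0.002, 0.001, "perioperative_death"),
                         catalogue_utility("perioperative_death")),
      complication_entry("deafness",
                         prob_estimate(0.018, 0.030, "deafness"),
                         catalogue_utility("unilateral_deafness")),
      complication_entry("csf_leak",
                         prob_estimate(0.013, 0.021, "csf_leak"),
                         catalogue_utility("csf_leak")),
      complication_entry("meningitis_wound_infection",
                         prob_estimate(0.012, 0.016, "meningitis_wound_infection"),
                         catalogue_utility("meningitis")),
      complication_entry("other_complications",
                         prob_estimate(0.033, 0.005, "other_complications"),
                         other))
  } else {
    list(
      complication_entry("facial_numbness",
                         prob_estimate(0.141, 0.053, "facial_numbness"),
                         catalogue_utility("facial_numbness")),
      complication_entry("facial_palsy",
                         prob_estimate(0.017, 0.013, "facial_palsy"),
                         catalogue_utility("facial_palsy")),
      complication_entry("corneal_keratitis",
                         prob_estimate(0.015, 0.009, "corneal_keratitis"),
                         catalogue_utility("corneal_keratitis"),
                         compound_with = c("facial_numbness", "facial_palsy")),
      complication_entry("hypertension_other",
                         prob_estimate(0.020, 0.019, "hypertension_other"),
                         other))
  }
}

#' Default BNI state utilities
#'
#' Utility weights of the four pain states.  BNI I is anchored at 1.0 with no
#' uncertainty; the model values relative, not absolute, quality of life.
#'
#' @return named list of [utility_estimate()]s over [BNI_LEVELS].
#' @export
default_bni_utilities <- function() {
  list(
    I    = utility_estimate(1.0,   0,     "Hunink 2001"),
    II   = utility_estimate(0.871, 0.213, "Perez 2009"),
    III  = utility_estimate(0.739, 0.221, "Perez 2009; Spatz 2007"),
    IV_V = utility_estimate(0.399, 0.189, "Perez 2009"))
}

#' Full parameter set for one treatment arm
#'
#' Bundles everything that defines an arm of the comparison: the distribution
#' of post-treatment BNI pain states, the pooled complication rate, the
#' seven-year recurrence rate, the fraction of recurrences re-treated, the
#' itemized complication profile, the BNI state utilities, the medication
#' side-effect model, the event-timing constants and the re-treatment
#' modality mix.  BNI distribution means are renormalized to sum to one (with
#' a warning when they deviate by more than `1e-6`).
#'
#' @param treatment `"MVD"` or `"SRS"`.
#' @param bni_dist named list of [prob_estimate()]s over [BNI_LEVELS].
#' @param complication_rate,recurrence_rate_7y,retreat_fraction
#'   [prob_estimate()]s.
#' @param complications list of [complication_entry()]s.
#' @param bni_utility named list of [utility_estimate()]s over [BNI_LEVELS].
#' @param medication a [medication_model()].
#' @param response_delay_months months from procedure to the post-treatment
#'   BNI state taking effect (0 MVD, 1 SRS).
#' @param retreat_delay_months months from procedure to re-treatment of an
#'   initial failure (1 MVD, 3 SRS).
#' @param complication_onset_months months from procedure to complication
#'   onset (0 MVD, 6 SRS); complications are permanent thereafter.
#' @param retreat_modality_mix named numeric (`MVD`, `SRS`) summing to 1:
#'   which procedure a re-treatment uses.
#' @return object of class `treatment_params`.
#' @export
treatment_params <- function(treatment,
                             bni_dist,
                             complication_rate,
                             recurrence_rate_7y,
                             retreat_fraction,
                             complications,
                             bni_utility = default_bni_utilities(),
                             medication = default_medication_model(),
                             response_delay_months,
                             retreat_delay_months,
                             complication_onset_months,
                             retreat_modality_mix) {
  treatment <- match.arg(treatment, c("MVD", "SRS"))
  stopifnot(setequal(names(bni_dist), BNI_LEVELS),
            setequal(names(bni_utility), BNI_LEVELS),
            inherits(complication_rate, "tn_estimate"),
            inherits(recurrence_rate_7y, "tn_estimate"),
            inherits(retreat_fraction, "tn_estimate"),
            inherits(medication, "medication_model"),
            is.numeric(response_delay_months), response_delay_months >= 0,
            is.numeric(retreat_delay_months), retreat_delay_months >= 0,
            is.numeric(complication_onset_months), complication_onset_months >= 0)
  stopifnot(setequal(names(retreat_modality_mix), c("MVD", "SRS")),
            all(retreat_modality_mix >= 0))
  mix_sum <- sum(retreat_modality_mix)
  if (abs(mix_sum - 1) > 1e-9) {
    stop("retreat_modality_mix must sum to 1 (got ", mix_sum, ")")
  }
  bni_dist <- bni_dist[BNI_LEVELS]
  bni_utility <- bni_utility[BNI_LEVELS]
  s <- sum(vapply(bni_dist, `[[`, 0, "mean"))
  if (s <= 0) stop("BNI distribution means sum to zero")
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("BNI distribution means sum to %.4g; renormalizing", s))
  }
  if (abs(s - 1) > .Machine$double.eps) {
    bni_dist <- lapply(bni_dist, function(p) {
      prob_estimate(p$mean / s, p$sd, p$label)
    })
  }
  for (e in complications) stopifnot(inherits(e, "complication_entry"))
  structure(list(
    treatment = treatment,
    bni_dist = bni_dist,
    complication_rate = complication_rate,
    recurrence_rate_7y = recurrence_rate_7y,
    retreat_fraction = retreat_fraction,
    complications = complications,
    bni_utility = bni_utility,
    medication = medication,
    response_delay_months = response_delay_months,
    retreat_delay_months = retreat_delay_months,
    complication_onset_months = complication_onset_months,
    retreat_modality_mix = retreat_modality_mix[c("MVD", "SRS")]),
    class = "treatment_params")
}

#' Packaged default parameters for one treatment arm
#'
#' The pooled outcome probabilities, recurrence/re-treatment rates,
#' complication profiles, state utilities and timing constants that define
#' the base-case MVD and SRS arms.  Probabilities printed as percent in the
#' source tables are stored here as proportions.
#'
#' Note one transcription flag: the MVD BNI IV-V standard deviation (0.67 on
#' the percent scale, hence 0.0067 as a proportion) is anomalously small next
#' to its neighbours but is carried verbatim.
#'
#' @param treatment `"MVD"` or `"SRS"`.
#' @param other_utility passed to [default_complications()].
#' @return a [treatment_params()].
#' @examples
#' p <- default_parameters("MVD")
#' p$bni_dist$I$mean          # 0.528
#' p$retreat_fraction$mean    # 0.08
#' @export
default_parameters <- function(treatment = c("MVD", "SRS"),
                               other_utility = 1.0) {
  treatment <- match.arg(treatment)
  if (treatment == "MVD") {
    treatment_params(
      treatment = "MVD",
      bni_dist = list(
        I    = prob_estimate(0.528, 0.213, "BNI I"),
        II   = prob_estimate(0.262, 0.245, "BNI II"),
        III  = prob_estimate(0.133, 0.051, "BNI III"),
        IV_V = prob_estimate(0.077, 0.0067, "BNI IV-V")),
      complication_rate = prob_estimate(0.176, 0.005, "complications"),
      recurrence_rate_7y = prob_estimate(0.159, 0.105, "7-year recurrence"),
      retreat_fraction = prob_estimate(0.080, 0.069, "recurrences re-treated"),
      complications = default_complications("MVD", other_utility),
      response_delay_months = 0,
      retreat_delay_months = 1,
      complication_onset_months = 0,
      retreat_modality_mix = c(MVD = 0.8, SRS = 0.2))
  } else {
    treatment_params(
      treatment = "SRS",
      bni_dist = list(
        I    = prob_estimate(0.388, 0.175, "BNI I"),
        II   = prob_estimate(0.209, 0.108, "BNI II"),
        III  = prob_estimate(0.255, 0.127, "BNI III"),
        IV_V = prob_estimate(0.148, 0.064, "BNI IV-V")),
      complication_rate = prob_estimate(0.193, 0.007, "complications"),
      recurrence_rate_7y = prob_estimate(0.226, 0.134, "7-year recurrence"),
      retreat_fraction = prob_estimate(0.455, 0.355, "recurrences re-treated"),
      complications = default_complications("SRS", other_utility),
      response_delay_months = 1,
      retreat_delay_months = 3,
      complication_onset_months = 6,
      retreat_modality_mix = c(MVD = 1.0, SRS = 0.0))
  }
}

#' Model configuration
#'
#' Structural settings of the QALY model and the probabilistic sensitivity
#' analysis.
#'
#' @param horizon_years follow-up horizon in years (base case 7; a 1-year
#'   horizon reproduces the short-term comparison, where recurrence at 2.5
#'   years cannot occur).
#' @param recurrence_time_years years after a procedure at which all
#'   recurrences are assumed to occur (2.5).
#' @param max_additional_procedures cap on re-treatments beyond the primary
#'   procedure (2).
#' @param retreat_utility_multiplier utility multiplier applied per
#'   additional procedure, compounding with depth (0.915).
#' @param post_recurrence_untreated_level BNI state of recurrences not
#'   re-treated (III, medicated).
#' @param post_recurrence_pre_treatment_level BNI state while awaiting /
#'   responding to a (re-)treatment (IV_V, medicated).
#' @param psa_outer,psa_inner outer parameter draws and inner patient
#'   microsimulations per draw (100 x 100).
#' @param seed integer master seed for all randomness.
#' @return object of class `model_config`.
#' @export
model_config <- function(horizon_years = 7,
                         recurrence_time_years = 2.5,
                         max_additional_procedures = 2,
                         retreat_utility_multiplier = 0.915,
                         post_recurrence_untreated_level = "III",
                         post_recurrence_pre_treatment_level = "IV_V",
                         psa_outer = 100,
                         psa_inner = 100,
                         seed = 1L) {
  stopifnot(horizon_years >= 0,
            recurrence_time_years > 0,
            max_additional_procedures >= 0,
            retreat_utility_multiplier >= 0, retreat_utility_multiplier <= 1,
            post_recurrence_untreated_level %in% BNI_LEVELS,
            post_recurrence_pre_treatment_level %in% BNI_LEVELS,
            psa_outer >= 1, psa_inner >= 1)
  structure(list(
    horizon_years = horizon_years,
    recurrence_time_years = recurrence_time_years,
    max_additional_procedures = as.integer(max_additional_procedures),
    retreat_utility_multiplier = retreat_utility_multiplier,
    post_recurrence_untreated_level = post_recurrence_untreated_level,
    post_recurrence_pre_treatment_level = post_recurrence_pre_treatment_level,
    psa_outer = as.integer(psa_outer),
    psa_inner = as.integer(psa_inner),
    seed = as.integer(seed)),
    class = "model_config")
}
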