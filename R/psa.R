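#' Fit a beta distribution by the method of moments
#'
#' Given a mean and standard deviation on \[0, 1\], solves
#' `nu = mean (1 - mean) / sd^2 - 1`, `alpha = mean nu`,
#' `beta = (1 - mean) nu`.  An `sd` of zero (or a mean at the boundary)
#' yields a degenerate point mass.  An infeasible `sd`
#' (`sd^2 >= mean (1 - mean)`) is clipped to 95% of the feasible bound with
#' a warning, or rejected when `on_infeasible = "error"`.
#'
#' @param mean mean in \[0, 1\].
#' @param sd nonnegative standard deviation.
#' @param on_infeasible `"clip"` (default) or `"error"`.
#' @return object of class `beta_spec`: `alpha`, `beta`, `degenerate`,
#'   `mean`, `sd` (the possibly clipped sd actually fitted).
#' @examples
#' fit_beta(0.5, sqrt(1 / 12))  # alpha = beta = 1, the uniform
#' @export
fit_beta <- function(mean, sd, on_infeasible = c("clip", "error")) {
  on_infeasible <- match.arg(on_infeasible)
  stopifnot(mean >= 0, mean <= 1, sd >= 0)
  if (sd == 0 || mean == 0 || mean == 1) {
    return(structure(list(alpha = NA_real_, beta = NA_real_, degenerate = TRUE,
                          mean = mean, sd = 0), class = "beta_spec"))
  }
  bound <- mean * (1 - mean)
  if (sd^2 >= bound) {
    if (on_infeasible == "error") {
      stop(sprintf("sd %.4g infeasible for beta with mean %.4g (bound %.4g)",
                   sd, mean, sqrt(bound)))
    }
    warning(sprintf("sd %.4g clipped to beta-feasible bound for mean %.4g",
                    sd, mean))
    sd <- 0.95 * sqrt(bound)
  }
  nu <- bound / sd^2 - 1
  structure(list(alpha = mean * nu, beta = (1 - mean) * nu, degenerate = FALSE,
                 mean = mean, sd = sd), class = "beta_spec")
}

#' Draw from a fitted beta specification
#'
#' @param spec a [fit_beta()] result.
#' @param n number of draws.
#' @return numeric vector; the mean itself, repeated, for degenerate specs.
#' @export
draw_beta <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "beta_spec"))
  if (spec$degenerate) return(rep(spec$mean, n))
  stats::rbeta(n, spec$alpha, spec$beta)
}

draw_estimate <- function(est) {
  draw_beta(fit_beta(est$mean, est$sd), 1L)
}

point_estimate <- function(est, value) {
  est$mean <- value
  est$sd <- 0
  est
}

#' Draw one point-parameter set from a treatment arm's uncertainty
#'
#' Replaces every probability and utility in the arm by one independent beta
#' draw (method-of-moments fit to the stored mean and sd; zero-sd estimates
#' stay fixed): the four BNI state probabilities (renormalized to sum to one
#' after drawing), the complication rate, the recurrence and re-treatment
#' rates, every itemized complication incidence and utility, the BNI state
#' utilities, and the three medication categories' probabilities and
#' utilities.  Timing constants and the modality mix are structural and not
#' drawn.
#'
#' @param params a [treatment_params()].
#' @return a [treatment_params()] whose estimates all have `sd = 0`.
#' @export
draw_parameter_set <- function(params) {
  stopifnot(inherits(params, "treatment_params"))
  p <- params
  bni_draw <- vapply(p$bni_dist, draw_estimate, 0)
  bni_draw <- bni_draw / sum(bni_draw)
  for (lvl in BNI_LEVELS) {
    p$bni_dist[[lvl]] <- point_estimate(p$bni_dist[[lvl]], bni_draw[[lvl]])
    p$bni_utility[[lvl]] <- point_estimate(p$bni_utility[[lvl]],
                                           draw_estimate(p$bni_utility[[lvl]]))
  }
  p$complication_rate <- point_estimate(p$complication_rate,
                                        draw_estimate(p$complication_rate))
  p$recurrence_rate_7y <- point_estimate(p$recurrence_rate_7y,
                                         draw_estimate(p$recurrence_rate_7y))
  p$retreat_fraction <- point_estimate(p$retreat_fraction,
                                       draw_estimate(p$retreat_fraction))
  p$complications <- lapply(p$complications, function(e) {
    e$incidence <- point_estimate(e$incidence, draw_estimate(e$incidence))
    e$utility <- point_estimate(e$utility, draw_estimate(e$utility))
    e
  })
  for (cat in names(p$medication$probs)) {
    p$medication$probs[[cat]] <-
      point_estimate(p$medication$probs[[cat]],
                     draw_estimate(p$medication$probs[[cat]]))
    p$medication$utilities[[cat]] <-
      point_estimate(p$medication$utilities[[cat]],
                     draw_estimate(p$medication$utilities[[cat]]))
  }
  psum <- sum(vapply(p$medication$probs, `[[`, 0, "mean"))
  for (cat in names(p$medication$probs)) {
    p$medication$probs[[cat]]$mean <- p$medication$probs[[cat]]$mean / psum
  }
  p
}

#' Simulate one patient through an assembled tree
#'
#' Walks the tree from the root by sequential categorical draws, one per
#' chance node, and returns the terminal payoff (the sampled path's timeline
#' QALYs).  `simulate_patients` repeats the walk `n` times.
#'
#' @param tree a `tn_node` from [build_treatment_tree()].
#' @return `simulate_patient`: one QALY value; `simulate_patients`: a numeric
#'   vector of length `n`.
#' @export
simulate_patient <- function(tree) {
  node <- tree
  while (!is_terminal(node)) {
    cp <- cumsum(node$probs) / sum(node$probs)
    i <- findInterval(stats::runif(1L), cp) + 1L
    node <- node$children[[i]]
  }
  node$payoff
}

#' @rdname simulate_patient
#' @param n number of patients.
#' @export
simulate_patients <- function(tree, n) {
  vapply(seq_len(n), function(i) simulate_patient(tree), 0)
}

#' Two-dimensional Monte Carlo probabilistic sensitivity analysis
#'
#' Outer loop: one beta draw of every probability and utility in each arm
#' (see [draw_parameter_set()]); inner loop: `n_inner` patient
#' microsimulations through the tree assembled from that draw.  Each outer
#' trial records the mean QALYs of its simulated patients; the two arms'
#' trial means are compared by a Welch t-test.  All randomness derives from
#' `config$seed` through per-trial substreams, so a given seed reproduces the
#' result bitwise regardless of how trials might be scheduled.
#'
#' @param params_mvd,params_srs [treatment_params()] for the two arms.
#' @param config a [model_config()]; `psa_outer`, `psa_inner` and `seed` are
#'   used here.
#' @return object of class `psa_result`: per-arm trial means, grand means,
#'   across-trial SDs, Welch `t` and `p`, and the simulation sizes.
#' @export
run_two_level_psa <- function(params_mvd = default_parameters("MVD"),
                              params_srs = default_parameters("SRS"),
                              config = model_config()) {
  stopifnot(config$psa_outer >= 2L, config$psa_inner >= 2L)
  set.seed(config$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, config$psa_outer)
  one_trial <- function(seed) {
    set.seed(seed)
    d_mvd <- draw_parameter_set(params_mvd)
    d_srs <- draw_parameter_set(params_srs)
    tree_mvd <- build_treatment_tree("MVD", d_mvd, config, other_params = d_srs)
    tree_srs <- build_treatment_tree("SRS", d_srs, config, other_params = d_mvd)
    c(mean(simulate_patients(tree_mvd, config$psa_inner)),
      mean(simulate_patients(tree_srs, config$psa_inner)))
  }
  tm <- vapply(trial_seeds, one_trial, numeric(2L))
  trial_means <- list(MVD = tm[1L, ], SRS = tm[2L, ])
  test <- welch_t_test(trial_means$MVD, trial_means$SRS)
  structure(list(
    trial_means = trial_means,
    grand_mean = c(MVD = mean(trial_means$MVD), SRS = mean(trial_means$SRS)),
    sd = c(MVD = stats::sd(trial_means$MVD), SRS = stats::sd(trial_means$SRS)),
    t = test$t, p = test$p,
    seed = config$seed, n_outer = config$psa_outer,
    n_inner = config$psa_inner, horizon_years = config$horizon_years),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Two-level Monte Carlo PSA (%d trials x %d patients, seed %d)\n",
              x$n_outer, x$n_inner, x$seed))
  cat(sprintf("  MVD: %.3f +/- %.3f QALYs over %g years\n",
              x$grand_mean["MVD"], x$sd["MVD"], x$horizon_years))
  cat(sprintf("  SRS: %.3f +/- %.3f QALYs over %g years\n",
              x$grand_mean["SRS"], x$sd["SRS"], x$horizon_years))
  cat(sprintf("  Welch t = %.2f, p = %.3g\n", x$t, x$p))
  invisible(x)
}
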