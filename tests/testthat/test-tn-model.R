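test_that("complication sub-models reproduce the itemized table aggregates", {
  mvd <- complication_submodel(default_complications("MVD"))
  expect_equal(mvd$total_rate, 0.133)
  expect_equal(mvd$conditional_utility, 0.9529323, tolerance = 1e-6)
  srs <- complication_submodel(default_complications("SRS"))
  expect_equal(srs$total_rate, 0.193)
  expect_equal(srs$conditional_utility, 0.9621889, tolerance = 1e-6)
  # printed rounded values: SRS exactly 0.962; MVD prints 0.958 but direct
  # computation with the residual category at utility 1 gives 0.953
  expect_equal(round(srs$conditional_utility, 3), 0.962)
  expect_lt(abs(mvd$conditional_utility - 0.958), 0.01)
})

test_that("complication sub-model trivial and error cases", {
  single <- complication_submodel(list(
    complication_entry("x", prob_estimate(0.1), utility_estimate(0.9))))
  expect_equal(single$total_rate, 0.1)
  expect_equal(single$conditional_utility, 0.9)
  empty <- complication_submodel(list())
  expect_equal(empty$total_rate, 0)
  expect_equal(empty$conditional_utility, 1.0)
  expect_error(complication_submodel(list(
    complication_entry("a", prob_estimate(0.7), utility_estimate(1)),
    complication_entry("b", prob_estimate(0.5), utility_estimate(1)))),
    "sum to 1.2")
  expect_error(complication_submodel(list(
    complication_entry("a", prob_estimate(0.1), utility_estimate(1),
                       compound_with = "ghost"))),
    "unknown complication")
})

test_that("rollback of the complication sub-tree equals the arithmetic sub-model", {
  for (tr in c("MVD", "SRS")) {
    entries <- default_complications(tr)
    tree <- build_complication_tree(entries)
    expect_equal(rollback(tree),
                 complication_submodel(entries)$conditional_utility,
                 tolerance = 1e-12)
  }
})

test_that("medication sub-model is the renormalized probability-weighted mean", {
  med <- default_medication_model()
  expect_equal(medication_submodel(med), 0.874048, tolerance = 1e-6)
  # by construction: weighted mean of the renormalized categories
  p <- vapply(med$probs, `[[`, 0, "mean")
  u <- vapply(med$utilities, `[[`, 0, "mean")
  expect_equal(medication_submodel(med), sum(p * u), tolerance = 1e-12)
  expect_equal(medication_submodel(med, pinned = 0.881), 0.881)

  flat <- medication_model(
    probs = list(none = prob_estimate(0.2), mild_moderate = prob_estimate(0.5),
                 severe = prob_estimate(0.3)),
    utilities = list(none = utility_estimate(0.8),
                     mild_moderate = utility_estimate(0.8),
                     severe = utility_estimate(0.8)))
  expect_equal(medication_submodel(flat), 0.8)
  no_severe <- medication_model(
    probs = list(none = prob_estimate(0.25), mild_moderate = prob_estimate(0.75),
                 severe = prob_estimate(0)),
    utilities = list(none = utility_estimate(0.9),
                     mild_moderate = utility_estimate(0.7),
                     severe = utility_estimate(0.1)))
  expect_equal(medication_submodel(no_severe), 0.25 * 0.9 + 0.75 * 0.7)
})

test_that("composite state utilities multiply their factors", {
  p <- default_parameters("MVD")
  cfg <- model_config()
  med <- medication_submodel(p$medication)
  expect_equal(state_utility(list(bni = "I"), p, cfg), 1.0)
  expect_equal(state_utility(list(bni = "I", retreat_depth = 1L), p, cfg), 0.915)
  expect_equal(state_utility(list(bni = "III", complication_multiplier = 0.958),
                             p, cfg),
               0.958 * 0.739 * med, tolerance = 1e-12)
  expect_equal(state_utility(list(bni = "IV_V", complication_multiplier = 0.9,
                                  retreat_depth = 2L), p, cfg),
               0.399 * med * 0.9 * 0.915^2, tolerance = 1e-12)
  # BNI II carries no medication multiplier
  expect_equal(state_utility(list(bni = "II"), p, cfg), 0.871)
  expect_error(state_utility(list(bni = "III", retreat_depth = 5L), p, cfg))
})

test_that("timeline QALYs integrate duration times utility", {
  expect_equal(timeline_qaly(patient_timeline(0, 4, 0.25)), 1.0)
  expect_equal(timeline_qaly(patient_timeline(0, 7, 1)), 7.0)
  expect_equal(timeline_qaly(patient_timeline(0, 7, 0)), 0.0)
  two <- patient_timeline(c(0, 2), c(2, 7), c(1, 0.5))
  expect_equal(timeline_qaly(two), 2 + 2.5)
  expect_error(timeline_qaly(patient_timeline(c(0, 3), c(2, 7), c(1, 1))),
               "gaps or overlaps")
  expect_error(timeline_qaly(patient_timeline(c(0, 1), c(2, 7), c(1, 1))),
               "gaps or overlaps")
  expect_error(timeline_qaly(patient_timeline(1, 7, 1)), "start at 0")
  expect_error(timeline_qaly(patient_timeline(0, 7, 1.2)), "outside")
})

perfect_params <- function() {
  p <- default_parameters("MVD")
  p$complication_rate$mean <- 0
  p$recurrence_rate_7y$mean <- 0
  for (lvl in BNI_LEVELS) p$bni_dist[[lvl]]$mean <- as.numeric(lvl == "I")
  p
}

test_that("a certain complication-free cure accrues the full horizon in QALYs", {
  tree <- build_treatment_tree("MVD", perfect_params(), model_config())
  paths <- enumerate_paths(tree)
  support <- paths[paths$prob > 0, ]
  expect_equal(nrow(support), 1L)
  expect_equal(support$payoff, 7.0, tolerance = 1e-12)
  expect_equal(expected_qalys("MVD", perfect_params()), 7.0, tolerance = 1e-12)
})

test_that("a re-treatment cap of zero removes all re-treatment branches", {
  cfg <- model_config(max_additional_procedures = 0)
  tree <- build_treatment_tree("MVD", config = cfg)
  expect_false(any(grepl("retreat", collect_labels(tree))))
})

test_that("default trees conserve probability and match the enumeration oracle", {
  for (tr in c("MVD", "SRS")) {
    tree <- build_treatment_tree(tr)
    paths <- enumerate_paths(tree)
    expect_equal(sum(paths$prob), 1, tolerance = 1e-9)
    expect_lt(abs(sum(paths$prob * paths$payoff) - rollback(tree)), 1e-12)
    expect_true(all(paths$payoff >= 0 & paths$payoff <= 7))
  }
})

test_that("with no recurrence and no re-treatment the rollback has a closed form", {
  p <- default_parameters("MVD")
  p$recurrence_rate_7y$mean <- 0
  cfg <- model_config(max_additional_procedures = 0)
  got <- expected_qalys("MVD", p, cfg)
  cs <- complication_submodel(p$complications)
  med <- medication_submodel(p$medication)
  u <- c(1, 0.871, 0.739 * med, 0.399 * med)
  pb <- vapply(p$bni_dist, `[[`, 0, "mean")
  pc <- p$complication_rate$mean
  want <- 7 * (1 - pc + pc * cs$conditional_utility) * sum(pb * u)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("expected QALYs respect bounds and degenerate horizons", {
  expect_equal(expected_qalys("MVD", config = model_config(horizon_years = 0)), 0)
  for (tr in c("MVD", "SRS")) {
    q <- expected_qalys(tr)
    expect_gte(q, 0); expect_lte(q, 7)
    q1 <- expected_qalys(tr, config = model_config(horizon_years = 1))
    expect_gte(q1, 0); expect_lte(q1, 1)
  }
})

test_that("all utilities at one with no effective complications attain the horizon", {
  p <- default_parameters("MVD")
  for (lvl in BNI_LEVELS) p$bni_utility[[lvl]]$mean <- 1
  for (i in seq_along(p$complications)) p$complications[[i]]$utility$mean <- 1
  for (cat in names(p$medication$utilities)) p$medication$utilities[[cat]]$mean <- 1
  p$recurrence_rate_7y$mean <- 0
  cfg <- model_config(retreat_utility_multiplier = 1)
  # same parameters govern any re-treatment arm
  expect_equal(expected_qalys("MVD", p, cfg, other_params = p), 7,
               tolerance = 1e-12)
})

test_that("one-way sensitivity includes the baseline and responds monotonically", {
  base <- expected_qalys("MVD")
  sens <- one_way_sensitivity("MVD", parameter_id = "complication_rate",
                              values = c(0.05, 0.35, 0.65))
  expect_equal(sens$qalys[sens$baseline], base, tolerance = 1e-12)
  expect_true(all(diff(sens$qalys[order(sens$value)]) < 0))

  up <- one_way_sensitivity("MVD", parameter_id = "bni_utility.III",
                            values = c(0.5, 0.9))
  expect_true(all(diff(up$qalys[order(up$value)]) > 0))

  expect_error(one_way_sensitivity("MVD", parameter_id = "nope", values = 1),
               "unknown parameter id")
  cfg_sens <- one_way_sensitivity("MVD",
                                  parameter_id = "config.retreat_utility_multiplier",
                                  values = c(0.8))
  expect_equal(nrow(cfg_sens), 2L)
})

test_that("the SRS response delay charges the first month at the pre-treatment state", {
  p <- default_parameters("SRS")
  p$complication_rate$mean <- 0
  p$recurrence_rate_7y$mean <- 0
  for (lvl in BNI_LEVELS) p$bni_dist[[lvl]]$mean <- as.numeric(lvl == "I")
  q <- expected_qalys("SRS", p)
  med <- medication_submodel(p$medication)
  expect_equal(q, (1 / 12) * 0.399 * med + (7 - 1 / 12) * 1, tolerance = 1e-12)
})
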