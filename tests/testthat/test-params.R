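test_that("packaged defaults reproduce the pooled table values as proportions", {
  mvd <- default_parameters("MVD")
  srs <- default_parameters("SRS")
  expect_equal(mvd$bni_dist$I$mean, 0.528)
  expect_equal(mvd$bni_dist$IV_V$sd, 0.0067)  # transcribed verbatim
  expect_equal(srs$bni_dist$I$mean, 0.388)
  expect_equal(mvd$recurrence_rate_7y$mean, 0.159)
  expect_equal(srs$recurrence_rate_7y$mean, 0.226)
  expect_equal(mvd$retreat_fraction$mean, 0.080)
  expect_equal(srs$retreat_fraction$mean, 0.455)
  expect_equal(mvd$complication_rate$mean, 0.176)
  expect_equal(srs$complication_rate$mean, 0.193)
  expect_equal(mvd$bni_utility$I$mean, 1.0)
  expect_equal(mvd$bni_utility$I$sd, 0)
  expect_equal(mvd$bni_utility$IV_V$mean, 0.399)
  # itemized incidences sum to the text's totals
  inc <- function(p) sum(vapply(p$complications, function(e) e$incidence$mean, 0))
  expect_equal(inc(mvd), 0.133)
  expect_equal(inc(srs), 0.193)
  # timing constants (months): MVD (0, 1, 0), SRS (1, 3, 6)
  expect_equal(c(mvd$response_delay_months, mvd$retreat_delay_months,
                 mvd$complication_onset_months), c(0, 1, 0))
  expect_equal(c(srs$response_delay_months, srs$retreat_delay_months,
                 srs$complication_onset_months), c(1, 3, 6))
  expect_equal(mvd$retreat_modality_mix, c(MVD = 0.8, SRS = 0.2))
  expect_equal(srs$retreat_modality_mix, c(MVD = 1.0, SRS = 0.0))
})

test_that("medication category probabilities renormalize from the 1.001 sum", {
  med <- default_medication_model()
  expect_equal(med$raw_sum, 1.001)
  expect_equal(sum(vapply(med$probs, `[[`, 0, "mean")), 1, tolerance = 1e-12)
  # relative weights preserved
  expect_equal(med$probs$severe$mean / med$probs$none$mean, 0.311 / 0.176)
})

test_that("BNI distributions that do not sum to one are renormalized with a warning", {
  d <- list(I = prob_estimate(0.5), II = prob_estimate(0.5),
            III = prob_estimate(0.25), IV_V = prob_estimate(0))
  expect_warning(
    p <- treatment_params("MVD", bni_dist = d,
                          complication_rate = prob_estimate(0.1),
                          recurrence_rate_7y = prob_estimate(0.1),
                          retreat_fraction = prob_estimate(0.1),
                          complications = list(),
                          response_delay_months = 0, retreat_delay_months = 1,
                          complication_onset_months = 0,
                          retreat_modality_mix = c(MVD = 1, SRS = 0)),
    "renormalizing")
  expect_equal(vapply(p$bni_dist, `[[`, 0, "mean"),
               c(I = 0.4, II = 0.4, III = 0.2, IV_V = 0))
})

test_that("estimate constructors reject invalid values", {
  expect_error(prob_estimate(1.2), "outside")
  expect_error(prob_estimate(0.5, -0.1), "negative sd")
  expect_error(utility_estimate(-0.01), "outside")
  expect_error(assert_beta_feasible(prob_estimate(0.5, 0.6)), "beta-feasible")
  expect_silent(assert_beta_feasible(prob_estimate(0.5, 0.2)))
  expect_silent(assert_beta_feasible(prob_estimate(0.5, 0)))
})

test_that("the packaged parameter file loads back to the in-code defaults bit-exactly", {
  loaded <- load_parameters(packaged_parameters_path())
  expect_identical(loaded$MVD, default_parameters("MVD"))
  expect_identical(loaded$SRS, default_parameters("SRS"))
})

test_that("write -> load round-trips bit-exactly in CSV and JSON", {
  ps <- list(default_parameters("MVD"), default_parameters("SRS"))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_parameters(ps, path)
    back <- load_parameters(path)
    expect_identical(back$MVD, ps[[1]])
    expect_identical(back$SRS, ps[[2]])
  }
})

test_that("loading flags beta-infeasible dispersions by field name", {
  tab <- params_to_table(default_parameters("MVD"))
  tab$sd[tab$parameter == "bni_prob" & tab$level_or_name == "II"] <- 60
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(load_parameters(path), "bni_prob\\[II\\].*beta-feasibility")
})

test_that("malformed parameter files raise schema errors naming the problem", {
  tab <- params_to_table(default_parameters("MVD"))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[tab$parameter != "recurrence_rate_7y", ], path,
                   row.names = FALSE)
  expect_error(load_parameters(path), "recurrence_rate_7y")
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), path2, row.names = FALSE)
  expect_error(load_parameters(path2), "missing column")
  expect_error(load_parameters(withr::local_tempfile(fileext = ".csv")),
               "no such file")
})

test_that("model configuration round-trips through YAML and rejects unknown fields", {
  cfg <- model_config(horizon_years = 1, psa_outer = 10, seed = 42L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  expect_identical(load_parameters(path, "config"), cfg)
  writeLines("horizon_years: 7\nnot_a_field: 3", path)
  expect_error(load_parameters(path, "config"), "not_a_field")
})

test_that("the medication schema loads a standalone medication model", {
  tab <- params_to_table(default_parameters("SRS"))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  med <- load_parameters(path, "medication")
  expect_identical(med, default_medication_model())
})
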