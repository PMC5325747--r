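records_from_counts <- function(events, n, outcome = "x", treatment = "MVD") {
  study_records(sprintf("s%02d", seq_along(events)), treatment, outcome,
                n, events, follow_up_months = 24)
}

test_that("pooling identical studies returns their proportion with no heterogeneity", {
  rec <- records_from_counts(rep(20L, 5), rep(100L, 5))
  est <- pool_proportion(rec)
  expect_equal(est$mean, 0.2)
  expect_equal(est$tau2, 0)
  expect_equal(est$q, 0, tolerance = 1e-12)
  expect_equal(est$p_het, 1)
  expect_equal(est$k, 5L)
})

test_that("a single study pools to itself", {
  est <- pool_proportion(records_from_counts(30L, 60L))
  expect_equal(est$mean, 0.5)
  expect_equal(est$k, 1L)
  expect_equal(est$tau2, 0)
})

test_that("pooling matches an independent closed-form DerSimonian-Laird oracle", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:15, 1)
    n <- sample(30:300, k, replace = TRUE)
    events <- rbinom(k, n, runif(1, 0.05, 0.9))
    rec <- records_from_counts(events, n)
    est <- pool_proportion(rec)
    boundary <- events == 0L | events == n
    p <- ifelse(boundary, (events + 0.5) / (n + 1), events / n)
    v <- p * (1 - p) / ifelse(boundary, n + 1, n)
    oracle <- dl_pool_oracle(p, v)
    expect_equal(est$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(est$se, oracle$se, tolerance = 1e-12)
    expect_equal(est$tau2, oracle$tau2, tolerance = 1e-12)
    expect_equal(est$q, oracle$q, tolerance = 1e-10)
    # pooled mean inside the span of the (corrected) study proportions
    expect_gte(est$mean, min(p) - 1e-12)
    expect_lte(est$mean, max(p) + 1e-12)
  }
})

test_that("pooling agrees with metafor's DL fit on the same inputs", {
  set.seed(5)
  n <- sample(50:200, 8, replace = TRUE)
  events <- rbinom(8, n, 0.3)
  rec <- records_from_counts(events, n)
  est <- pool_proportion(rec)
  fit <- metafor::rma(yi = events / n, vi = (events / n) * (1 - events / n) / n,
                      method = "DL")
  expect_equal(est$mean, unname(fit$beta[1]), tolerance = 1e-10)
  expect_equal(est$se, fit$se, tolerance = 1e-10)
  expect_equal(est$tau2, fit$tau2, tolerance = 1e-10)
  expect_equal(est$q, fit$QE, tolerance = 1e-10)
  expect_equal(est$p_het, fit$QEp, tolerance = 1e-10)
})

test_that("equal-variance studies pool to the unweighted mean", {
  # 30/100 and 70/100 have identical sampling variances, so all weights are
  # equal whatever tau2 is, and the pooled mean is the simple average
  est <- pool_proportion(records_from_counts(c(30L, 70L), c(100L, 100L)))
  expect_equal(est$mean, 0.5, tolerance = 1e-12)
})

test_that("pooling rejects empty and mixed-outcome inputs", {
  rec <- records_from_counts(c(10L, 12L), c(50L, 60L))
  expect_error(pool_proportion(rec[0, ]), "no study records")
  rec$outcome <- c("a", "b")
  expect_error(pool_proportion(rec), "mix outcome labels")
})

test_that("heterogeneity test flags discordant studies and ignores order", {
  rec <- records_from_counts(c(5L, 95L), c(100L, 100L))
  ht <- heterogeneity_test(rec)
  expect_lt(ht$p_het, 0.001)
  # closed-form chi-square oracle
  p <- c(0.05, 0.95); v <- p * (1 - p) / 100
  expect_equal(ht$q, dl_pool_oracle(p, v)$q, tolerance = 1e-10)
  expect_equal(ht$p_het, pchisq(ht$q, df = 1, lower.tail = FALSE))
  shuffled <- heterogeneity_test(rec[2:1, ])
  expect_equal(shuffled$q, ht$q)
  expect_error(heterogeneity_test(rec[1, ]), "at least 2")
})

test_that("pooled proportions recover the generator's truth at nominal coverage", {
  hits <- 0L
  reps <- 500L
  for (r in seq_len(reps)) {
    spec <- single_rate_spec(0.528, k = 20L, n = 200L, seed = 1000L + r)
    corpus <- generate_corpus(spec)
    est <- pool_proportion(corpus[corpus$treatment == "MVD", ])
    if (abs(est$mean - 0.528) <= 3 * est$se) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("logit-scale pooling is available and agrees at moderate rates", {
  set.seed(3)
  n <- rep(200L, 10)
  events <- rbinom(10, n, 0.4)
  rec <- records_from_counts(events, n)
  raw <- pool_proportion(rec)
  lgt <- pool_proportion(rec, scale = "logit")
  expect_equal(lgt$mean, raw$mean, tolerance = 0.02)
})

test_that("meta-regression recovers a null slope on average", {
  slopes <- vapply(1:200, function(r) {
    spec <- single_rate_spec(0.3, k = 15L, n = 150L, seed = 2000L + r)
    corpus <- generate_corpus(spec)
    meta_regress(corpus[corpus$treatment == "MVD", ], "follow_up_months")$slope
  }, 0)
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("meta-regression recovers the sign of a real follow-up effect", {
  hits <- vapply(1:100, function(r) {
    spec <- single_rate_spec(0.3, k = 20L, n = 200L, seed = 3000L + r,
                             slopes = c(follow_up_months = 0.5, mean_age = 0,
                                        pct_female = 0, pct_prior = 0))
    corpus <- generate_corpus(spec)
    fit <- meta_regress(corpus[corpus$treatment == "MVD", ], "follow_up_months")
    fit$slope > 0
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("a flat synthetic recurrence corpus yields a non-significant follow-up slope", {
  spec <- corpus_spec(seed = 77L)
  corpus <- generate_corpus(spec)
  for (tr in c("MVD", "SRS")) {
    fit <- meta_regress(
      corpus[corpus$treatment == tr & corpus$outcome == "recurrence", ],
      "follow_up_months")
    expect_gt(fit$p_slope, 0.05)
    expect_gte(fit$r2, 0)
    expect_lte(fit$r2, 1)
  }
})

test_that("meta-regression rejects degenerate inputs", {
  rec <- records_from_counts(c(10L, 20L, 30L), rep(100L, 3))
  rec$follow_up_months <- 24
  expect_error(meta_regress(rec, "follow_up_months"), "constant")
  expect_error(meta_regress(rec[1:2, ], "mean_age"), "at least 3")
  expect_error(meta_regress(rec, "nope"), "unknown covariate")
})

test_that("Welch t-test behaves on identical, swapped and separated samples", {
  x <- c(1, 2, 3, 4)
  same <- welch_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(8)
  a <- rnorm(100); b <- rnorm(100, mean = 5)
  ab <- welch_t_test(a, b); ba <- welch_t_test(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_lt(ab$p, 0.001)
  expect_error(welch_t_test(1, x), "at least 2")
})

test_that("study records validate counts and loading drops high-prior-procedure studies", {
  expect_error(study_records("a", "MVD", "x", 10L, 12L, 24), "\\[0, n\\]")
  expect_error(study_records("a", "MVD", "x", 0L, 0L, 24), "positive")
  expect_error(study_records("a", "PGR", "x", 10L, 2L, 24), "MVD")

  rec <- study_records(c("a", "b", "c"), "SRS", "x", c(50L, 60L, 70L),
                       c(5L, 6L, 7L), 24, pct_prior = c(0.10, 0.50, 0.20))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec, path, row.names = FALSE)
  expect_message(kept <- load_study_records(path), "excluding 1")
  expect_equal(kept$study_id, c("a", "c"))
  writeLines("study_id,n\na,5", path)
  expect_error(load_study_records(path), "missing columns")
})
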