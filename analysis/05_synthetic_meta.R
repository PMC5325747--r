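#!/usr/bin/env Rscript
# Step 5 - Synthetic evidence base: pooling and meta-regression checks.
#
# No study-level data ships with the published pooled tables, so the
# meta-analytic layer is exercised on a synthetic corpus with the same
# structure: 17 MVD + 40 SRS studies, sizes 15-500, true rates equal to the
# pooled means, follow-up and demographics matching the reported
# distributions.  Expected findings: pooled proportions recover the true
# rates within a few pooled SEs, recurrence shows no follow-up trend (the
# generator encodes none, matching the published non-significant
# meta-regressions), and parameters pooled from the corpus give expected
# QALYs close to those from the true rates.

suppressPackageStartupMessages(library(tndecide))
dir.create("results", showWarnings = FALSE)

spec <- corpus_spec(seed = 11L)
fx <- end_to_end_fixture(spec)
write.csv(fx$corpus, "results/synthetic_corpus.csv", row.names = FALSE)

pool_rows <- do.call(rbind, lapply(c("MVD", "SRS"), function(tr) {
  pooled <- attr(fx$params[[tr]], "pooled")
  do.call(rbind, lapply(names(pooled), function(oc) {
    e <- pooled[[oc]]
    data.frame(treatment = tr, outcome = oc, true_rate = spec$true_rates[[tr]][[oc]],
               pooled_mean = e$mean, pooled_se = e$se, tau2 = e$tau2,
               q = e$q, p_het = e$p_het, k = e$k)
  }))
}))
write.csv(pool_rows, "results/synthetic_pooling.csv", row.names = FALSE)
message(sprintf("max |pooled - true| across outcomes: %.4f",
                max(abs(pool_rows$pooled_mean - pool_rows$true_rate))))

reg_rows <- do.call(rbind, lapply(c("MVD", "SRS"), function(tr) {
  rec <- fx$corpus[fx$corpus$treatment == tr & fx$corpus$outcome == "recurrence", ]
  fit <- meta_regress(rec, "follow_up_months")
  data.frame(treatment = tr, outcome = "recurrence",
             covariate = "follow_up_months", slope = fit$slope,
             slope_se = fit$slope_se, p_slope = fit$p_slope, r2 = fit$r2)
}))
write.csv(reg_rows, "results/synthetic_meta_regression.csv", row.names = FALSE)
for (i in seq_len(nrow(reg_rows))) {
  message(sprintf(
    "%s recurrence vs follow-up: slope %.2g per month (p = %.2f) - no trend, as generated",
    reg_rows$treatment[i], reg_rows$slope[i], reg_rows$p_slope[i]))
}

qaly_rows <- do.call(rbind, lapply(c("MVD", "SRS"), function(tr) {
  other <- setdiff(c("MVD", "SRS"), tr)
  data.frame(
    treatment = tr,
    qalys_true_params = expected_qalys(tr),
    qalys_pooled_params = expected_qalys(tr, fx$params[[tr]],
                                         other_params = fx$params[[other]]))
}))
write.csv(qaly_rows, "results/synthetic_end_to_end.csv", row.names = FALSE)
for (i in seq_len(nrow(qaly_rows))) {
  message(sprintf("%s: %.3f QALYs from true rates vs %.3f from the pooled corpus",
                  qaly_rows$treatment[i], qaly_rows$qalys_true_params[i],
                  qaly_rows$qalys_pooled_params[i]))
}
message("wrote results/synthetic_*.csv")
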