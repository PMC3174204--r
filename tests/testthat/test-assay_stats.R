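test_that("two-sample t-test matches the textbook pooled-variance formula", {
  res <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.2878641, tolerance = 1e-6)

  set.seed(101)
  for (i in 1:50) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    got <- two_sample_ttest(x, y)
    want <- oracle_ttest(x, y)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    swapped <- two_sample_ttest(y, x)
    expect_equal(swapped$statistic, -got$statistic, tolerance = 1e-10)
    expect_equal(swapped$p_value, got$p_value, tolerance = 1e-10)
  }

  expect_equal(two_sample_ttest(c(1, 1, 1), c(1, 1, 1)),
               list(statistic = 0, df = 4, p_value = 1))
  expect_equal(two_sample_ttest(c(2, 2), c(1, 1))$p_value, 0)
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("delta-delta-Ct fold change follows the hand-computed arithmetic", {
  mk <- function(dct, ref = 15) data.frame(ct_target = ref + dct,
                                           ct_reference = ref)
  # identical groups: fold change 1
  expect_equal(ddct_fold_change(mk(c(5, 5, 5)), mk(c(5, 5, 5)))$linear_fc, 1)
  # treated dCt 4 vs control dCt 5 (noiseless): 2^-(4-5) = 2
  fc <- ddct_fold_change(mk(c(4, 4, 4)), mk(c(5, 5, 5)))
  expect_equal(fc$linear_fc, 2)
  expect_equal(fc$log2_fc, 1)
  # invariance to a per-replicate additive shift on target and reference
  set.seed(3)
  tr <- data.frame(ct_target = rnorm(3, 22), ct_reference = rnorm(3, 15))
  co <- data.frame(ct_target = rnorm(3, 23), ct_reference = rnorm(3, 15))
  base <- ddct_fold_change(tr, co)
  shift <- runif(3, -2, 2)
  tr2 <- tr + shift; co2 <- co  # shift applied to both columns of each replicate
  shifted <- ddct_fold_change(tr2, co2)
  expect_equal(shifted$linear_fc, base$linear_fc, tolerance = 1e-12)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-12)
  expect_error(ddct_fold_change(data.frame(ct_target = 1:3), co), "ct_reference")
})

fc_result <- function(linear_fc, p, assay = "screen") {
  structure(list(gene = "g", species = "s", assay = assay,
                 linear_fc = linear_fc, log2_fc = log2(linear_fc),
                 p_value = p, n_treated = 3, n_control = 3),
            class = "fold_change_result")
}

test_that("screen calls apply strict fold-change and significance gates", {
  thr <- default_thresholds()
  # no change never passes, whatever the p-value
  expect_false(screen_call(fc_result(1.0, 1e-9), "LOF", thr)$passed)
  expect_false(screen_call(fc_result(1.0, 1e-9), "GOF", thr)$passed)
  # boundary: linear FC exactly 1.3 fails the LOF call (strict inequality)
  expect_false(screen_call(fc_result(1.3, 1e-9), "LOF", thr)$passed)
  expect_true(screen_call(fc_result(1.3 + 1e-9, 1e-9), "LOF", thr)$passed)
  # GOF mirrors the cutoff on the repression scale
  expect_false(screen_call(fc_result(1 / 1.3, 1e-9), "GOF", thr)$passed)
  expect_true(screen_call(fc_result(1 / 1.3 - 1e-9, 1e-9), "GOF", thr)$passed)
  # significance required even for large changes
  expect_false(screen_call(fc_result(3, 0.2), "LOF", thr)$passed)
  expect_error(screen_call(fc_result(2, 0.01), "unknown"), "arg")
  # gene-level screen pass is the OR of the two arms
  gof <- screen_call(fc_result(0.5, 1e-4), "GOF", thr)
  lof <- screen_call(fc_result(1.1, 0.5), "LOF", thr)
  expect_true(screen_gene_call(gof, lof)$passed)
  expect_false(screen_gene_call(screen_call(fc_result(0.9, 0.5), "GOF", thr),
                                lof)$passed)
})

test_that("pull-down enrichment call uses a strict log2 cutoff", {
  thr <- default_thresholds()
  mk <- function(dct) data.frame(ct_target = 20 + dct, ct_reference = 15)
  # equal normalized abundance: log2 enrichment 0, fail
  eq <- pulldown_enrichment_call(mk(c(5, 5, 5)), mk(c(5, 5, 5)), thresholds = thr)
  expect_equal(eq$stats$log2_fc, 0)
  expect_false(eq$passed)
  # log2 enrichment exactly 0.5 (noiseless, p = 0 by convention) still fails
  half <- pulldown_enrichment_call(mk(c(4.5, 4.5, 4.5)), mk(c(5, 5, 5)),
                                   thresholds = thr)
  expect_equal(half$stats$log2_fc, 0.5)
  expect_false(half$passed)
  # clearly enriched passes
  strong <- pulldown_enrichment_call(mk(c(3, 3.01, 2.99)), mk(c(5, 5.01, 4.99)),
                                     thresholds = thr)
  expect_true(strong$passed)
  expect_error(pulldown_enrichment_call(mk(1:3), NULL), "control bait")
})

test_that("luciferase percent activity is ratio-normalized and calls need p < 0.01", {
  mk <- function(ren, fir = 1000) data.frame(renilla = ren, firefly = fir)
  thr <- default_thresholds()
  # treatment identical to control: 100%
  same <- luciferase_percent_activity(mk(c(500, 510, 490)), mk(c(500, 510, 490)))
  expect_equal(same$percent, 100)
  expect_false(luciferase_repression_call(same, thresholds = thr)$passed)
  # exact halving: 50%
  half <- luciferase_percent_activity(mk(c(250, 255, 245)), mk(c(500, 510, 490)))
  expect_equal(half$percent, 50)
  # per-well scale factors cancel in the ratio
  fac <- c(0.5, 2, 1.3)
  scaled <- luciferase_percent_activity(
    data.frame(renilla = c(250, 255, 245) * fac, firefly = 1000 * fac),
    mk(c(500, 510, 490)))
  expect_equal(scaled$percent, half$percent, tolerance = 1e-12)
  # repressed but noisy (p large) fails; repressed and significant passes
  noisy <- structure(list(construct = "c", percent = 55, p_value = 0.5,
                          n_treatment = 3, n_control = 3,
                          norm_treatment = c(.2, .9, .4),
                          norm_control = c(.5, .5, .5)),
                     class = "luciferase_result")
  expect_false(luciferase_repression_call(noisy, thresholds = thr)$passed)
  clear <- structure(list(construct = "c", percent = 55, p_value = 0.001,
                          n_treatment = 3, n_control = 3,
                          norm_treatment = c(.27, .28, .27),
                          norm_control = c(.5, .5, .5)),
                     class = "luciferase_result")
  expect_true(luciferase_repression_call(clear, thresholds = thr)$passed)
  expect_error(luciferase_percent_activity(mk(1, fir = 0), mk(1)), "firefly")
})

test_that("seed-mutant abrogation follows the documented conventions", {
  thr <- default_thresholds()
  wt_res <- luciferase_percent_activity(
    data.frame(renilla = c(250, 252, 248), firefly = 1000),
    data.frame(renilla = c(500, 502, 498), firefly = 1000))
  wt <- luciferase_repression_call(wt_res, thresholds = thr)
  expect_true(wt$passed)
  # mutant back at baseline: abrogated
  mut_flat <- luciferase_percent_activity(
    data.frame(renilla = c(495, 500, 505), firefly = 1000),
    data.frame(renilla = c(500, 502, 498), firefly = 1000))
  expect_true(seed_mutant_rescue_test(wt, mut_flat, thr)$abrogated)
  # mutant identical to the repressed wild-type profile: not abrogated
  expect_false(seed_mutant_rescue_test(wt, wt_res, thr)$abrogated)
  # alternative reading: mutant vs wild-type comparison
  expect_true(seed_mutant_rescue_test(wt, mut_flat, thr,
                                      method = "exceeds_wildtype")$abrogated)
  # calling without a passing wild-type is an error
  failed_wt <- luciferase_repression_call(mut_flat, thresholds = thr)
  expect_error(seed_mutant_rescue_test(failed_wt, mut_flat, thr), "passed")
})

test_that("calls are monotone in effect size on noiseless inputs", {
  thr <- default_thresholds()
  tiny <- c(-1e-6, 0, 1e-6)  # symmetric jitter so the t-test has variance
  mk <- function(dct) data.frame(ct_target = 20 + dct + tiny, ct_reference = 15)
  prev_screen <- prev_pd <- FALSE
  for (eff in seq(0, 3, by = 0.25)) {
    # GOF repression raises the target Ct; pull-down enrichment lowers it
    sc <- screen_call(ddct_fold_change(mk(eff), mk(0), assay = "screen"),
                      "GOF", thr)$passed
    pd <- pulldown_enrichment_call(mk(-eff), mk(0), thresholds = thr)$passed
    expect_false(prev_screen && !sc, info = paste("screen effect", eff))
    expect_false(prev_pd && !pd, info = paste("pulldown effect", eff))
    prev_screen <- sc; prev_pd <- pd
  }
  expect_true(prev_screen)
  expect_true(prev_pd)
})
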