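test_that("simulation config validates its invariants", {
  expect_error(simulation_config(frac_direct = 0.7, frac_indirect = 0.5),
               "fractions")
  expect_error(simulation_config(n_replicates = 1), ">= 2")
  expect_error(simulation_config(luciferase_repression = 0), "repression")
  expect_error(simulation_config(utr_length = 10), "utr_length")
})

test_that("truth generation respects fractions, determinism, and binomial bounds", {
  # degenerate fractions: everything null
  cfg0 <- simulation_config(n_genes = 50, frac_direct = 0, frac_indirect = 0,
                            rng_seed = 4)
  expect_true(all(generate_truth(cfg0)$class == "null"))

  # same config, same seed: identical tables
  cfg <- simulation_config(n_genes = 100, rng_seed = 5)
  expect_identical(generate_truth(cfg), generate_truth(cfg))

  # direct counts within the exact binomial 99% interval of n * p
  cfg2 <- simulation_config(n_genes = 1000, species_list = "human",
                            frac_direct = 0.3, frac_indirect = 0,
                            rng_seed = 6)
  n_direct <- sum(generate_truth(cfg2)$class == "direct_target")
  expect_gte(n_direct, qbinom(0.005, 1000, 0.3))
  expect_lte(n_direct, qbinom(0.995, 1000, 0.3))
})

test_that("synthesized UTRs plant sites in direct targets and none elsewhere", {
  mir <- test_mirna()
  cfg <- simulation_config(n_genes = 30, species_list = "human",
                           frac_direct = 0.5, frac_indirect = 0.2,
                           utr_length = 200, rng_seed = 8)
  truth <- generate_truth(cfg)
  syn <- synthesize_utrs(truth, mir, cfg)
  for (i in seq_len(nrow(syn$truth))) {
    hits <- find_seed_sites(syn$utrs[[i]], mir,
                            c("8mer", "7mer-m8", "7mer-A1", "perfect23"))
    if (syn$truth$class[i] == "direct_target") {
      expect_gte(nrow(hits), 1L)
      expect_true(syn$truth$site_start[i] %in% hits$start)
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }
  expect_error(synthesize_utrs(truth, mir,
                               simulation_config(utr_length = 30)),
               NA)  # 30 nt hosts a 7-nt site
})

test_that("chance seed-match counts in unrejected background follow (L-6)/4^7", {
  mir <- test_mirna()
  set.seed(99)
  L <- 1000; n_utr <- 120
  counts <- vapply(seq_len(n_utr), function(i) {
    nrow(find_seed_sites(rand_rna(L), mir, "7mer-m8"))
  }, numeric(1))
  expected <- (L - 6) / 4^7
  # mean count over UTRs approaches the per-window hit probability times windows
  se <- sqrt(expected / n_utr)  # Poisson-scale error
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("assay simulators are deterministic and recover planted effects", {
  mir <- test_mirna()
  cfg <- simulation_config(n_genes = 12, species_list = "human",
                           frac_direct = 0.5, frac_indirect = 0.25,
                           effect_log2fc = 1, noise_sd_ct = 0.1,
                           rng_seed = 10)
  truth <- generate_truth(cfg)
  expect_identical(simulate_qpcr_screen(truth, cfg),
                   simulate_qpcr_screen(truth, cfg))
  expect_identical(simulate_pulldown(truth, cfg),
                   simulate_pulldown(truth, cfg))
  expect_identical(simulate_luciferase(truth, cfg),
                   simulate_luciferase(truth, cfg))

  # noiseless limit: recovered fold change is exactly 2^effect
  cfg0 <- simulation_config(n_genes = 6, species_list = "human",
                            frac_direct = 1, frac_indirect = 0,
                            effect_log2fc = 1, noise_sd_ct = 0,
                            rng_seed = 11)
  truth0 <- generate_truth(cfg0)
  screen0 <- simulate_qpcr_screen(truth0, cfg0)
  g <- truth0$gene[1]
  rows <- screen0[screen0$gene == g & screen0$mode == "LOF", ]
  fc <- ddct_fold_change(rows[rows$condition == "treatment", ],
                         rows[rows$condition == "negative_control", ])
  expect_equal(fc$linear_fc, 2, tolerance = 1e-12)

  # low noise: direct genes recover FC near 2 in the LOF arm and pass calls
  cfgr <- simulation_config(n_genes = 40, species_list = "human",
                            frac_direct = 1, frac_indirect = 0,
                            effect_log2fc = 1, noise_sd_ct = 0.1,
                            rng_seed = 12)
  trr <- generate_truth(cfgr)
  scr <- run_screen_calls(simulate_qpcr_screen(trr, cfgr))
  lof <- scr$details[scr$details$mode == "LOF", ]
  expect_equal(median(lof$linear_fc), 2, tolerance = 0.15)
  expect_gt(mean(vapply(scr$calls, function(cl) cl$passed, logical(1))), 0.95)

  pdc <- run_pulldown_calls(simulate_pulldown(trr, cfgr))
  expect_gt(mean(pdc$details$passed), 0.95)

  lucc <- run_luciferase_calls(simulate_luciferase(trr, cfgr))
  expect_equal(median(lucc$details$percent), 50, tolerance = 6)
  expect_gt(mean(lucc$details$passed), 0.9)
})

test_that("indirect responders respond in the screen but not in the pull-down", {
  cfg <- simulation_config(n_genes = 60, species_list = "human",
                           frac_direct = 0, frac_indirect = 1,
                           effect_log2fc = 1, noise_sd_ct = 0.2,
                           rng_seed = 13)
  truth <- generate_truth(cfg)
  scr <- run_screen_calls(simulate_qpcr_screen(truth, cfg))
  expect_gt(mean(vapply(scr$calls, function(cl) cl$passed, logical(1))), 0.9)
  pdc <- run_pulldown_calls(simulate_pulldown(truth, cfg))
  expect_lt(mean(abs(pdc$details$log2_fc)), 0.3)   # centred at zero enrichment
  expect_lt(mean(pdc$details$passed), 0.1)
})

test_that("a full bundle is seed-deterministic end to end", {
  cfg <- simulation_config(n_genes = 15, rng_seed = 14)
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  b1$mirna <- b2$mirna <- NULL  # environments differ; content compared below
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
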