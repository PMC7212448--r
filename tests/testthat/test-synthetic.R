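test_that("simulation is fully deterministic for a given seed", {
  s1 <- simulate_experiment(small_sim_config(seed = 1))
  s2 <- simulate_experiment(small_sim_config(seed = 1))
  expect_equal(s1$glyco_psms, s2$glyco_psms)
  expect_equal(s1$protein_psms, s2$protein_psms)
  expect_equal(s1$truth, s2$truth)
  s3 <- simulate_experiment(small_sim_config(seed = 2))
  expect_false(identical(s1$glyco_psms, s3$glyco_psms))
  # the generator restores the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_experiment(small_sim_config(seed = 1)))
  expect_equal(runif(1), before)
})

test_that("catalog size follows the configured structure", {
  cfg <- sim_config(n_glycoproteins = 10, mean_extra_sites = 0,
                    mean_extra_glycans = 0, seed = 5)
  cat10 <- generate_catalog(cfg)
  expect_equal(nrow(cat10), 10) # 10 proteins x 1 site x 1 glycan
  expect_equal(length(unique(cat10$protein)), 10)
  expect_true(all(cat10$glycosite >= 1))
  expect_true(all(grepl("N#[^P][ST]", cat10$peptide))) # sequon marker
  expect_equal(cat10, generate_catalog(cfg))
})

test_that("a pure oligo-mannose pool yields only HexNAc2 compositions", {
  pool <- default_glycan_pool()
  pool <- pool[pool$subtype == "oligo-mannose", ]
  cfg <- sim_config(n_glycoproteins = 20, pool = pool, seed = 3)
  cat_oligo <- generate_catalog(cfg)
  expect_true(all(parse_glycan(cat_oligo$glycan)$n_hexnac == 2))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(frac_common_up = 0.9, frac_protein_driven = 0.2),
               "sum")
  expect_error(sim_config(psm_mean = -1), "psm_mean")
  expect_error(sim_config(sigma = -0.1), "sigma")
  expect_error(sim_config(fold_common = 1), "exceed 1")
  expect_error(sim_config(channel_loadings = c(`126` = 1)), "loading")
})

test_that("noiseless null runs give exactly unit ratios after normalization", {
  cfg <- sim_config(
    n_glycoproteins = 30, sigma = 0, psm_scatter_sd = 0,
    frac_common_up = 0, frac_common_down = 0, frac_unique_low = 0,
    frac_unique_high = 0, frac_protein_driven = 0,
    frac_occupancy_shift = 0,
    channel_loadings = c(`126` = 2, `127N` = 1, `128C` = 1, `129N` = 1),
    seed = 12
  )
  res <- run_pipeline(simulate_experiment(cfg))
  # the 2x loading on channel 126 is fully removed by normalization
  expect_equal(res$factors$factor[1] / res$factors$factor[2], 2,
               tolerance = 1e-12)
  ratios <- as.matrix(
    tibble::as_tibble(res$glyco)[grep("^log2_", names(res$glyco))]
  )
  expect_equal(max(abs(ratios)), 0, tolerance = 1e-12)
})

test_that("noiseless planted effects propagate exactly", {
  cfg <- sim_config(
    n_glycoproteins = 40, sigma = 0, psm_scatter_sd = 0,
    frac_common_up = 0.2, frac_common_down = 0, frac_unique_low = 0,
    frac_unique_high = 0, frac_protein_driven = 0,
    frac_occupancy_shift = 0, fold_common = 4, seed = 13
  )
  sim <- simulate_experiment(cfg)
  res <- run_pipeline(sim)
  joined <- tibble::as_tibble(res$glyco) |>
    dplyr::inner_join(sim$truth[c("feature_id", "label")],
                      by = "feature_id")
  up <- joined[joined$label == "common-up", ]
  expect_gt(nrow(up), 0)
  expect_equal(up$log2_tumor_vs_para_lowAFP, rep(2, nrow(up)),
               tolerance = 1e-12)
  expect_equal(up$log2_tumor_vs_para_highAFP, rep(2, nrow(up)),
               tolerance = 1e-12)
  null <- joined[joined$label == "null", ]
  expect_equal(max(abs(null$log2_tumor_vs_para_lowAFP)), 0,
               tolerance = 1e-12)
})

test_that("planted truth is internally consistent", {
  sim <- simulate_experiment(sim_config(seed = 22))
  tr <- sim$truth
  # occupancy + protein = glycopeptide effect, per comparison
  for (cmp in c("tumor_vs_para_lowAFP", "tumor_lowAFP_vs_highAFP")) {
    expect_equal(
      tr[[paste0("true_glyco_", cmp)]],
      tr[[paste0("true_protein_", cmp)]] +
        tr[[paste0("true_occupancy_", cmp)]]
    )
  }
  # protein-driven implies zero occupancy effect everywhere
  pd <- tr[tr$label == "protein-driven", ]
  occ_cols <- grep("^true_occupancy_", names(tr), value = TRUE)
  expect_equal(max(abs(as.matrix(pd[occ_cols]))), 0)
  # occupancy-shift implies a glycopeptide-flat, occupancy-down change
  os <- tr[tr$label == "occupancy-shift", ]
  expect_equal(max(abs(os$true_glyco_tumor_vs_para_lowAFP)), 0)
  expect_lt(max(os$true_occupancy_tumor_vs_para_lowAFP), 0)
})

test_that("the default pool reproduces the tissue subtype mix", {
  # catalog-level oligo-mannose fraction should match the pool weight
  # (0.291) within clustered-sampling error across two seeds
  fr <- vapply(c(301, 302), function(s) {
    cat_s <- generate_catalog(sim_config(seed = s))
    mean(classify_glycans(cat_s$glycan)$subtype == "oligo-mannose")
  }, numeric(1))
  expect_true(all(abs(fr - 0.291) < 0.05))
  # and the PSM-level mix lands near 59.8 / 29.1 / 11.1
  # PSM-level split lands near 59.8 / 29.1 / 11.1 within ~3 clustered
  # binomial standard errors (~1.5 pp at ~1,000 glycopeptides)
  sim <- simulate_experiment(sim_config(seed = 303))
  f <- subtype_psm_fractions(sim$glyco_psms)
  expect_lt(abs(f$pct[f$subtype == "complex"] - 59.8), 5)
  expect_lt(abs(f$pct[f$subtype == "oligo-mannose"] - 29.1), 5)
  expect_lt(abs(f$pct[f$subtype == "hybrid"] - 11.1), 4)
})

test_that("recovery scoring handles perfect, imperfect and empty calls", {
  truth <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    label = factor(c("common-up", "common-down", "null", "protein-driven"),
                   levels = glycoquant:::SIM_LABELS)
  )
  calls <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    common_label = factor(c("up", "down", "none", "none"),
                          levels = c("up", "down", "none")),
    unique_label = factor(rep("none", 4),
                          levels = c("lowAFP-unique", "highAFP-unique",
                                     "none"))
  )
  rec <- evaluate_recovery(calls, truth)
  expect_equal(rec$recall[rec$label == "common-up"], 1)
  expect_equal(rec$precision[rec$label == "common-down"], 1)
  expect_true(is.na(rec$recall[rec$label == "lowAFP-unique"])) # no truths

  # no calls at all: recall 0 where truths exist, precision NA
  rec0 <- evaluate_recovery(calls[0, ], truth)
  expect_equal(rec0$recall[rec0$label == "common-up"], 0)
  expect_true(all(is.na(rec0$precision)))

  bad <- calls
  bad$feature_id[1] <- "zzz"
  expect_error(evaluate_recovery(bad, truth), "absent")
})

test_that("YAML configuration round-trips with threshold defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_glycoproteins: 15",
    "sigma: 0.1",
    "seed: 4",
    "common_cutoff: 3"
  ), path)
  got <- read_sim_config(path)
  expect_equal(got$config$n_glycoproteins, 15L)
  expect_equal(got$config$sigma, 0.1)
  expect_equal(got$thresholds$common_cutoff, 3)
  expect_equal(got$thresholds$min_psms, 5)
  expect_equal(got$thresholds$unique_cutoff, 1.5)
  writeLines("not_a_key: 1", path)
  expect_error(read_sim_config(path), "not_a_key")
})
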