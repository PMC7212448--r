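test_that("symmetric protein PSMs give unit normalization factors", {
  psms <- protein_psms_fixture("P1", channel_mult = c(1, 1, 1, 1))
  fac <- compute_channel_factors(psms, test_design)
  expect_equal(fac$factor, rep(1, 4))
})

test_that("a uniformly 2x channel yields the closed-form factors", {
  # with 4 channels, the scaled channel's ratio to the PSM geometric mean
  # is 2 / 2^(1/4) = 2^(3/4); the others are 2^(-1/4)
  psms <- dplyr::bind_rows(
    protein_psms_fixture("P1", c(2, 1, 1, 1), n_psms = 7, base = 1e6),
    protein_psms_fixture("P2", c(2, 1, 1, 1), n_psms = 5, base = 3e5)
  )
  fac <- compute_channel_factors(psms, test_design)
  expect_equal(fac$factor, c(2^(3 / 4), 2^(-1 / 4), 2^(-1 / 4), 2^(-1 / 4)),
               tolerance = 1e-12)
  # after normalization all channel medians are equal
  norm <- as.matrix(psms[paste0("intensity_", test_design$channels)])
  norm <- sweep(norm, 2, fac$factor, "/")
  meds <- apply(norm, 2, median)
  expect_equal(max(meds) / min(meds), 1, tolerance = 1e-12)
})

test_that("factors are robust to duplicating the median PSM", {
  withr::with_seed(11, {
    base <- 10^runif(9, 4, 7)
  })
  psms <- purrr::map_dfr(seq_along(base), function(i) {
    protein_psms_fixture(paste0("P", i), c(1.7, 0.9, 1.1, 1),
                         n_psms = 1, base = base[i])
  })
  fac1 <- compute_channel_factors(psms, test_design)
  med_row <- psms[which(rank(psms$intensity_126) == 5), ]
  fac2 <- compute_channel_factors(
    dplyr::bind_rows(psms, med_row, med_row), test_design
  )
  expect_equal(fac1$factor, fac2$factor)
})

test_that("factors error when no complete protein PSM exists", {
  psms <- protein_psms_fixture("P1", c(1, 1, 1, 1))
  psms$incomplete <- TRUE
  expect_error(compute_channel_factors(psms, test_design), "complete")
})

test_that("features below the minimum PSM count are dropped", {
  psms <- dplyr::bind_rows(
    feature_psms("P1", 100, "N4H5S2", c(1, 1, 1, 1), n_psms = 4),
    feature_psms("P1", 200, "N2H8", c(1, 1, 1, 1), n_psms = 5)
  )
  q <- quantify_features(psms, unit_factors(), test_design, min_psms = 5)
  expect_equal(q$feature_id, "P1|200|N2H8")
  expect_equal(q$n_psms, 5L)
  expect_error(
    quantify_features(psms, unit_factors(), test_design, min_psms = 0),
    "min_psms"
  )
})

test_that("the feature ratio is the ratio of channel medians", {
  # per-PSM tumor/para ratios 1,2,4,8,16 in the low-AFP pair -> median 4
  ratios <- c(1, 2, 4, 8, 16)
  psms <- purrr::map_dfr(seq_along(ratios), function(i) {
    p <- feature_psms("P1", 100, "N4H5S2",
                      c(1, ratios[i], 1, 1), n_psms = 1, base = 1e6)
    p$spectrum_id <- paste0("s", i)
    p
  })
  q <- quantify_features(psms, unit_factors(), test_design, min_psms = 5)
  expect_equal(2^q$log2_tumor_vs_para_lowAFP, 4.0, tolerance = 1e-12)
})

test_that("quantitation is invariant to PSM row order", {
  sim <- simulate_experiment(small_sim_config(seed = 2))
  fac <- compute_channel_factors(sim$protein_psms, test_design)
  q1 <- quantify_features(sim$glyco_psms, fac, test_design)
  withr::with_seed(9, {
    shuffled <- sim$glyco_psms[sample(nrow(sim$glyco_psms)), ]
  })
  q2 <- quantify_features(shuffled, fac, test_design)
  expect_equal(tibble::as_tibble(q1), tibble::as_tibble(q2))
})

test_that("normalization absorbs any per-channel rescaling", {
  sim <- simulate_experiment(small_sim_config(seed = 3))
  run_ratios <- function(glyco, protein) {
    fac <- compute_channel_factors(protein, test_design)
    q <- quantify_features(glyco, fac, test_design)
    as.matrix(tibble::as_tibble(q)[grep("^log2_", names(q))])
  }
  r1 <- run_ratios(sim$glyco_psms, sim$protein_psms)
  scaled_g <- sim$glyco_psms
  scaled_p <- sim$protein_psms
  scaled_g$intensity_128C <- scaled_g$intensity_128C * 7
  scaled_p$intensity_128C <- scaled_p$intensity_128C * 7
  r2 <- run_ratios(scaled_g, scaled_p)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("median-ratio estimator is unbiased for a 2-fold change", {
  # Monte-Carlo oracle: 9 PSMs, log2 noise sd 0.25, planted 2-fold change,
  # 1,000 replicates; |mean estimate - 1 log2 unit| < 0.05
  n_rep <- 1000
  n_psm <- 9
  withr::with_seed(123, {
    est <- vapply(seq_len(n_rep), function(r) {
      noise_t <- rnorm(n_psm, 0, 0.25)
      noise_p <- rnorm(n_psm, 0, 0.25)
      base <- rnorm(n_psm, 20, 1)
      log2(median(2^(base + 1 + noise_t)) / median(2^(base + noise_p)))
    }, numeric(1))
  })
  expect_lt(abs(mean(est) - 1), 0.05)
})

test_that("occupancy subtracts the parent-protein ratio", {
  gpsms <- dplyr::bind_rows(
    feature_psms("P1", 100, "N4H5S2", c(1, 2, 1, 2)), # glyco 2x, both tumors
    feature_psms("P2", 50, "N2H8", c(1, 2, 1, 2))     # parent unquantified
  )
  ppsms <- protein_psms_fixture("P1", c(1, 2, 1, 1)) # protein 2x in low tumor
  fac <- unit_factors()
  gq <- quantify_features(gpsms, fac, test_design, kind = "glyco")
  pq <- quantify_features(ppsms, fac, test_design, kind = "protein")
  occ <- occupancy_ratios(gq, pq)

  p1 <- occ[occ$protein == "P1", ]
  # low-AFP pair: glyco 1.0 - protein 1.0 = 0 (pure protein-level change)
  expect_equal(p1$occupancy_tumor_vs_para_lowAFP, 0, tolerance = 1e-12)
  # high-AFP pair: glyco 1.0 - protein 0.0 = 1 (pure occupancy change)
  expect_equal(p1$occupancy_tumor_vs_para_highAFP, 1, tolerance = 1e-12)
  expect_true(p1$parent_protein_quantified)

  p2 <- occ[occ$protein == "P2", ]
  expect_false(p2$parent_protein_quantified)
  expect_true(is.na(p2$occupancy_tumor_vs_para_lowAFP))
})

test_that("flipping a comparison's direction negates the occupancy change", {
  flipped <- channel_design(
    channels = test_design$channels,
    groups = unname(test_design$groups),
    comparisons = tibble::tibble(
      comparison = c("fwd", "rev"),
      numerator = c("127N", "126"),
      denominator = c("126", "127N")
    )
  )
  gpsms <- feature_psms("P1", 100, "N4H5S2", c(1, 3, 1, 1),
                        design = flipped)
  ppsms <- protein_psms_fixture("P1", c(1, 1.5, 1, 1), design = flipped)
  fac <- unit_factors(flipped)
  gq <- quantify_features(gpsms, fac, flipped, kind = "glyco")
  pq <- quantify_features(ppsms, fac, flipped, kind = "protein")
  occ <- occupancy_ratios(gq, pq)
  expect_equal(occ$occupancy_fwd, -occ$occupancy_rev, tolerance = 1e-12)
  expect_equal(occ$occupancy_fwd, log2(3 / 1.5), tolerance = 1e-12)
})

test_that("tidy and glance summarize quantified features", {
  sim <- simulate_experiment(small_sim_config(seed = 4))
  res <- run_pipeline(sim)
  long <- tidy(res$glyco)
  expect_equal(nrow(long), nrow(res$glyco) * 4)
  expect_named(long, c("feature_id", "n_psms", "comparison", "log2_ratio"))
  g <- glance(res$glyco)
  expect_equal(g$n_features, nrow(res$glyco))
  expect_true(all(res$glyco$n_psms >= g$min_psms))
})
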