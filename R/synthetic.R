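# Synthetic glyco-PSM and protein-PSM generator with planted effects and
# ground truth, emulating the statistical structure of a pooled 4-channel
# isobaric glycoproteomics experiment: a glycopeptide catalog over a
# realistic composition pool, negative-binomial PSM counts, log-normal
# reporter noise, per-channel loading factors (exercising normalization),
# and effect blocks at the protein, glycopeptide and occupancy levels.

SIM_LABELS <- c("null", "common-up", "common-down", "lowAFP-unique",
                "highAFP-unique", "protein-driven", "occupancy-shift")

#' Default N-glycan composition pool
#'
#' A weighted pool of compositions whose PSM mass reproduces the canonical
#' tissue subtype split (~60% complex / 29% oligo-mannose / 11% hybrid),
#' with biantennary compositions carrying about two thirds of the complex
#' weight and the common biantennary and oligo-mannose species (N4H5S2,
#' N4H5S1, N4H5F1S1, N2H5..N2H9, ...) dominating.
#'
#' @return Tibble with `glycan`, `weight` (summing to 1) and `subtype`.
#' @export
default_glycan_pool <- function() {
  pool <- tibble::tribble(
    ~glycan,      ~weight,
    # complex, biantennary (2/3 of complex mass)
    "N4H5S2",     0.110,
    "N4H5S1",     0.090,
    "N4H5F1S1",   0.075,
    "N4H5F1S2",   0.055,
    "N4H5F1",     0.035,
    "N4H5",       0.020,
    "N4H4F1",     0.010,
    "N4H5S3",     0.005,
    # complex, tri/tetra-antennary (1/3 of complex mass)
    "N5H6S3",     0.060,
    "N5H6S2",     0.045,
    "N5H6F1S2",   0.035,
    "N5H6F1S3",   0.025,
    "N6H7S4",     0.020,
    "N6H7F1S3",   0.013,
    # oligo-mannose (incl. fucosylated species)
    "N2H8",       0.070,
    "N2H7",       0.060,
    "N2H6",       0.050,
    "N2H5",       0.045,
    "N2H9",       0.040,
    "N2H6F1",     0.015,
    "N2H7F1",     0.011,
    # hybrid
    "N3H6",       0.035,
    "N3H6S1",     0.030,
    "N3H7",       0.020,
    "N3H5F1",     0.015,
    "N4H7S1",     0.011
  )
  pool$weight <- pool$weight / sum(pool$weight)
  pool$subtype <- as.character(classify_glycans(pool$glycan)$subtype)
  pool
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale experiment of roughly 1,000 glycopeptides
#' (250 glycoproteins, 1 + Poisson(1) sites each, 1 + Poisson(1) glycans
#' per site), negative-binomial PSM counts with mean 8, log2 reporter noise
#' 0.25, glycopeptide baselines spanning about four orders of magnitude,
#' unequal channel loadings, and planted effect blocks: 5% common 4-fold
#' tumor changes (half up, half down), 3% each low- and high-AFP-unique
#' 2-fold increases, 3% protein-driven 4-fold changes and 2% pure
#' occupancy shifts.
#'
#' @param n_glycoproteins Number of glycoproteins in the catalog.
#' @param mean_extra_sites,mean_extra_glycans Poisson means for extra
#'   glycosites per protein and extra glycans per site (each at least 1).
#' @param pool Composition pool (see [default_glycan_pool()]).
#' @param design Channel design; defaults to [hcc_afp_design()].
#' @param psm_mean,psm_size Negative-binomial mean and size of PSM counts
#'   per glycopeptide.
#' @param protein_psm_mean,protein_psm_size Same for protein PSM counts per
#'   protein.
#' @param sigma Log2 reporter noise standard deviation per PSM x channel.
#' @param baseline_log2_mean,baseline_log2_sd Log2 abundance baseline
#'   distribution across glycopeptides/proteins.
#' @param psm_scatter_sd Log2 spread of per-PSM precursor intensity around
#'   the feature baseline (cancels in within-PSM channel ratios).
#' @param channel_loadings Named positive multipliers per channel,
#'   simulating unequal channel loading for normalization to remove.
#' @param frac_common_up,frac_common_down,frac_unique_low,frac_unique_high,frac_protein_driven,frac_occupancy_shift
#'   Fractions of glycopeptides per planted effect block (must sum to <= 1).
#' @param fold_common,fold_unique,fold_protein,fold_occupancy Fold sizes of
#'   the planted effects.
#' @param endomembrane_fraction Fraction of proteins marked
#'   endomembrane-like; their sites preferentially draw oligo-mannose
#'   compositions (factor `oligo_bias`), mimicking the ER/Golgi residence
#'   of high-mannose glycans.
#' @param oligo_bias Weight multiplier for oligo-mannose compositions at
#'   endomembrane-like sites.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_glycoproteins = 250,
                       mean_extra_sites = 1,
                       mean_extra_glycans = 1,
                       pool = default_glycan_pool(),
                       design = hcc_afp_design(),
                       psm_mean = 8, psm_size = 8,
                       protein_psm_mean = 30, protein_psm_size = 10,
                       sigma = 0.25,
                       baseline_log2_mean = 20, baseline_log2_sd = 3.3,
                       psm_scatter_sd = 1,
                       channel_loadings = c(`126` = 1, `127N` = 1.25,
                                            `128C` = 0.8, `129N` = 1.1),
                       frac_common_up = 0.025, frac_common_down = 0.025,
                       frac_unique_low = 0.03, frac_unique_high = 0.03,
                       frac_protein_driven = 0.03,
                       frac_occupancy_shift = 0.02,
                       fold_common = 4, fold_unique = 2,
                       fold_protein = 4, fold_occupancy = 2,
                       endomembrane_fraction = 0.35, oligo_bias = 3,
                       seed = 1) {
  cfg <- list(
    n_glycoproteins = as.integer(n_glycoproteins),
    mean_extra_sites = mean_extra_sites,
    mean_extra_glycans = mean_extra_glycans,
    pool = as_tibble(pool), design = design,
    psm_mean = psm_mean, psm_size = psm_size,
    protein_psm_mean = protein_psm_mean,
    protein_psm_size = protein_psm_size,
    sigma = sigma,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    psm_scatter_sd = psm_scatter_sd,
    channel_loadings = channel_loadings,
    frac_common_up = frac_common_up, frac_common_down = frac_common_down,
    frac_unique_low = frac_unique_low, frac_unique_high = frac_unique_high,
    frac_protein_driven = frac_protein_driven,
    frac_occupancy_shift = frac_occupancy_shift,
    fold_common = fold_common, fold_unique = fold_unique,
    fold_protein = fold_protein, fold_occupancy = fold_occupancy,
    endomembrane_fraction = endomembrane_fraction, oligo_bias = oligo_bias,
    seed = as.integer(seed)
  )
  fracs <- c(frac_common_up, frac_common_down, frac_unique_low,
             frac_unique_high, frac_protein_driven, frac_occupancy_shift)
  if (any(fracs < 0) || sum(fracs) > 1) {
    abort("Effect-block fractions must be non-negative and sum to <= 1.")
  }
  pos <- c(n_glycoproteins = n_glycoproteins, psm_mean = psm_mean,
           psm_size = psm_size, protein_psm_mean = protein_psm_mean,
           protein_psm_size = protein_psm_size,
           baseline_log2_sd = baseline_log2_sd)
  bad <- names(pos)[pos <= 0]
  if (length(bad)) {
    abort(sprintf("Invalid config field(s), must be positive: %s",
                  paste(bad, collapse = ", ")))
  }
  if (sigma < 0 || psm_scatter_sd < 0 || mean_extra_sites < 0 ||
        mean_extra_glycans < 0) {
    abort("sigma, psm_scatter_sd and Poisson means must be non-negative.")
  }
  if (!setequal(names(channel_loadings), design$channels) ||
        any(channel_loadings <= 0)) {
    abort("`channel_loadings` must name a positive factor per channel.")
  }
  if (any(c(fold_common, fold_unique, fold_protein, fold_occupancy) <= 1)) {
    abort("Planted fold sizes must exceed 1.")
  }
  stopifnot(all(c("glycan", "weight") %in% names(cfg$pool)),
            all(cfg$pool$weight >= 0), sum(cfg$pool$weight) > 0)
  structure(cfg, class = "sim_config")
}

#' Read a simulation/threshold configuration from YAML
#'
#' Keys mirror the [sim_config()] arguments plus the pipeline thresholds
#' (`min_psms`, `common_cutoff`, `unique_cutoff`); unknown keys are an
#' error. Threshold keys default to 5, 2 and 1.5.
#'
#' @param path YAML file path.
#' @return List with elements `config` (a `sim_config`) and `thresholds`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  thresholds <- list(
    min_psms = raw$min_psms %||% 5,
    common_cutoff = raw$common_cutoff %||% 2,
    unique_cutoff = raw$unique_cutoff %||% 1.5
  )
  raw$min_psms <- raw$common_cutoff <- raw$unique_cutoff <- NULL
  if (!is.null(raw$channel_loadings)) {
    raw$channel_loadings <- unlist(raw$channel_loadings)
  }
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  list(config = do.call(sim_config, raw), thresholds = thresholds)
}

random_peptide <- function(n) {
  aas <- strsplit("ACDEFGHIKLMPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste0(
      paste(sample(aas, sample(4:8, 1), replace = TRUE), collapse = ""),
      "N#", sample(setdiff(aas, "P"), 1), sample(c("S", "T"), 1),
      paste(sample(aas, sample(2:6, 1), replace = TRUE), collapse = "")
    )
  }, character(1))
}

#' Generate a glycopeptide catalog
#'
#' Draws the catalog structure only (no intensities): proteins, 1-based
#' glycosite positions, tryptic-style peptides with the glycosylated
#' asparagine marked `N#`, and a composition per site-glycan slot sampled
#' from the pool. Sites on endomembrane-like proteins draw oligo-mannose
#' compositions with `oligo_bias`-fold upweighting. Deterministic for a
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Tibble: `feature_id`, `protein`, `glycosite`, `peptide`,
#'   `glycan`, `endomembrane`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, generate_catalog_impl(config))
}

generate_catalog_impl <- function(config) {
  nprot <- config$n_glycoproteins
  proteins <- sprintf("GP%04d", seq_len(nprot))
  endo <- stats::runif(nprot) < config$endomembrane_fraction
  n_sites <- 1L + rpois(nprot, config$mean_extra_sites)

  pool <- config$pool
  is_oligo <- classify_glycans(pool$glycan)$subtype == "oligo-mannose"

  # Endomembrane-like sites draw oligo-mannose with `oligo_bias`-fold
  # upweighting; the remaining sites are downweighted so the marginal
  # oligo-mannose draw probability stays at the pool's oligo weight.
  w_o <- sum(pool$weight[is_oligo]) / sum(pool$weight)
  f <- config$endomembrane_fraction
  if (w_o <= 0 || w_o >= 1 || f <= 0) {
    # single-class pools (or no endomembrane sites): no biasing possible
    bias_endo <- 1
    bias_non <- 1
  } else {
    bias_endo <- config$oligo_bias
    p_endo <- bias_endo * w_o / (bias_endo * w_o + (1 - w_o))
    p_non <- if (f < 1) (w_o - f * p_endo) / (1 - f) else w_o
    if (p_non <= 0 || p_non >= 1) {
      abort(paste0("endomembrane_fraction/oligo_bias leave no ",
                   "oligo-mannose weight for non-endomembrane sites."))
    }
    bias_non <- p_non * (1 - w_o) / (w_o * (1 - p_non))
  }

  rows <- vector("list", nprot)
  for (i in seq_len(nprot)) {
    positions <- sort(sample(30:800, n_sites[i]))
    w <- pool$weight *
      ifelse(is_oligo, if (endo[i]) bias_endo else bias_non, 1)
    site_rows <- lapply(seq_along(positions), function(j) {
      k <- 1L + rpois(1, config$mean_extra_glycans)
      k <- min(k, nrow(pool))
      glycans <- sample(pool$glycan, k, prob = w)
      tibble(
        protein = proteins[i], glycosite = positions[j],
        peptide = random_peptide(1), glycan = glycans,
        endomembrane = endo[i]
      )
    })
    rows[[i]] <- dplyr::bind_rows(site_rows)
  }
  out <- dplyr::bind_rows(rows)
  out$feature_id <- paste(out$protein, out$glycosite, out$glycan, sep = "|")
  out[c("feature_id", "protein", "glycosite", "peptide", "glycan",
        "endomembrane")]
}

# Assign planted-effect labels: protein-level blocks claim whole proteins
# (every glycopeptide of an affected protein shares its protein's change);
# glycopeptide-level blocks are drawn from the remaining proteins.
assign_truth_labels <- function(catalog, config) {
  n_gp <- nrow(catalog)
  gp_per_protein <- table(catalog$protein)
  prots <- sample(names(gp_per_protein))

  take_proteins <- function(prots, target_gp) {
    if (target_gp <= 0 || !length(prots)) return(character())
    cum <- cumsum(as.integer(gp_per_protein[prots]))
    hit <- which(cum >= target_gp)
    prots[seq_len(if (length(hit)) hit[1] else length(prots))]
  }
  prot_driven <- take_proteins(prots, round(config$frac_protein_driven * n_gp))
  prots <- setdiff(prots, prot_driven)
  occ_shift <- take_proteins(prots, round(config$frac_occupancy_shift * n_gp))
  prots <- setdiff(prots, occ_shift)

  label <- rep("null", n_gp)
  label[catalog$protein %in% prot_driven] <- "protein-driven"
  label[catalog$protein %in% occ_shift] <- "occupancy-shift"

  free <- which(label == "null")
  n_blocks <- round(n_gp * c(config$frac_common_up, config$frac_common_down,
                             config$frac_unique_low, config$frac_unique_high))
  picks <- sample(free, min(sum(n_blocks), length(free)))
  block_names <- rep(c("common-up", "common-down", "lowAFP-unique",
                       "highAFP-unique"), n_blocks)
  label[picks] <- block_names[seq_along(picks)]
  factor(label, levels = SIM_LABELS)
}

# Per-group planted log2 effects for each glycopeptide (glyco level) and
# each protein (protein level).
#
# Protein-driven effects model a protein whose expression differs between
# the low- and high-AFP patient groups in both tumor and paracancer tissue
# (the glycopeptide moves with it; occupancy effect zero) — the case the
# paracancer protein/occupancy gates of the unique cascade must reject.
# Occupancy-shift effects model a tumor-specific protein increase with the
# glycopeptide flat (occupancy decrease), invisible to the glycopeptide-
# level cascades but visible at the occupancy level.
planted_effects <- function(catalog, label, config) {
  groups <- unique(unname(config$design$groups))
  tumor <- c("tumor_lowAFP", "tumor_highAFP")
  glyco <- matrix(0, nrow(catalog), length(groups),
                  dimnames = list(catalog$feature_id, groups))
  proteins <- unique(catalog$protein)
  prot <- matrix(0, length(proteins), length(groups),
                 dimnames = list(proteins, groups))

  glyco[label == "common-up", tumor] <- log2(config$fold_common)
  glyco[label == "common-down", tumor] <- -log2(config$fold_common)
  glyco[label == "lowAFP-unique", "tumor_lowAFP"] <- log2(config$fold_unique)
  glyco[label == "highAFP-unique", "tumor_highAFP"] <- log2(config$fold_unique)

  pd <- unique(catalog$protein[label == "protein-driven"])
  if (length(pd)) {
    side_low <- stats::runif(length(pd)) < 0.5
    low_grp <- c("tumor_lowAFP", "para_lowAFP")
    high_grp <- c("tumor_highAFP", "para_highAFP")
    prot[pd[side_low], low_grp] <- log2(config$fold_protein)
    prot[pd[!side_low], high_grp] <- log2(config$fold_protein)
  }
  os <- unique(catalog$protein[label == "occupancy-shift"])
  prot[os, tumor] <- log2(config$fold_occupancy)
  glyco[label == "occupancy-shift", tumor] <- -log2(config$fold_occupancy)

  list(glyco = glyco, protein = prot)
}

truth_table <- function(catalog, label, eff, config) {
  cmp <- config$design$comparisons
  groups_of <- config$design$groups
  out <- catalog[c("feature_id", "protein", "glycosite", "glycan")]
  out$label <- label
  for (i in seq_len(nrow(cmp))) {
    gn <- groups_of[[cmp$numerator[i]]]
    gd <- groups_of[[cmp$denominator[i]]]
    d_prot <- eff$protein[catalog$protein, gn] -
      eff$protein[catalog$protein, gd]
    d_glyco <- eff$glyco[, gn] - eff$glyco[, gd]
    out[[paste0("true_protein_", cmp$comparison[i])]] <- unname(d_prot)
    out[[paste0("true_occupancy_", cmp$comparison[i])]] <- unname(d_glyco)
    out[[paste0("true_glyco_", cmp$comparison[i])]] <-
      unname(d_prot + d_glyco)
  }
  as_tibble(out)
}

draw_psm_intensities <- function(ids, n_psms, base_log2, group_effect,
                                 config, prefix) {
  keep <- n_psms > 0
  idx <- rep(which(keep), n_psms[keep])
  n_rows <- length(idx)
  scatter <- rnorm(n_rows, 0, config$psm_scatter_sd)
  out <- tibble(.idx = idx,
                spectrum_id = sprintf("%s%07d", prefix, seq_len(n_rows)))
  design <- config$design
  for (ch in design$channels) {
    g <- design$groups[[ch]]
    mu <- base_log2[idx] + scatter + group_effect[idx, g] +
      log2(config$channel_loadings[[ch]])
    out[[paste0("intensity_", ch)]] <-
      2^(mu + rnorm(n_rows, 0, config$sigma))
  }
  out
}

#' Simulate a pooled isobaric glycoproteomics experiment
#'
#' Generates the glycopeptide catalog, plants the configured effect blocks,
#' and draws glyco-PSM and protein-PSM tables in the exact schema
#' [read_psm_table()] produces, together with the ground truth (label and
#' true log2 effect per comparison at the glycopeptide, protein and
#' occupancy levels). Per-PSM channel intensities are
#' `2^(baseline + PSM scatter + group effects + log2 loading + N(0, sigma))`.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `glyco_sim` list: `glyco_psms`, `protein_psms`, `truth`,
#'   `catalog`, `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, {
    catalog <- generate_catalog_impl(config)
    label <- assign_truth_labels(catalog, config)
    eff <- planted_effects(catalog, label, config)
    truth <- truth_table(catalog, label, eff, config)

    base_gp <- rnorm(nrow(catalog), config$baseline_log2_mean,
                     config$baseline_log2_sd)
    n_psms <- rnbinom(nrow(catalog), size = config$psm_size,
                      mu = config$psm_mean)
    glyco_eff_total <- eff$glyco + eff$protein[catalog$protein, , drop = FALSE]
    glyco_psms <- draw_psm_intensities(
      catalog$feature_id, n_psms, base_gp, glyco_eff_total, config, "GS"
    )
    glyco_psms <- dplyr::bind_cols(
      catalog[glyco_psms$.idx, c("peptide", "protein", "glycosite", "glycan")],
      glyco_psms[setdiff(names(glyco_psms), ".idx")]
    )[c("spectrum_id", "peptide", "protein", "glycosite", "glycan",
        paste0("intensity_", config$design$channels))]
    glyco_psms$incomplete <- FALSE

    proteins <- unique(catalog$protein)
    base_prot <- rnorm(length(proteins), config$baseline_log2_mean,
                       config$baseline_log2_sd)
    n_prot_psms <- rnbinom(length(proteins), size = config$protein_psm_size,
                           mu = config$protein_psm_mean)
    prot_psms <- draw_psm_intensities(
      proteins, n_prot_psms, base_prot,
      eff$protein[proteins, , drop = FALSE], config, "PS"
    )
    prot_psms$protein <- proteins[prot_psms$.idx]
    prot_psms$peptide <- paste0("PEP_", prot_psms$protein)
    prot_psms <- prot_psms[c("spectrum_id", "peptide", "protein",
                             paste0("intensity_", config$design$channels))]
    prot_psms$incomplete <- FALSE

    structure(
      list(glyco_psms = as_tibble(glyco_psms),
           protein_psms = as_tibble(prot_psms),
           truth = truth, catalog = catalog, config = config),
      class = "glyco_sim"
    )
  })
}

#' @export
print.glyco_sim <- function(x, ...) {
  cat("<glyco_sim> ", nrow(x$catalog), " glycopeptides on ",
      length(unique(x$catalog$protein)), " glycoproteins; ",
      nrow(x$glyco_psms), " glyco PSMs, ", nrow(x$protein_psms),
      " protein PSMs (seed ", x$config$seed, ")\n", sep = "")
  print(table(x$truth$label))
  invisible(x)
}

#' Run the full quantitation and differential pipeline
#'
#' Normalization factors from the protein PSMs, median-ratio quantitation
#' of glycopeptides and proteins, occupancy ratios, and both differential
#' cascades.
#'
#' @param x A `glyco_sim` object, or a glyco-PSM table (then
#'   `protein_psms` and `design` are required).
#' @param protein_psms Protein PSM table (ignored for `glyco_sim` input).
#' @param design A [channel_design()] (ignored for `glyco_sim` input).
#' @param min_psms Minimum complete PSMs per quantified feature.
#' @param common_cutoff,unique_cutoff Fold cutoffs for the two cascades.
#' @return List with `factors`, `glyco`, `protein`, `occupancy`, `calls`.
#' @export
run_pipeline <- function(x, protein_psms = NULL, design = NULL,
                         min_psms = 5, common_cutoff = 2,
                         unique_cutoff = 1.5) {
  if (inherits(x, "glyco_sim")) {
    protein_psms <- x$protein_psms
    design <- x$config$design
    x <- x$glyco_psms
  }
  if (is.null(protein_psms) || is.null(design)) {
    abort("Supply `protein_psms` and `design` for raw PSM-table input.")
  }
  factors <- compute_channel_factors(protein_psms, design)
  glyco <- quantify_features(x, factors, design, min_psms = min_psms,
                             kind = "glyco")
  protein <- quantify_features(protein_psms, factors, design,
                               min_psms = min_psms, kind = "protein")
  occupancy <- occupancy_ratios(glyco, protein)
  calls <- differential_calls(glyco, protein, occupancy,
                              common_cutoff = common_cutoff,
                              unique_cutoff = unique_cutoff)
  list(factors = factors, glyco = glyco, protein = protein,
       occupancy = occupancy, calls = calls)
}

#' Score differential calls against planted ground truth
#'
#' Per planted label (common-up, common-down, lowAFP-unique,
#' highAFP-unique): true/false positives, false negatives, precision and
#' recall. Recall is computed over the planted features that survived
#' quantitation (i.e. appear in `calls`), since features failing the
#' minimum-PSM filter are invisible to the cascades by design; `n_truth`
#' and `n_evaluable` report both denominators. Protein-driven and
#' occupancy-shift truths count as negatives for every call label.
#'
#' @param calls A `glyco_calls` table.
#' @param truth Ground-truth table from [simulate_experiment()].
#' @return Tibble: `label`, `n_truth`, `n_evaluable`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
evaluate_recovery <- function(calls, truth) {
  calls <- as_tibble(calls)
  truth <- as_tibble(truth)
  if (!all(calls$feature_id %in% truth$feature_id)) {
    abort("`calls` contains feature ids absent from `truth`.")
  }
  truth$evaluable <- truth$feature_id %in% calls$feature_id
  called <- list(
    "common-up" = calls$feature_id[calls$common_label == "up"],
    "common-down" = calls$feature_id[calls$common_label == "down"],
    "lowAFP-unique" =
      calls$feature_id[calls$unique_label == "lowAFP-unique"],
    "highAFP-unique" =
      calls$feature_id[calls$unique_label == "highAFP-unique"]
  )
  purrr::imap_dfr(called, function(pos_ids, lab) {
    true_ids <- truth$feature_id[truth$label == lab]
    eval_ids <- truth$feature_id[truth$label == lab & truth$evaluable]
    tp <- length(intersect(pos_ids, true_ids))
    fp <- length(setdiff(pos_ids, true_ids))
    fn <- length(setdiff(eval_ids, pos_ids))
    tibble(
      label = lab,
      n_truth = length(true_ids),
      n_evaluable = length(eval_ids),
      tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) {
        tp / (tp + fn)
      } else if (length(true_ids) > 0) 0 else NA_real_
    )
  })
}
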