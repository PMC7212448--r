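# Fold-change cascades over quantified glycopeptides.
#
# The pooled one-channel-per-group design carries no replicate variance, so
# change calls are fold-change thresholds, justified empirically by the
# stability of the paracancer-vs-paracancer null comparison (the within-
# fold fraction). Two cascades are implemented:
#   * commonly altered: >= `cutoff`-fold tumor/paracancer change, in the
#     same direction, in BOTH AFP groups (default 2-fold);
#   * group-unique: >= `cutoff`-fold difference between low- and high-AFP
#     tumors while the paracancer low-vs-high comparison stays within the
#     cutoff at all three levels — glycopeptide, parent protein, and
#     glycosylation occupancy (default 1.5-fold).
# Boundaries are inclusive on both sides: |log2 r| >= log2(cutoff) counts
# as changed, <= log2(cutoff) counts as stable.

#' Fraction of features within a fold-change band
#'
#' The fraction of log2 ratios with absolute value at most `log2(k)`; used
#' to report the stability of null comparisons and justify fold cutoffs.
#'
#' @param log2_ratios Numeric vector of log2 ratios (NAs dropped).
#' @param k Fold cutoff, > 1.
#' @return A single fraction in \[0, 1\].
#' @examples
#' within_fold_fraction(log2(c(1, 3, 0.4, 1.9)), 2) # 0.5
#' @export
within_fold_fraction <- function(log2_ratios, k) {
  if (k <= 1) abort("`k` must exceed 1.")
  x <- log2_ratios[!is.na(log2_ratios)]
  if (!length(x)) abort("No ratios supplied.")
  mean(abs(x) <= log2(k))
}

#' Call commonly altered glycopeptides
#'
#' Labels a feature `up` when both tumor/paracancer log2 ratios are at
#' least `log2(cutoff)`, `down` when both are at most `-log2(cutoff)`, and
#' `none` otherwise. Features changed by at least the cutoff in both groups
#' but in opposite directions are labelled `none` and flagged `discordant`
#' for separate reporting.
#'
#' @param features A `glyco_quant` tibble of glycopeptides.
#' @param cutoff Fold cutoff, > 1 (default 2).
#' @param comparisons Names of the two tumor-vs-paracancer comparisons.
#' @return The feature identifiers plus `common_label` (factor up/down/none)
#'   and logical `discordant`.
#' @export
call_common_altered <- function(features, cutoff = 2,
                                comparisons = c("tumor_vs_para_lowAFP",
                                                "tumor_vs_para_highAFP")) {
  if (cutoff <= 1) abort("`cutoff` must exceed 1.")
  stopifnot(length(comparisons) == 2)
  x <- as_tibble(features)
  r1 <- x[[paste0("log2_", comparisons[1])]]
  r2 <- x[[paste0("log2_", comparisons[2])]]
  if (is.null(r1) || is.null(r2)) {
    abort("`features` lacks the requested comparison ratio columns.")
  }
  lk <- log2(cutoff)
  up <- r1 >= lk & r2 >= lk
  down <- r1 <= -lk & r2 <= -lk
  discordant <- (abs(r1) >= lk & abs(r2) >= lk) & !up & !down
  out <- x[intersect(c("feature_id", "protein", "glycosite", "glycan"),
                     names(x))]
  out$common_label <- factor(
    dplyr::case_when(up ~ "up", down ~ "down", TRUE ~ "none"),
    levels = c("up", "down", "none")
  )
  out$discordant <- discordant
  out
}

#' Call AFP-group-unique glycopeptides
#'
#' A feature is `lowAFP-unique` when the low- vs high-AFP tumor ratio is at
#' least `cutoff`-fold (numerator: low-AFP tumor) while the paired
#' paracancer low-vs-high comparison stays within the cutoff at all three
#' levels — the glycopeptide ratio, the parent-protein ratio, and the
#' glycosylation-occupancy change. `highAFP-unique` is symmetric (at least
#' `cutoff`-fold in the other direction). Features whose parent protein was
#' not quantified cannot be gated and are ineligible (`none`).
#'
#' @param features Quantified glycopeptides (`glyco_quant`).
#' @param protein_features Quantified proteins against the same design.
#' @param occupancy Occupancy table from [occupancy_ratios()].
#' @param cutoff Fold cutoff, > 1 (default 1.5).
#' @param tumor_comparison Name of the tumor low-vs-high comparison.
#' @param para_comparison Name of the paracancer low-vs-high comparison.
#' @return Feature identifiers plus `unique_label` (factor lowAFP-unique /
#'   highAFP-unique / none), `parent_protein_quantified`, and the three
#'   paracancer-stability gate flags `stable_para_glyco`,
#'   `stable_para_protein`, `stable_para_occupancy`.
#' @export
call_group_unique <- function(features, protein_features, occupancy,
                              cutoff = 1.5,
                              tumor_comparison = "tumor_lowAFP_vs_highAFP",
                              para_comparison = "para_lowAFP_vs_highAFP") {
  if (cutoff <= 1) abort("`cutoff` must exceed 1.")
  x <- as_tibble(features)
  lk <- log2(cutoff)
  tum <- x[[paste0("log2_", tumor_comparison)]]
  para_gp <- x[[paste0("log2_", para_comparison)]]
  if (is.null(tum) || is.null(para_gp)) {
    abort("`features` lacks the requested comparison ratio columns.")
  }

  prot <- as_tibble(protein_features)
  prot_para <- setNames(prot[[paste0("log2_", para_comparison)]],
                        prot$protein)
  para_prot <- unname(prot_para[x$protein])

  occ <- as_tibble(occupancy)
  occ_para <- setNames(occ[[paste0("occupancy_", para_comparison)]],
                       occ$feature_id)
  para_occ <- unname(occ_para[x$feature_id])

  eligible <- !is.na(para_prot)
  stable_gp <- abs(para_gp) <= lk
  stable_prot <- !is.na(para_prot) & abs(para_prot) <= lk
  stable_occ <- !is.na(para_occ) & abs(para_occ) <= lk
  gate <- stable_gp & stable_prot & stable_occ

  label <- dplyr::case_when(
    gate & tum >= lk ~ "lowAFP-unique",
    gate & tum <= -lk ~ "highAFP-unique",
    TRUE ~ "none"
  )
  out <- x[intersect(c("feature_id", "protein", "glycosite", "glycan"),
                     names(x))]
  out$unique_label <- factor(
    label, levels = c("lowAFP-unique", "highAFP-unique", "none")
  )
  out$parent_protein_quantified <- eligible
  out$stable_para_glyco <- stable_gp
  out$stable_para_protein <- stable_prot
  out$stable_para_occupancy <- stable_occ
  out
}

#' Run both differential cascades on a quantified experiment
#'
#' Convenience wrapper joining [call_common_altered()] and
#' [call_group_unique()] into one table per glycopeptide, carrying all
#' comparison ratios and occupancy values alongside the labels.
#'
#' @inheritParams call_group_unique
#' @param common_cutoff Fold cutoff for the commonly-altered cascade.
#' @param unique_cutoff Fold cutoff for the group-unique cascade.
#' @return A `glyco_calls` tibble.
#' @export
differential_calls <- function(features, protein_features, occupancy,
                               common_cutoff = 2, unique_cutoff = 1.5) {
  design <- attr(features, "design")
  common <- call_common_altered(features, cutoff = common_cutoff)
  uniq <- call_group_unique(features, protein_features, occupancy,
                            cutoff = unique_cutoff)
  out <- as_tibble(features) |>
    dplyr::left_join(
      common[c("feature_id", "common_label", "discordant")],
      by = "feature_id"
    ) |>
    dplyr::left_join(
      uniq[setdiff(names(uniq),
                   c("protein", "glycosite", "glycan"))],
      by = "feature_id"
    ) |>
    dplyr::left_join(
      as_tibble(occupancy)[c("feature_id", occupancy_cols(design))],
      by = "feature_id"
    )
  structure(out,
    class = c("glyco_calls", setdiff(class(out), "glyco_quant")),
    design = design,
    common_cutoff = common_cutoff, unique_cutoff = unique_cutoff
  )
}

#' Glycan-feature frequencies among changed glycopeptide sets
#'
#' Cross-tabulates the changed sets from the two cascades (common-up,
#' common-down, lowAFP-unique, highAFP-unique) against glycan feature
#' classes: subtype, antenna count, sialic-acid count, core-fucose status
#' and bisecting status.
#'
#' @param calls A `glyco_calls` table (or any table with `glycan`,
#'   `common_label`, `unique_label`).
#' @param classes Optional precomputed [classify_glycans()] table for the
#'   call glycans; classified on the fly when omitted.
#' @return A tibble with columns `set`, `family`, `level`, `n`.
#' @export
summarize_changed_features <- function(calls, classes = NULL) {
  x <- as_tibble(calls)
  if (is.null(classes)) classes <- classify_glycans(x$glycan)
  stopifnot(nrow(classes) == nrow(x))
  feat <- tibble(
    subtype = as.character(classes$subtype),
    antennae = ifelse(is.na(classes$antennae), "not complex",
                      as.character(classes$antennae)),
    n_sia = as.character(classes$n_sia),
    core_fucose = ifelse(classes$n_core_fuc > 0, "core-fucosylated",
                         "no core fucose"),
    bisecting = as.character(classes$bisecting)
  )
  sets <- list(
    `common-up` = x$common_label == "up",
    `common-down` = x$common_label == "down",
    `lowAFP-unique` = x$unique_label == "lowAFP-unique",
    `highAFP-unique` = x$unique_label == "highAFP-unique"
  )
  purrr::imap_dfr(sets, function(sel, set_name) {
    sub <- feat[which(sel), , drop = FALSE]
    purrr::imap_dfr(sub, function(vals, family) {
      if (!length(vals)) {
        return(tibble(set = set_name, family = family,
                      level = character(), n = integer()))
      }
      tab <- table(vals)
      tibble(set = set_name, family = family,
             level = names(tab), n = as.integer(tab))
    })
  })
}

#' @method glance glyco_calls
#' @export
glance.glyco_calls <- function(x, ...) {
  tibble(
    n_quantified = nrow(x),
    n_common_up = sum(x$common_label == "up"),
    n_common_down = sum(x$common_label == "down"),
    n_common_altered = sum(x$common_label != "none"),
    n_discordant = sum(x$discordant),
    n_low_unique = sum(x$unique_label == "lowAFP-unique"),
    n_high_unique = sum(x$unique_label == "highAFP-unique"),
    pct_common_altered = percent_of(sum(x$common_label != "none"), nrow(x))
  )
}
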