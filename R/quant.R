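# Reporter-channel normalization and median-ratio quantitation.
#
# Normalization factors are derived from the global-proteome PSMs only:
# for each complete protein PSM, each channel's intensity is divided by the
# geometric mean of that PSM's intensities across channels; the per-channel
# median of these scale-free ratios is the channel's loading factor.
# Dividing any PSM table by these factors equalizes channel medians, which
# removes per-channel loading/labelling differences under the usual
# assumption that most proteins do not change.

complete_psms <- function(psms) {
  if (!"incomplete" %in% names(psms)) return(as_tibble(psms))
  dplyr::filter(as_tibble(psms), !.data$incomplete)
}

#' Proteome-derived channel normalization factors
#'
#' @param protein_psms Protein PSM table (see [read_psm_table()] or
#'   [simulate_experiment()]) with one `intensity_<channel>` column per
#'   design channel. Incomplete rows are ignored.
#' @param design A [channel_design()].
#' @return A tibble with one row per channel: `channel`, `factor`
#'   (positive; dividing that channel's intensities by it equalizes channel
#'   medians across the proteome).
#' @export
compute_channel_factors <- function(protein_psms, design) {
  psms <- complete_psms(protein_psms)
  cols <- intensity_cols(design)
  stopifnot(all(cols %in% names(psms)))
  if (nrow(psms) == 0) {
    abort("No complete protein PSMs to derive normalization factors from.")
  }
  m <- as.matrix(psms[cols])
  gm <- exp(rowMeans(log(m)))
  factors <- apply(m / gm, 2, median)
  tibble(channel = design$channels, factor = as.numeric(factors))
}

feature_key <- function(psms, kind) {
  if (kind == "glyco") {
    paste(psms$protein, psms$glycosite, psms$glycan, sep = "|")
  } else {
    psms$protein
  }
}

#' Median-ratio quantitation of glycopeptides or proteins
#'
#' Groups PSMs into features (glycopeptide = protein + glycosite + glycan;
#' protein = accession), keeps features with at least `min_psms` complete
#' PSMs, and summarizes each channel as the median of its normalized PSM
#' intensities. One log2 ratio per named design comparison is computed from
#' the channel medians.
#'
#' @param psms PSM table (glyco or protein) with `intensity_<channel>`
#'   columns; incomplete rows are excluded from quantitation.
#' @param factors Channel factors from [compute_channel_factors()].
#' @param design A [channel_design()].
#' @param min_psms Minimum complete PSMs per feature (default 5, the
#'   conventional floor for reliable reporter-ion ratios).
#' @param kind `"glyco"` or `"protein"`.
#' @return A `glyco_quant` tibble: feature identifiers, `n_psms`, one
#'   `value_<channel>` column per channel (normalized median intensity,
#'   strictly positive) and one `log2_<comparison>` column per comparison.
#' @export
quantify_features <- function(psms, factors, design, min_psms = 5,
                              kind = c("glyco", "protein")) {
  kind <- match.arg(kind)
  if (min_psms < 1) abort("`min_psms` must be at least 1.")
  psms <- complete_psms(psms)
  cols <- intensity_cols(design)
  stopifnot(all(cols %in% names(psms)))
  fac <- setNames(factors$factor, factors$channel)[design$channels]
  if (any(is.na(fac) | fac <= 0)) {
    abort("`factors` must supply a positive factor for every channel.")
  }

  psms$feature_id <- feature_key(psms, kind)
  for (i in seq_along(cols)) {
    psms[[cols[i]]] <- psms[[cols[i]]] / fac[i]
  }

  id_cols <- if (kind == "glyco") {
    c("feature_id", "protein", "glycosite", "glycan")
  } else {
    c("feature_id", "protein")
  }
  out <- psms |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::summarise(
      n_psms = dplyr::n(),
      dplyr::across(dplyr::all_of(cols), median,
                    .names = "value_{sub('intensity_', '', .col)}"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_psms >= min_psms) |>
    dplyr::arrange(.data$feature_id)

  for (i in seq_len(nrow(design$comparisons))) {
    cmp <- design$comparisons[i, ]
    out[[paste0("log2_", cmp$comparison)]] <-
      log2(out[[paste0("value_", cmp$numerator)]] /
             out[[paste0("value_", cmp$denominator)]])
  }
  structure(out,
    class = c("glyco_quant", class(out)),
    design = design, min_psms = min_psms, kind = kind
  )
}

#' Glycosylation-occupancy ratios
#'
#' Site-specific glycopeptide ratios confound protein-expression change
#' with glycosylation change. The occupancy log2 change of a glycopeptide
#' for a comparison is its log2 ratio minus the log2 ratio of its parent
#' protein (matched by accession): zero for purely protein-driven changes,
#' equal to the glycopeptide ratio for purely glycosylation-level changes.
#'
#' @param glyco_features Quantified glycopeptides ([quantify_features()]
#'   with `kind = "glyco"`).
#' @param protein_features Quantified proteins (`kind = "protein"`),
#'   quantified against the same design.
#' @return A tibble with `feature_id`, `protein`, logical
#'   `parent_protein_quantified`, and one `occupancy_<comparison>` column
#'   per comparison (NA when the parent protein did not pass quantitation).
#' @export
occupancy_ratios <- function(glyco_features, protein_features) {
  design <- attr(glyco_features, "design")
  lcols <- log2_cols(design)
  prot <- as_tibble(protein_features)[c("protein", lcols)]
  names(prot)[-1] <- paste0(".prot_", lcols)
  out <- as_tibble(glyco_features)[c("feature_id", "protein", lcols)] |>
    dplyr::left_join(prot, by = "protein")
  out$parent_protein_quantified <-
    !is.na(out[[paste0(".prot_", lcols[1])]])
  for (lc in lcols) {
    out[[sub("^log2_", "occupancy_", lc)]] <-
      out[[lc]] - out[[paste0(".prot_", lc)]]
  }
  out[c("feature_id", "protein", "parent_protein_quantified",
        sub("^log2_", "occupancy_", lcols))]
}

#' @method tidy glyco_quant
#' @export
tidy.glyco_quant <- function(x, ...) {
  design <- attr(x, "design")
  as_tibble(x) |>
    dplyr::select(dplyr::all_of(c("feature_id", "n_psms", log2_cols(design)))) |>
    tidyr::pivot_longer(
      dplyr::all_of(log2_cols(design)),
      names_to = "comparison", names_prefix = "log2_",
      values_to = "log2_ratio"
    )
}

#' @method glance glyco_quant
#' @export
glance.glyco_quant <- function(x, ...) {
  tibble(
    kind = attr(x, "kind"),
    n_features = nrow(x),
    n_psms_used = sum(x$n_psms),
    min_psms = attr(x, "min_psms"),
    median_psms_per_feature = median(x$n_psms)
  )
}
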