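# Census-style profiling of a glyco-PSM table: the glycan-by-glycosite PSM
# count matrix and PSM-weighted feature distributions. Profiling uses
# identifications only (never reporter intensities), so it is invariant to
# row order and channel subsets, and incomplete-intensity PSMs count.

site_key <- function(psms) paste(psms$protein, psms$glycosite, sep = "@")

#' Build the glycan-by-glycosite PSM count matrix
#'
#' Aggregates PSMs over spectra into a sparse matrix of PSM counts with
#' glycans (canonical composition strings) as rows and glycosites
#' (`protein@position`) as columns, plus the two marginals: the number of
#' glycosites modified by each glycan and the number of distinct glycans at
#' each glycosite.
#'
#' @param psms Glyco-PSM table with `protein`, `glycosite`, `glycan`.
#' @return A `glyco_profile` list: `cells` (tibble glycan, site, n_psms —
#'   sparse triplets), `glycans` (glycan, n_sites, n_psms), `sites` (site,
#'   n_glycans, n_psms, subtypes present), `n_psms`, `n_glycopeptides`
#'   (distinct site-glycan pairs), `n_glycans`, `n_sites`.
#' @export
build_site_glycan_matrix <- function(psms) {
  x <- as_tibble(psms)
  if (!nrow(x)) abort("Empty PSM table.")
  x$glycan <- format_glycan(x$glycan)
  x$site <- site_key(x)
  cells <- x |>
    dplyr::count(.data$glycan, .data$site, name = "n_psms") |>
    dplyr::arrange(.data$glycan, .data$site)
  glycans <- cells |>
    dplyr::group_by(.data$glycan) |>
    dplyr::summarise(n_sites = dplyr::n(), n_psms = sum(.data$n_psms),
                     .groups = "drop")
  cls <- classify_glycans(cells$glycan)
  sites <- cells |>
    dplyr::mutate(subtype = as.character(cls$subtype)) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      n_glycans = dplyr::n(),
      n_psms = sum(.data$n_psms),
      n_subtypes = dplyr::n_distinct(.data$subtype),
      sole_subtype = ifelse(dplyr::n_distinct(.data$subtype) == 1,
                            .data$subtype[1], NA_character_),
      .groups = "drop"
    )
  structure(
    list(
      cells = cells, glycans = glycans, sites = sites,
      n_psms = sum(cells$n_psms),
      n_glycopeptides = nrow(cells),
      n_glycans = nrow(glycans),
      n_sites = nrow(sites)
    ),
    class = "glyco_profile"
  )
}

#' @export
print.glyco_profile <- function(x, ...) {
  cat("<glyco_profile> ", x$n_psms, " PSMs over ", x$n_glycopeptides,
      " glycopeptides (", x$n_glycans, " glycans x ", x$n_sites,
      " glycosites)\n", sep = "")
  sole <- sum(!is.na(x$sites$sole_subtype))
  cat(sprintf("glycosites solely occupied by one subtype: %d (%.1f%%)\n",
              sole, 100 * sole / x$n_sites))
  invisible(x)
}

#' PSM percentages of the three canonical N-glycan subtypes
#'
#' Counts PSMs per subtype and reports each of complex, oligo-mannose and
#' hybrid as a percentage of their combined total, rounded to one decimal.
#' Pauci/other PSMs are reported with their count but excluded from the
#' percentage denominator.
#'
#' @param psms Glyco-PSM table (or any table with a `glycan` column; one
#'   row per PSM).
#' @param classes Optional precomputed [classify_glycans()] rows for
#'   `psms$glycan`.
#' @return Tibble with `subtype`, `n_psms`, `pct` (NA for pauci/other).
#' @export
subtype_psm_fractions <- function(psms, classes = NULL) {
  x <- as_tibble(psms)
  if (is.null(classes)) classes <- classify_glycans(x$glycan)
  counts <- tibble(subtype = factor(classes$subtype,
                                    levels = GLYCAN_SUBTYPES)) |>
    dplyr::count(.data$subtype, name = "n_psms", .drop = FALSE)
  main <- counts$subtype != "pauci/other"
  denom <- sum(counts$n_psms[main])
  counts$pct <- NA_real_
  if (denom > 0) {
    counts$pct[main] <- percent_of(counts$n_psms[main], denom)
  }
  counts
}

#' Rank glycans by the number of glycosites they modify
#'
#' Descending by sites-per-glycan; ties broken by total PSM count
#' (descending) then canonical composition string, so the ranking is
#' deterministic.
#'
#' @param profile A [build_site_glycan_matrix()] result.
#' @param n Number of top glycans to return (default 10).
#' @return Tibble `glycan`, `n_sites`, `n_psms`, `rank`.
#' @export
rank_glycans_by_sites <- function(profile, n = 10) {
  if (n < 1) abort("`n` must be at least 1.")
  profile$glycans |>
    dplyr::arrange(dplyr::desc(.data$n_sites), dplyr::desc(.data$n_psms),
                   .data$glycan) |>
    head(n) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' PSM-weighted glycan feature distributions
#'
#' Fractions of PSMs by antenna count (complex-glycan PSMs only), by
#' sialic-acid count (bins 0, 1, 2, 3, >=4) and by fucose count (bins 0,
#' 1, >=2). Each bin family sums to 1.
#'
#' @inheritParams subtype_psm_fractions
#' @return Tibble `family`, `bin`, `n_psms`, `fraction`.
#' @export
glycan_feature_distribution <- function(psms, classes = NULL) {
  x <- as_tibble(psms)
  if (is.null(classes)) classes <- classify_glycans(x$glycan)
  bin_table <- function(vals, family, levels) {
    vals <- factor(vals, levels = levels)
    tab <- table(vals)
    tibble(family = family, bin = names(tab), n_psms = as.integer(tab),
           fraction = as.numeric(tab) / max(sum(tab), 1L))
  }
  fuc_bins <- ifelse(classes$n_fuc_total >= 2, ">=2",
                     as.character(classes$n_fuc_total))
  sia_bins <- ifelse(classes$n_sia >= 4, ">=4", as.character(classes$n_sia))
  ant <- classes$antennae[!is.na(classes$antennae)]
  dplyr::bind_rows(
    bin_table(ant, "antennae", sort(unique(ant))),
    bin_table(sia_bins, "sialic_acid", c("0", "1", "2", "3", ">=4")),
    bin_table(fuc_bins, "fucose", c("0", "1", ">=2"))
  )
}
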