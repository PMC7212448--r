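# Reading, validating and writing the PSM and result tables.
#
# PSM tables are TSV with one row per (glyco)peptide-spectrum match:
#   spectrum_id  peptide  protein  [glycosite  glycan]  intensity_<channel>...
# Glycosite positions are 1-based in the protein sequence; peptide strings
# mark the glycosylated asparagine with '#' (e.g. "YKN#NSDISSTR").

#' Read and validate a PSM table
#'
#' Reads a tab-separated PSM table, checks the required columns against the
#' channel design, validates glycan composition strings (glyco tables), and
#' flags rows with missing, non-finite or non-positive reporter intensity in
#' any channel as `incomplete`. Flagged rows are kept — census-style
#' profiling uses them — but quantitation excludes them.
#'
#' @param path Path to a TSV file.
#' @param design A [channel_design()]; one `intensity_<channel>` column per
#'   design channel is required (bare channel-label columns are accepted and
#'   renamed).
#' @param kind `"glyco"` (requires `glycosite` and `glycan` columns) or
#'   `"protein"`.
#' @param strict If `TRUE`, rows with invalid glycan strings or
#'   non-numeric intensities are an error; otherwise they are dropped with
#'   a warning and attached as the `"rejected"` attribute (with line
#'   numbers).
#' @return A tibble of validated PSM records with a logical `incomplete`
#'   column.
#' @export
read_psm_table <- function(path, design, kind = c("glyco", "protein"),
                           strict = FALSE) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"))
  # accept bare channel labels as intensity column names
  for (ch in design$channels) {
    if (ch %in% names(raw) && !(paste0("intensity_", ch) %in% names(raw))) {
      names(raw)[names(raw) == ch] <- paste0("intensity_", ch)
    }
  }
  required <- c("spectrum_id", "peptide", "protein",
                if (kind == "glyco") c("glycosite", "glycan"),
                intensity_cols(design))
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  raw <- raw[required]
  raw$.line <- seq_len(nrow(raw)) + 1L # header is line 1

  problems <- character()
  if (kind == "glyco") {
    gc <- glycan_counts(raw$glycan)
    bad_glycan <- !is.na(gc$parse_error)
    if (any(bad_glycan)) {
      problems <- c(problems, sprintf(
        "line %d: glycan \"%s\": %s",
        raw$.line[bad_glycan], raw$glycan[bad_glycan],
        gc$parse_error[bad_glycan]
      ))
    }
    raw$glycan[!bad_glycan] <- format_glycan(gc[!bad_glycan, ])
    site <- suppressWarnings(as.integer(raw$glycosite))
    bad_site <- is.na(site) | site < 1L
    if (any(bad_site)) {
      problems <- c(problems, sprintf(
        "line %d: invalid glycosite \"%s\"", raw$.line[bad_site],
        raw$glycosite[bad_site]
      ))
    }
    raw$glycosite <- site
    bad_row <- bad_glycan | bad_site
  } else {
    bad_row <- rep(FALSE, nrow(raw))
  }

  ints <- raw[intensity_cols(design)]
  nonnum <- matrix(FALSE, nrow(raw), ncol(ints))
  for (j in seq_along(ints)) {
    parsed <- suppressWarnings(as.numeric(ints[[j]]))
    nonnum[, j] <- !is.na(ints[[j]]) & is.na(parsed)
    raw[[intensity_cols(design)[j]]] <- parsed
  }
  bad_num <- rowSums(nonnum) > 0
  if (any(bad_num)) {
    problems <- c(problems, sprintf(
      "line %d: non-numeric intensity", raw$.line[bad_num]
    ))
  }
  bad_row <- bad_row | bad_num

  if (length(problems)) {
    if (strict) {
      abort(c("Invalid PSM rows:", setNames(problems,
                                            rep("x", length(problems)))))
    }
    warn(sprintf("Dropping %d invalid PSM row(s); see attr(, \"rejected\").",
                 sum(bad_row)))
  }
  rejected <- problems
  out <- raw[!bad_row, , drop = FALSE]

  intmat <- as.matrix(out[intensity_cols(design)])
  bad_int <- !is.finite(intmat) | (intmat <= 0)
  bad_int[is.na(bad_int)] <- TRUE
  out$incomplete <- rowSums(bad_int) > 0
  out$.line <- NULL
  out <- as_tibble(out)
  attr(out, "rejected") <- rejected
  attr(out, "design") <- design
  attr(out, "kind") <- kind
  out
}

#' Write pipeline result tables with a run manifest
#'
#' Writes each table as TSV with a deterministic column order (as given)
#' and row order (as given), plus a `manifest.json` recording the
#' configuration hash, seed, package version and R version so a run can be
#' identified and reproduced. Identical inputs and configuration produce
#' byte-identical outputs.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration object to hash into the manifest.
#' @param seed Optional integer seed recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(tables[[nm]]), p)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "glycoquant",
    version = as.character(utils::packageVersion("glycoquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = if (is.null(config)) NA else rlang::hash(config),
    seed = seed,
    tables = names(tables)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mp))
}
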