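# N-glycan composition parsing, canonical formatting, classification into
# the feature classes used for site-specific glycosylation profiling, and
# monoisotopic mass.
#
# A composition is a count vector over four monosaccharide classes:
#   N = HexNAc, H = Hex, F = deoxyhexose (fucose), S = sialic acid (NeuAc).

# Monoisotopic residue masses (Da) of the glycosidically linked residues.
GLYCAN_RESIDUE_MASS <- c(
  n_hexnac = 203.07937, # HexNAc
  n_hex    = 162.05282, # Hex
  n_fuc    = 146.05791, # dHex / Fuc
  n_neuac  = 291.09542  # NeuAc
)

COUNT_COLS <- c("n_hexnac", "n_hex", "n_fuc", "n_neuac")

# Tokenize one composition string into the four counts, or return an error
# message naming the offending token. Short codes N/H/F/S; long names
# HexNAc/Hex/Fuc/dHex/Sia/NeuAc are matched case-insensitively. Each
# monosaccharide may appear at most once.
.parse_one_glycan <- function(text) {
  counts <- c(n_hexnac = 0L, n_hex = 0L, n_fuc = 0L, n_neuac = 0L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(list(counts = NULL, error = "empty composition string"))
  }
  s <- trimws(text)
  long_pat <- stringr::regex("^(hexnac|neuac|hex|fuc|dhex|sia)([0-9]+)",
    ignore_case = TRUE
  )
  short_pat <- "^([NHFS])([0-9]+)"
  long_map <- c(
    hexnac = "n_hexnac", hex = "n_hex", fuc = "n_fuc", dhex = "n_fuc",
    sia = "n_neuac", neuac = "n_neuac"
  )
  short_map <- c(
    N = "n_hexnac", H = "n_hex", F = "n_fuc", S = "n_neuac"
  )
  seen <- character()
  while (nzchar(s)) {
    m <- stringr::str_match(s, long_pat)
    if (!is.na(m[1, 1])) {
      key <- long_map[[tolower(m[1, 2])]]
    } else {
      m <- stringr::str_match(s, short_pat)
      if (!is.na(m[1, 1])) {
        key <- short_map[[m[1, 2]]]
      } else {
        bad <- stringr::str_extract(s, "^[A-Za-z]+[0-9]*")
        if (is.na(bad)) bad <- substr(s, 1, 1)
        return(list(
          counts = NULL,
          error = sprintf("unrecognized token \"%s\"", bad)
        ))
      }
    }
    if (key %in% seen) {
      return(list(
        counts = NULL,
        error = sprintf("duplicated monosaccharide in token \"%s\"", m[1, 1])
      ))
    }
    seen <- c(seen, key)
    counts[[key]] <- as.integer(m[1, 3])
    s <- substr(s, nchar(m[1, 1]) + 1L, nchar(s))
  }
  if (sum(counts) == 0L) {
    return(list(counts = NULL, error = "composition has no residues"))
  }
  list(counts = counts, error = NA_character_)
}

# Non-throwing vectorized parser: one row per input with counts (NA when
# invalid) and an error message column. Used by the strict parser and by
# table validation.
glycan_counts <- function(glycan) {
  rows <- purrr::map(as.character(glycan), .parse_one_glycan)
  tibble(
    glycan = as.character(glycan),
    n_hexnac = purrr::map_int(rows, ~ .x$counts[["n_hexnac"]] %||% NA_integer_),
    n_hex = purrr::map_int(rows, ~ .x$counts[["n_hex"]] %||% NA_integer_),
    n_fuc = purrr::map_int(rows, ~ .x$counts[["n_fuc"]] %||% NA_integer_),
    n_neuac = purrr::map_int(rows, ~ .x$counts[["n_neuac"]] %||% NA_integer_),
    parse_error = purrr::map_chr(rows, "error")
  )
}

#' Parse N-glycan composition strings
#'
#' Accepts both the short one-letter dialect (`"N4H5F1S1"`) and the long
#' monosaccharide names (`"HexNAc4Hex5Fuc1Sia1"`, case-insensitive; `dHex`
#' and `NeuAc` are synonyms of `Fuc` and `Sia`). Letters may come in any
#' order, each at most once; absent letters mean a count of zero.
#'
#' @param glycan Character vector of composition strings.
#' @return A tibble with one row per input: `glycan` (the input string) and
#'   integer counts `n_hexnac`, `n_hex`, `n_fuc`, `n_neuac`.
#' @examples
#' parse_glycan(c("N4H5F1S1", "HexNAc2Hex3"))
#' @seealso [format_glycan()], [classify_glycans()]
#' @export
parse_glycan <- function(glycan) {
  out <- glycan_counts(glycan)
  bad <- !is.na(out$parse_error)
  if (any(bad)) {
    msgs <- sprintf(
      "\"%s\": %s", out$glycan[bad], out$parse_error[bad]
    )
    abort(c(
      "Invalid glycan composition string(s):",
      setNames(unique(msgs), rep("x", length(unique(msgs))))
    ))
  }
  out$parse_error <- NULL
  out
}

#' Format glycan compositions canonically
#'
#' Serializes compositions to the canonical short form with fixed letter
#' order N, H, F, S and zero counts omitted (`"N4H5F1S2"`). The inverse of
#' [parse_glycan()]: `format_glycan(parse_glycan(x))` reproduces the
#' canonical spelling of `x`.
#'
#' @param comp A data frame with columns `n_hexnac`, `n_hex`, `n_fuc`,
#'   `n_neuac` (as returned by [parse_glycan()]), or a character vector of
#'   composition strings to canonicalize.
#' @return Character vector of canonical composition strings.
#' @examples
#' format_glycan(parse_glycan("Hex5HexNAc4Fuc1Sia2")) # "N4H5F1S2"
#' @export
format_glycan <- function(comp) {
  if (is.character(comp)) comp <- parse_glycan(comp)
  stopifnot(all(COUNT_COLS %in% names(comp)))
  counts <- as.matrix(comp[COUNT_COLS])
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("Composition counts must be non-negative integers.")
  }
  if (any(rowSums(counts) == 0)) {
    abort("Cannot format an all-zero composition.")
  }
  letters4 <- c("N", "H", "F", "S")
  apply(counts, 1, function(x) {
    keep <- x > 0
    paste0(letters4[keep], x[keep], collapse = "")
  })
}

#' Partition fucose counts into core and antennary
#'
#' Composition data carry no linkage information, so the split is a
#' heuristic: when at least one fucose is present, one is assigned to the
#' core (the innermost GlcNAc) and any remainder to the antennae. An
#' override table replaces the heuristic for listed compositions, which
#' preserves known antennary-only fucosylation cases.
#'
#' @param comp Data frame with composition count columns, or a character
#'   vector of composition strings.
#' @param overrides Optional data frame with columns `glycan` (canonical
#'   composition string) and logical `core_fucose`; listed compositions with
#'   `core_fucose = FALSE` get all fucoses assigned antennary, `TRUE` forces
#'   the first fucose core.
#' @return The input counts plus integer columns `n_core_fuc` and
#'   `n_antennary_fuc` (summing to `n_fuc`).
#' @examples
#' partition_fucose("N4H5F1S1") # core 1, antennary 0
#' @export
partition_fucose <- function(comp, overrides = NULL) {
  if (is.character(comp)) comp <- parse_glycan(comp)
  out <- as_tibble(comp)
  out$n_core_fuc <- as.integer(pmin(out$n_fuc, 1L))
  if (!is.null(overrides)) {
    stopifnot(all(c("glycan", "core_fucose") %in% names(overrides)))
    key <- format_glycan(out)
    ov <- setNames(as.logical(overrides$core_fucose),
                   format_glycan(overrides$glycan))
    hit <- key %in% names(ov)
    out$n_core_fuc[hit] <- ifelse(
      ov[key[hit]], pmin(out$n_fuc[hit], 1L), 0L
    )
  }
  out$n_antennary_fuc <- out$n_fuc - out$n_core_fuc
  out
}

#' Classify N-glycan compositions into structural feature classes
#'
#' Assigns each composition to exactly one subtype and derives the feature
#' counts used in glycan-centric profiling. The subtype rules operate on
#' counts alone:
#'
#' * **oligo-mannose**: `n_hexnac == 2`, `n_hex >= 4`, no sialic acid
#'   (fucosylated oligo-mannose compositions are retained in this class);
#' * **hybrid**: `n_hexnac >= 3` and `n_hex > n_hexnac + 1` (uncapped
#'   mannose arm alongside GlcNAc-initiated antennae);
#' * **complex**: `n_hexnac >= 3` and `n_hex <= n_hexnac + 1`;
#' * **pauci/other**: everything else (truncated cores such as N2H3, N1H1,
#'   and sialylated HexNAc2 compositions).
#'
#' For complex glycans the antenna count is `n_hexnac - 2` (core GlcNAc2),
#' minus one when the composition is annotated as carrying a bisecting
#' GlcNAc. Bisecting GlcNAc is not inferable from counts, so it defaults to
#' `"unknown"` unless an annotation set is supplied.
#'
#' @param x A data frame with a `glycan` column (composition strings) or
#'   composition count columns, or a character vector of composition strings.
#' @param bisecting Optional character vector of compositions annotated as
#'   bisecting; when supplied, membership sets `bisecting = "yes"`/`"no"`,
#'   otherwise every row gets `"unknown"`.
#' @param fucose_overrides Optional override table passed to
#'   [partition_fucose()].
#' @return A tibble with the composition counts plus `glycan` (canonical
#'   string), `subtype` (factor: complex, oligo-mannose, hybrid,
#'   pauci/other), `mannose_count` (Hex count for oligo-mannose, else NA),
#'   `antennae` (complex only, else NA), `n_sia`, `n_fuc_total`,
#'   `n_core_fuc`, `n_antennary_fuc`, `bisecting`.
#' @examples
#' classify_glycans(c("N2H8", "N4H5S2", "N3H6", "N4H5F1S1"))
#' @export
classify_glycans <- function(x, bisecting = NULL, fucose_overrides = NULL) {
  if (is.character(x)) {
    comp <- parse_glycan(x)
  } else if (all(COUNT_COLS %in% names(x))) {
    comp <- as_tibble(x)
  } else if ("glycan" %in% names(x)) {
    comp <- parse_glycan(x$glycan)
  } else {
    abort("`x` must be composition strings or carry a `glycan` column.")
  }
  comp$glycan <- format_glycan(comp)

  subtype <- dplyr::case_when(
    comp$n_hexnac == 2L & comp$n_hex >= 4L & comp$n_neuac == 0L ~
      "oligo-mannose",
    comp$n_hexnac >= 3L & comp$n_hex > comp$n_hexnac + 1L ~ "hybrid",
    comp$n_hexnac >= 3L & comp$n_hex <= comp$n_hexnac + 1L ~ "complex",
    TRUE ~ "pauci/other"
  )
  subtype <- factor(subtype, levels = GLYCAN_SUBTYPES)

  bis <- if (is.null(bisecting)) {
    rep("unknown", nrow(comp))
  } else {
    ifelse(comp$glycan %in% format_glycan(bisecting), "yes", "no")
  }

  antennae <- ifelse(
    subtype == "complex",
    comp$n_hexnac - 2L - (bis == "yes"),
    NA_integer_
  )

  fuc <- partition_fucose(comp, overrides = fucose_overrides)

  tibble(
    glycan = comp$glycan,
    n_hexnac = comp$n_hexnac,
    n_hex = comp$n_hex,
    n_fuc = comp$n_fuc,
    n_neuac = comp$n_neuac,
    subtype = subtype,
    mannose_count = ifelse(subtype == "oligo-mannose", comp$n_hex,
                           NA_integer_),
    antennae = as.integer(antennae),
    n_sia = comp$n_neuac,
    n_fuc_total = comp$n_fuc,
    n_core_fuc = fuc$n_core_fuc,
    n_antennary_fuc = fuc$n_antennary_fuc,
    bisecting = factor(bis, levels = c("yes", "no", "unknown"))
  )
}

#' @rdname classify_glycans
#' @format NULL
#' @export
GLYCAN_SUBTYPES <- c("complex", "oligo-mannose", "hybrid", "pauci/other")

#' Monoisotopic mass of glycan compositions
#'
#' Sum of glycosidically linked residue masses: HexNAc 203.07937, Hex
#' 162.05282, dHex 146.05791, NeuAc 291.09542 Da. The mass of the free
#' reducing glycan would add one water; residue masses are used here because
#' the compositions describe peptide-attached glycans.
#'
#' @inheritParams format_glycan
#' @return Numeric vector of masses in Da.
#' @examples
#' glycan_mass("N2H3") # 892.3172, the chitobiose + trimannosyl core
#' @export
glycan_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_glycan(comp)
  stopifnot(all(COUNT_COLS %in% names(comp)))
  as.numeric(
    as.matrix(comp[COUNT_COLS]) %*% GLYCAN_RESIDUE_MASS[COUNT_COLS]
  )
}

#' Read a two-column composition annotation table
#'
#' Reads TSV annotation files keyed by composition string, e.g. bisecting
#' annotations (`glycan`, `flag`) or core-fucose overrides (`glycan`,
#' `core_fucose`). Composition strings are canonicalized on read.
#'
#' @param path Path to a TSV file whose first column holds composition
#'   strings and second column a logical flag.
#' @return Tibble with canonical `glycan` and the flag column.
#' @export
read_glycan_annotation <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(tab) < 2) abort("Annotation file needs two columns.")
  tab[[1]] <- format_glycan(tab[[1]])
  names(tab)[1] <- "glycan"
  tab[[2]] <- as.logical(tab[[2]])
  as_tibble(tab)
}
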