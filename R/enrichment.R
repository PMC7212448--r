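# Generic over-representation analysis: one-sided hypergeometric test of a
# selected accession set against user-supplied term sets (GO terms, KEGG
# pathways, or any GMT-style collection), with count and raw-p filters.

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the selected accessions overlap the term's
#' members more than expected by chance when drawing `|selected|` accessions
#' from the background: the upper-tail hypergeometric probability
#' P(X >= k) with population size `|background|`, `|term ∩ background|`
#' successes, and `|selected|` draws. Terms are retained when the overlap
#' count reaches `min_count` and the raw p-value is below `alpha`; a
#' Benjamini-Hochberg column (computed over all tested terms, before
#' filtering) is included for reference but is not used as a filter.
#'
#' @param selected Character vector of selected accessions (must be a
#'   subset of `background`).
#' @param background Character vector: the statistical universe, typically
#'   all quantified glycoproteins in the run.
#' @param terms Term sets: a data frame with columns `term`, `name`,
#'   `members` (list-column), as returned by [read_gmt()], or a named list
#'   of accession vectors.
#' @param min_count Minimum overlap count to retain a term (default 3,
#'   i.e. "count > 2").
#' @param alpha Raw p-value threshold (default 0.05).
#' @return A `glyco_enrichment` tibble sorted by ascending p: `term`,
#'   `name`, `n_term` (members in background), `n_selected`, `overlap`,
#'   `expected`, `p_value`, `p_adjust_bh`, `members_hit`. The unfiltered
#'   table is attached as attribute `"all_terms"`.
#' @examples
#' bg <- sprintf("P%02d", 1:20)
#' overrepresentation_test(bg[1:5], bg, list(t1 = bg[2:6]), min_count = 3)
#' @export
overrepresentation_test <- function(selected, background, terms,
                                    min_count = 3, alpha = 0.05) {
  selected <- unique(as.character(selected))
  background <- unique(as.character(background))
  stray <- setdiff(selected, background)
  if (length(stray)) {
    abort(c(
      "`selected` must be a subset of `background`; offending accessions:",
      setNames(stray, rep("x", length(stray)))
    ))
  }
  terms <- as_term_table(terms)
  N <- length(background)
  n_draw <- length(selected)
  res <- terms |>
    dplyr::mutate(
      members_bg = purrr::map(.data$members,
                              ~ intersect(unique(.x), background)),
      n_term = lengths(.data$members_bg),
      members_hit = purrr::map(.data$members_bg, ~ intersect(.x, selected)),
      overlap = lengths(.data$members_hit),
      n_selected = n_draw,
      expected = n_draw * .data$n_term / N,
      p_value = phyper(.data$overlap - 1, .data$n_term, N - .data$n_term,
                       n_draw, lower.tail = FALSE)
    ) |>
    dplyr::mutate(p_adjust_bh = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::select(dplyr::all_of(c(
      "term", "name", "n_term", "n_selected", "overlap", "expected",
      "p_value", "p_adjust_bh", "members_hit"
    )))
  kept <- res |>
    dplyr::filter(.data$overlap >= min_count, .data$p_value < alpha) |>
    dplyr::arrange(.data$p_value, .data$term)
  structure(kept,
    class = c("glyco_enrichment", class(kept)),
    all_terms = res, min_count = min_count, alpha = alpha,
    n_background = N
  )
}

as_term_table <- function(terms) {
  if (is.data.frame(terms)) {
    stopifnot(all(c("term", "members") %in% names(terms)))
    out <- as_tibble(terms)
    if (!"name" %in% names(out)) out$name <- out$term
  } else {
    stopifnot(is.list(terms), !is.null(names(terms)))
    out <- tibble(
      term = names(terms), name = names(terms),
      members = purrr::map(terms, as.character)
    )
  }
  if (any(lengths(out$members) == 0)) {
    abort("Every term set must have at least one member.")
  }
  out$members <- unname(out$members)
  out[c("term", "name", "members")]
}

#' Read term sets from a GMT file
#'
#' GMT format: one term per line, tab-separated — term id, description,
#' then one member accession per remaining field.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with `term`, `name`, and list-column `members`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(which(bad), collapse = ", ")))
  }
  tibble(
    term = purrr::map_chr(parts, 1),
    name = purrr::map_chr(parts, 2),
    members = purrr::map(parts, ~ unique(.x[-(1:2)]))
  )
}

#' @method glance glyco_enrichment
#' @export
glance.glyco_enrichment <- function(x, ...) {
  tibble(
    n_terms_tested = nrow(attr(x, "all_terms")),
    n_retained = nrow(x),
    n_background = attr(x, "n_background"),
    min_count = attr(x, "min_count"),
    alpha = attr(x, "alpha")
  )
}
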