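# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library calls never clobber the global stream.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

geomean <- function(x) exp(mean(log(x)))

#' Express a count as a percentage of a total
#'
#' Reporting helper used throughout the package summaries: `100 * k / n`,
#' rounded to a fixed number of decimals (one by default, matching the
#' precision at which PSM and glycopeptide percentages are conventionally
#' reported).
#'
#' @param k Numerator count(s).
#' @param n Denominator total.
#' @param digits Decimal places to round to.
#' @return Numeric vector of percentages.
#' @examples
#' percent_of(82, 1110) # 7.4
#' @export
percent_of <- function(k, n, digits = 1) {
  if (any(n <= 0)) abort("`n` must be positive.")
  round(100 * k / n, digits)
}

# Column names holding reporter intensities for a channel design.
intensity_cols <- function(design) paste0("intensity_", design$channels)

log2_cols <- function(design) paste0("log2_", design$comparisons$comparison)

occupancy_cols <- function(design) {
  paste0("occupancy_", design$comparisons$comparison)
}
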