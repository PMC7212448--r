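# Channel design: maps isobaric reporter channels to sample groups and
# names the channel-pair comparisons the pipeline quantifies.

#' Define an isobaric channel design
#'
#' A design holds the ordered reporter channel labels, the sample group
#' each channel carries, and the named ratio comparisons (ordered
#' numerator/denominator channel pairs) computed during quantitation.
#'
#' @param channels Character vector of channel labels (e.g. `"126"`,
#'   `"127N"`), in table column order.
#' @param groups Character vector (same length) naming the sample group of
#'   each channel.
#' @param comparisons Data frame with columns `comparison`, `numerator`,
#'   `denominator`; both channel columns must reference `channels`.
#' @return An object of class `glyco_design`.
#' @seealso [hcc_afp_design()] for the default four-channel tumor/paracancer
#'   design.
#' @export
channel_design <- function(channels, groups, comparisons) {
  channels <- as.character(channels)
  groups <- as.character(groups)
  if (length(groups) != length(channels)) {
    abort("`groups` must name one group per channel.")
  }
  if (anyDuplicated(channels)) abort("Channel labels must be unique.")
  comparisons <- as_tibble(comparisons)
  stopifnot(all(c("comparison", "numerator", "denominator") %in%
                  names(comparisons)))
  missing <- setdiff(
    c(comparisons$numerator, comparisons$denominator), channels
  )
  if (length(missing)) {
    abort(sprintf(
      "Comparison references unknown channel(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  structure(
    list(
      channels = channels,
      groups = setNames(groups, channels),
      comparisons = comparisons
    ),
    class = "glyco_design"
  )
}

#' Four-channel tumor/paracancer design for low- and high-AFP HCC
#'
#' The pooled design used throughout the package examples: one channel per
#' pooled sample, 126 = paracancer (low AFP), 127N = tumor (low AFP),
#' 128C = paracancer (high AFP), 129N = tumor (high AFP). Four comparisons
#' are defined: tumor vs paired paracancer within each AFP group, tumor
#' low- vs high-AFP, and paracancer low- vs high-AFP.
#'
#' @return A `glyco_design`.
#' @examples
#' hcc_afp_design()
#' @export
hcc_afp_design <- function() {
  channel_design(
    channels = c("126", "127N", "128C", "129N"),
    groups = c("para_lowAFP", "tumor_lowAFP", "para_highAFP",
               "tumor_highAFP"),
    comparisons = tibble(
      comparison = c(
        "tumor_vs_para_lowAFP", "tumor_vs_para_highAFP",
        "tumor_lowAFP_vs_highAFP", "para_lowAFP_vs_highAFP"
      ),
      numerator = c("127N", "129N", "127N", "126"),
      denominator = c("126", "128C", "129N", "128C")
    )
  )
}

#' @export
print.glyco_design <- function(x, ...) {
  cat("<glyco_design> ", length(x$channels), " channels\n", sep = "")
  for (ch in x$channels) {
    cat("  ", format(ch, width = 5), " -> ", x$groups[[ch]], "\n", sep = "")
  }
  cat("comparisons:\n")
  for (i in seq_len(nrow(x$comparisons))) {
    cat("  ", x$comparisons$comparison[i], ": ",
        x$comparisons$numerator[i], "/", x$comparisons$denominator[i],
        "\n", sep = "")
  }
  invisible(x)
}
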