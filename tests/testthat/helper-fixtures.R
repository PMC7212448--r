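# Fixture builders shared across the test files. All data are constructed
# in code; channel order follows hcc_afp_design():
#   126 = para_lowAFP, 127N = tumor_lowAFP,
#   128C = para_highAFP, 129N = tumor_highAFP.

test_design <- hcc_afp_design()

unit_factors <- function(design = test_design) {
  tibble::tibble(channel = design$channels, factor = 1)
}

# One glycopeptide feature's PSMs with exact per-channel fold multipliers
# (channel_mult in design channel order). Per-PSM precursor level varies,
# the channel profile does not, so channel medians hit the multipliers
# exactly.
feature_psms <- function(protein, glycosite, glycan, channel_mult,
                         n_psms = 5, base = 1e6, design = test_design) {
  stopifnot(length(channel_mult) == length(design$channels))
  out <- tibble::tibble(
    spectrum_id = sprintf("%s_%d_%s_%d", protein, glycosite, glycan,
                          seq_len(n_psms)),
    peptide = "AAAN#GSK",
    protein = protein, glycosite = glycosite, glycan = glycan
  )
  scale <- base * seq(0.8, 1.2, length.out = n_psms)
  for (i in seq_along(design$channels)) {
    out[[paste0("intensity_", design$channels[i])]] <-
      scale * channel_mult[i]
  }
  out$incomplete <- FALSE
  out
}

protein_psms_fixture <- function(protein, channel_mult, n_psms = 6,
                                 base = 5e6, design = test_design) {
  out <- feature_psms(protein, 1, "N2H3", channel_mult, n_psms, base,
                      design)
  out$glycosite <- NULL
  out$glycan <- NULL
  out$peptide <- paste0("PEP_", protein)
  out$spectrum_id <- sprintf("%s_ps%d", protein, seq_len(n_psms))
  out
}

# Random valid compositions (counts 0..9, at least one positive).
random_compositions <- function(n) {
  m <- matrix(sample(0:9, 4 * n, replace = TRUE), ncol = 4)
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  tibble::tibble(
    n_hexnac = m[, 1], n_hex = m[, 2], n_fuc = m[, 3], n_neuac = m[, 4]
  )
}

# A small, fast simulation configuration for pipeline-level tests.
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_glycoproteins = 60, seed = seed, ...)
}
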