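# glycoquant

Site-specific N-glycosylation analysis of intact glycopeptides from
pooled isobaric (TMT) labelling experiments, built for studies that
compare tumor and adjacent (paracancer) tissue across patient groups —
the motivating use case is hepatocellular carcinoma stratified by serum
alpha-fetoprotein (AFP) level, where the question is which site-specific
glycans change in tumors generally and which change only in the low- or
high-AFP group.

An *intact glycopeptide* keeps the glycan attached to its peptide, so
every peptide-spectrum match (PSM) ties a glycan composition (e.g.
`N4H5F1S1` = HexNAc4 Hex5 Fuc1 NeuAc1) to one glycosite of one protein.
`glycoquant` takes glyco-PSM and protein-PSM tables with one reporter
intensity per TMT channel and provides:

* **Glycan compositions** — parsing (`N4H5F1S1` or
  `HexNAc4Hex5Fuc1Sia1`), canonical formatting, monoisotopic mass, and
  classification into subtype (complex / oligo-mannose / hybrid /
  pauci-other), antenna count, sialic-acid count, and core vs antennary
  fucosylation.
* **Profiling** — the glycan x glycosite PSM-count matrix with its
  marginals, PSM-weighted subtype percentages, and top glycans by number
  of modified sites.
* **Quantitation** — channel normalization factors derived from the
  global proteome (per-channel median of intensity over the PSM's
  geometric mean), median-ratio quantitation of features with >= 5 PSMs,
  and glycosylation-occupancy ratios: for feature *g* on protein *p* and
  comparison *c*,

  ```
  occupancy log2 change = log2 ratio_c(g) - log2 ratio_c(p)
  ```

  which separates glycosylation-level change from protein-expression
  change.
* **Differential cascades** — *commonly altered* calls (>= 2-fold
  tumor/paracancer change, same direction, in both AFP groups) and
  *group-unique* calls (>= 1.5-fold difference between low- and high-AFP
  tumors, gated on paracancer stability at the glycopeptide, protein and
  occupancy levels), plus glycan-feature frequency summaries of each
  changed set.
* **Enrichment** — a generic one-sided hypergeometric
  over-representation test against GMT term sets with the conventional
  `count > 2` and `p < 0.05` filters.
* **Synthetic data** — a seeded generator with a realistic composition
  pool, negative-binomial PSM counts, log-normal reporter noise, unequal
  channel loadings, and planted protein-level / common / group-unique /
  occupancy effects with ground truth, so the whole pipeline can be
  validated end to end.

All user-facing functions take data frames and return tibbles;
`tidy()`/`glance()` methods summarize fitted objects, and
`autoplot()`/`plot_*()` give ggplot2 views of each result type.

## Worked example

```r
library(glycoquant)

sim <- simulate_experiment(sim_config(seed = 7))
res <- run_pipeline(sim)       # normalization, quantitation, occupancy, calls

subtype_psm_fractions(sim$glyco_psms)
#>   subtype       n_psms   pct
#> 1 complex         4623  61.8
#> 2 oligo-mannose   1922  25.7
#> 3 hybrid           930  12.4
#> 4 pauci/other        0  NA
```

The simulated tissue has the expected glycan economy: roughly 60% of
PSMs carry complex glycans, 29% oligo-mannose and 11% hybrid
(pauci/other compositions are excluded from the percentage denominator).

```r
glance(res$calls)
#>   n_quantified n_common_up n_common_down n_common_altered ...
#> 1          770          22            18               40
```

Of 770 glycopeptides passing the >= 5-PSM filter, 40 are called commonly
altered (>= 2-fold, concordant in both AFP groups). Scored against the
planted truth:

```r
evaluate_recovery(res$calls, sim$truth)
#>   label          n_truth n_evaluable    tp    fp    fn precision recall
#> 1 common-up           23          22    22     0     0     1      1
#> 2 common-down         23          18    18     0     0     1      1
#> 3 lowAFP-unique       28          26    23     7     3     0.767  0.885
#> 4 highAFP-unique      28          22    21     3     1     0.875  0.955
```

Every planted common 4-fold effect that survived quantitation is
recovered with the correct direction; the 1.5-fold group-unique cascade
recovers ~90% of its targets and mislabels no protein-driven change
(recall is over planted features that passed quantitation —
`n_evaluable`; features with < 5 PSMs are invisible to the cascades by
construction). The most site-promiscuous glycans are the biantennary
sialylated and oligo-mannose species:

```r
rank_glycans_by_sites(build_site_glycan_matrix(sim$glyco_psms), 5)
#>   glycan   n_sites n_psms  rank
#> 1 N4H5S2        92    756     1
#> 2 N4H5S1        84    703     2
#> 3 N4H5F1S1      69    529     3
#> 4 N2H8          67    503     4
#> 5 N5H6S3        62    498     5
```

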