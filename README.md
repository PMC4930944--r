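# ebprbin

Genome recovery and cycle chemistry analysis for enhanced biological
phosphorus removal (EBPR) communities.

EBPR plants rely on polyphosphate-accumulating organisms (PAOs); their
glycogen-accumulating competitors (GAOs) take up the same anaerobic carbon
without removing phosphorus. `ebprbin` implements the computational
workflow used to characterize such communities:

* **Differential-coverage genome binning** — scaffolds of a metagenome
  assembly are placed in the plane of their per-sample sequencing depths
  (`log10(depth + 0.01)`); scaffolds of one genome cluster together, and
  genomes whose abundance differs between samples separate. Selection is by
  explicit polygon or deterministic density clustering, refined with
  read-pair linkage and single-copy marker genes.
* **Marker-gene quality control** — completeness
  `100 · |distinct markers| / |catalog|` and duplication
  `100 · (hits − distinct) / |catalog|` over a catalog of 107 essential
  single-copy genes.
* **Bin statistics** — genome size, scaffold/contig counts, contig N50,
  GC, and per-sample abundance as the bin's share of aligned bases.
* **EBPR cycle stoichiometry** — anaerobic transformation ratios (P/VFA,
  Glycogen/VFA, PHA/VFA, PHB/VFA, PHV/VFA, all molar) and a two-component
  mixing estimator for the PAO fraction of the PAO+GAO biomass:

  *f* = (P/VFA₍obs₎ − P/VFA₍GAO₎) / (P/VFA₍PAO₎ − P/VFA₍GAO₎)

  with reference end members PAO (0.5, 0.5, 1.33, 1.33, 0) and GAO
  (0, 1.12, 1.85, 1.36, 0.46), endpoint-delta and initial-rate conventions
  both reported.
* **In-silico FISH probe evaluation** — probe site search with mismatches
  and single-base indels, competitor verification, per-taxon coverage
  tables, and 16S reference position mapping.
* **Synthetic-data generation** — communities, read alignments (SAM),
  cycle chemistry (CSV) and labelled 16S sets (FASTA + TSV) with known
  ground truth, so the entire pipeline is testable offline.

## Worked example

Recover genomes from a simulated two-sample community and summarize a bin:

```r
library(ebprbin)

truth      <- generate_community(demo_community_spec(seed = 1))
records    <- simulate_alignments(truth, depth_per_sample = 20)
profiles   <- compute_coverage(filter_alignments(records), truth$scaffolds)
candidates <- cluster_coverage(length_filter(profiles, 1000), "A", "B",
                               radius = 0.15)
hits       <- detect_markers(truth$scaffolds, truth$catalog)
summarize_bin(candidates[[1]], truth$scaffolds, profiles, hits, truth$catalog)
#> Genome size (Mbp)  0.10
#> Scaffolds          11
#> Contigs            11
#> Contig N50         9059
#> Max contig size    11907
#> GC content (%)     36.1
#> Completeness (%)   100.0
#> Contamination (%)  0.0
#> Abundance A (%)   2.7
#> Abundance B (%)   0.6
```

The bin is complete (all 107 single-copy markers present once), free of
duplicated markers, and makes up 2.7% of sample A's aligned bases. Checked
against the generator's ground truth, all ten genomes come back with
precision and recall 1.0 here (`bin_recovery(candidates, truth)`).

Estimate the PAO fraction from a cycle time series:

```r
cyc <- generate_cycle(cycle_spec(f_pao = 0.58, noise_sd_rel = 0.01, seed = 1))
transformation_ratios(cyc)
#> P/VFA 0.290  Glycogen/VFA 0.755  PHA/VFA 1.521  PHB/VFA 1.331  PHV/VFA 0.191  [endpoint]
pao_fraction(transformation_ratios(cyc))
#> PAO 58% / GAO 42% of the PAO+GAO biomass (basis: p_vfa)
```

With observed ratios entered directly (endpoint convention) and a
rate-based figure for comparison:

```r
obs <- ratio_set(p_vfa = 0.3, gly_vfa = 0.59, phb_vfa = 1.16, phv_vfa = 0.56)
pao_fraction_report(obs, rate_based_pct = 58)
#>           method f_pao_pct
#> 1 endpoint_p_vfa        60
#> 2     rate_based        58
```

The two conventions legitimately differ by a couple of percentage points;
the report shows both rather than forcing agreement.

A YAML-driven end-to-end run (simulation → coverage → markers → linkage →
binning → statistics, with a checksummed manifest) is available as
`run_pipeline("pipeline.yaml")`, or from a shell via the thin wrapper in
`inst/scripts/ebprbin`.

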