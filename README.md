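# stallscan

Detection of extreme ribosome-stalling sites in ribosome-profiling data and
permutation tests for which amino acids are enriched in the nascent-peptide
segment occupying the ribosomal exit tunnel when stalling happens.

## Who this is for

Groups analyzing paired ribo-seq / mRNA-seq coverage who want to ask, at
codon resolution: *where do ribosomes pause hardest, and does the peptide
upstream of the pause (the ~31 residues filling the exit tunnel) carry a
residue signature?* The package covers the full path from raw footprint
intervals to classified amino acids, plus a synthetic-data generator with
planted ground truth so every stage is testable without external data.

## The method

For each gene, ribo-seq and mRNA-seq profiles are reduced to codon
resolution, each scaled by its own coverage, and divided to give the
ribosomal density ratio RD/mRNA, which cancels biases shared by the two
libraries. After masking the first 20 codons and dropping genes with < 40%
non-zero coverage, a codon *i* is a **stalling peak** when

```
RD/mRNA(i)  >  mean + 4·SD        (mean, SD over positive unmasked codons)
```

The **Upstream Stalling Region** (USR) of a peak is the translation of
codons *i−31 … i−1* — the peptide inside the exit tunnel while codon *i*
is in the A-site. For every amino acid *a*, the observed score is the
number of peaks whose USR contains *a*; the null redraws peak positions
uniformly within each gene (keeping per-gene peak counts) 1000 times, and

```
p_a = #(null score ≥ observed score) / 1000
```

with Benjamini–Hochberg correction across the 20 amino acids and composite
tests for the charged classes K/R/H and E/D. Prokaryotic peaks explainable
by Shine–Dalgarno-like hexamers (≤ 1 substitution from GGAGGU, 8–11 nt
upstream of the A-site) are excluded. Position-specific occupancy along
the 31 tunnel positions and a tAI-based rare-codon confound check complete
the report. See the vignette (`vignettes/stalling-detection.Rmd`) for the
full model and design choices.

## Worked example

Simulate 100 genes with a planted proline stalling signal and run the
pipeline:

```r
library(stallscan)
cfg <- stalling_scenario("P", seed = 7, n_genes = 100)
sim <- simulate_dataset(cfg)
res <- run_stalling_analysis(sim, seed = 7)
print(res)
#> <stalling_analysis> simulation
#>   genes: 100 -> 100 after filters
#>   peaks: 544 called, 433 tested
#>  significant amino acids: A(unde, p=0.994) C(over, p=0) D(unde, p=0.998)
#>    I(unde, p=0.998) L(over, p=0.035) P(over, p=0) W(over, p=0.037)
#>    Y(unde, p=0.993)

res$enrichment[res$enrichment$amino_acid %in% c("P", "K", "A"), ]
#>  amino_acid observed n_peaks observed_probability null_mean p_enriched q_value   classification
#>           A      369     433                0.852     383.5      0.994   0.998 underrepresented
#>           K      283     433                0.654     292.8      0.862   0.998  not_significant
#>           P      345     433                0.797      22.1      0.000   0.000  overrepresented
```

The planted amino acid P appears in 79.7% of the tested USRs against a
null expectation of 5.1% (22.1 of 433), empirical p = 0 (below 1/1000),
and is classified overrepresented; lysine, not planted, matches its null.
Secondary calls such as C illustrate a documented property of block-like
planted signals: consecutive peaks share overlapping USRs, which inflates
the variability of scores for co-occurring residues relative to the
scatter-position null (see "Known limitations" in the vignette).
`write_analysis(res, dir)` writes the classification, charge, peak and
profile tables plus a JSON manifest; rerunning with the same seed
reproduces them byte for byte.

A thin CLI over the same functions lives at `inst/cli/stallscan.R`
(`simulate` and `run-all` subcommands driven by a YAML config).

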