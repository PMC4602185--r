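---
title: "Detecting ribosome stalling and exit-tunnel amino acid enrichment"
author: "stallscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ribosome stalling and exit-tunnel amino acid enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stallscan)
```

## The question and the model

During elongation the nascent peptide threads through the ribosomal exit
tunnel, a channel long enough to hold roughly 31 amino acids. If particular
residues interact with the tunnel wall, ribosomes should pause
preferentially at codons whose *upstream* 31 codons encode those residues.
`stallscan` turns that idea into a statistical pipeline over paired
ribo-seq and mRNA-seq coverage:

1. **A-site assignment.** Footprints are collapsed to single A-site
   positions: eukaryotic fragments at a fixed 15-nt offset from the 5' end
   (`map_eukaryotic()`); prokaryotic fragments, whose ends are blurred by
   micrococcal nuclease, by trimming 12 nt from each end and spreading a
   unit mass of 1/N over the N remaining central positions
   (`map_prokaryotic()`). Both conserve read mass exactly.
2. **Codon resolution.** Nucleotide counts are averaged in triplets
   (`to_codon_resolution()`).
3. **Filtering.** The first 20 codons of every gene are masked (ramp
   region, known initiation biases), and genes with fewer than 40%
   non-zero ribo-seq codons are removed (`filter_profiles()`); sparse
   profiles make the peak statistics meaningless.
4. **Normalization.** Each profile is scaled by its own gene coverage and
   the per-codon ratio RD/mRNA is formed (`normalize_rd_over_mrna()`).
   Dividing by matched mRNA-seq cancels sequence-dependent biases shared by
   the two libraries. Codons with zero mRNA signal are masked, never
   imputed. A `ribo_only` mode skips the mRNA step as a control.
5. **Peak calling.** Within each gene, the mean and SD of the RD/mRNA
   profile are computed over positive unmasked codons, and codons strictly
   exceeding mean + 4 SD are stalling peaks (`call_peaks()`). The
   4-SD choice is anchored to a practical constraint: the union of the
   peaks' upstream windows must stay below 20% of the protein
   (`usr_coverage()`), otherwise the permutation null below has no room to
   redraw positions; genes over that bound are excluded from the tests.
6. **USR extraction.** The Upstream Stalling Region of a peak at codon i
   is the translation of codons i-31 ... i-1 -- the peptide occupying the
   tunnel while codon i is in the A-site (`extract_usr()`). Peaks closer
   than 31 codons to the start have truncated windows, which would bias
   per-amino-acid occurrence probabilities; they are excluded.
7. **Shine-Dalgarno control (prokaryotes).** Internal SD-like hexamers
   hybridize with the 16S rRNA and pause ribosomes regardless of the
   nascent chain. Peaks with a hexamer within one substitution of GGAGGU
   ending 8-11 nt upstream of the A-site are excluded
   (`filter_sd_peaks()`).
8. **Permutation enrichment.** For each amino acid, the observed score is
   the number of peaks whose USR contains it at least once. The null
   redraws peak positions uniformly from each gene's eligible codons,
   keeping the per-gene peak count fixed (`randomize_peaks()`), 1000
   times; the empirical p-value is the fraction of null scores at least as
   large (ties count; no pseudo-count). Composite tests score the charged
   classes K/R/H and E/D the same way (`charged_enrichment()`).
   Enrichment p-values across the 20 amino acids are Benjamini-Hochberg
   adjusted (`classify_amino_acids()`).
9. **Tunnel positions.** `positional_probabilities()` resolves occupancy
   by tunnel position (1 = P-site-proximal, 31 = distal);
   `flag_extreme_positions()` flags entries outside the central 95% of the
   permutation null.
10. **Rare-codon confound.** If peaks merely mark slowly decoded codons,
    P-site codon occupancy should anti-correlate with codon optimality.
    `compute_tai()` implements the tRNA adaptation index from tRNA gene
    copy numbers with the standard wobble penalties, and
    `tai_occupancy_correlation()` reports the Spearman correlation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `exclude_first` | 20 codons | ramp region masked from all statistics |
| `min_nonzero_fraction` | 0.40 | minimum non-zero ribo codon fraction per gene |
| `k_sd` | 4 | peak threshold in SDs above the gene mean |
| `tunnel_window` | 31 codons | USR length = tunnel capacity |
| `max_usr_coverage` | 0.20 | per-gene bound on USR union before exclusion |
| `n_randomizations` | 1000 | permutation draws |
| `alpha` | 0.05 | classification level |
| SD spacings | 8,9,10,11 nt | anti-SD to A-site spacing scanned |

Raising `min_nonzero_fraction` (say to 0.60) removes a superset of genes
and, on strongly planted synthetic signals, never flips an amino acid
between over- and underrepresented -- the robustness property the test
suite checks.

## Numerical and design choices

* **Coordinates** are 1-based and inclusive throughout, the R and
  Bioconductor convention; a eukaryotic read starting at nucleotide 1 maps
  to nucleotide 16. Wiggle output is 1-based fixed-step.
* **Ties at the peak threshold** are not peaks (strict inequality): a
  constant profile has no peaks.
* **The coverage mean** used for profile scaling includes zero codons
  (plain mean over unmasked positions); a flag switches to the
  non-zero-only mean. Including zeros keeps the ratio well defined and
  matches coverage as conventionally computed.
* **SD and mean are computed over the same set** (positive, unmasked
  codons) -- the only coherent reading of the peak rule.
* **One shared set of null draws** serves the 20 amino-acid tests, both
  charge tests and the positional flags. Sharing changes nothing in
  expectation and makes the whole report reproducible from one seed;
  independent draws are available by calling the test functions
  separately.
* **Eligible null positions** are unmasked codons with index > 31, so
  every random USR is complete and mRNA-valid, mirroring the constraints
  on real tested peaks.
* **The SD spacing set** defaults to the full optimal range 8-11 nt; a
  strict `c(8, 9, 11)` variant is accepted because the narrower set is
  sometimes quoted, and the choice is recorded in the run manifest.
* **The P-site codon** for the rare-codon check is one codon upstream of
  the peak (peak coordinates denote the A-site); `site = "asite"` uses the
  peak codon itself.
* **The positional significance procedure** is an interpretive choice:
  red/green-style flags could compare a position against the other
  positions of its own row or against a randomization null. Both are
  implemented (`mode = "row_percentile"` and `mode = "null"`); the null
  mode is the default because it inherits the peak-count structure of the
  data instead of assuming within-row exchangeability.
* **p = 0** is stored as 0.0 (the plain counting formula); with 1000
  draws this means "below 1/1000".

## The synthetic generator

Real ribosome profiling is noisy, biased and unlabeled, so the package
ships a generator (`synthetic_config()`, `simulate_dataset()`) that plants
a known stalling signal and provides ground truth for every downstream
stage. Per gene, a mean mRNA coverage is drawn log-uniformly (default
0.1-10 reads/nt, wide enough that the 40% filter is genuinely exercised),
mRNA counts are negative-binomial around it (dispersion 0.05; ribo-seq
counts are overdispersed in practice, and NB reduces to Poisson as the
dispersion goes to 0), and ribo counts are drawn per codon proportionally
to mRNA abundance times a relative dwell time, then split multinomially
over the codon's three nucleotides. The planted signal multiplies the
dwell time of every codon whose upstream 31-codon window contains a
trigger amino acid (`stall_mode = "window"`); the `"adjacent"` mode
instead elevates only the codon immediately after a trigger, modeling
position-specific pausing such as a P-site-proline effect, and is what the
tunnel-position recovery tests use.

Recovery scenarios (`stalling_scenario()`) make the trigger amino acids
rare (codon usage 0.001 per trigger) in long genes (600 codons). The
numbers follow from the peak rule, not from tuning: a block of codons at
multiplier M clears mean + 4 SD only if the elevated fraction f of the
gene satisfies f + 4*sqrt(f(1-f)) < 1, i.e. f below about 6%; one trigger
elevates a full 31-codon block, so genes must be long and triggers rare,
and genes with two or more triggers exceed the 20% USR-coverage bound and
drop out of the tests, which is the bound doing its job.

The generator does **not** emulate UTRs, introns, isoforms, ramp-region
bias (it is masked anyway), sequence-dependent ligation/PCR bias, or
codon-level dwell variation beyond the planted signal. Passing
recovery tests therefore demonstrates that the statistical machinery is
correct and calibrated, not that any particular biological dataset will
show a particular amino acid.

## Problem sizes used in validation

The test suite and the acceptance script validate on: a 2-gene toy whose
permutation null is enumerated exhaustively (90-660 placements) and
compared with 1000 Monte-Carlo draws; 20 null datasets of 200 genes x 300
codons for type-I calibration (the fraction of significant amino-acid
calls stays within a binomial band around the nominal 5%, allowing for the
conservatism of discrete empirical p-values); and 10-20 replicates per
planted scenario ({P}, {K,R}, {D} at multiplier 50) for recovery. These
sizes give stable rates while keeping a full validation run in minutes on
one core.

## Known limitations

* **Clustered peaks violate the independence the null assumes.** Under
  the window dwell model a single trigger elevates 31 consecutive codons,
  so a signal gene contributes a run of peaks whose USRs are overlapping
  shifted windows of one short sequence patch. The permutation null
  redraws the same number of positions but scatters them independently,
  so for amino acids that merely co-occur in those patches the observed
  score is far more variable than the null score, and enrichment
  p-values for non-planted amino acids become anti-conservative (the
  acceptance script measures this rate in the recovery scenarios). Real
  data with isolated extreme pauses, or the `"adjacent"` generator mode,
  do not have this geometry. Interpreting secondary hits next to a
  dominant, block-like signal therefore requires care; the per-gene peak
  counts in the manifest show when peaks cluster.
* Empirical p-values are bounded below by 1/`n_randomizations`; FDR
  rankings among very small p-values are ties.
* The SD filter is string matching, deliberately: no hybridization
  energetics.
* The tAI s-values are the standard defaults and are not re-optimized per
  organism; the computed `w` vector is logged so any other set can be
  substituted.

## A minimal run

```{r example, eval = FALSE}
cfg <- stalling_scenario("P", seed = 7, n_genes = 100)
sim <- simulate_dataset(cfg)
res <- run_stalling_analysis(sim, seed = 7)
res$enrichment[res$enrichment$amino_acid == "P", ]
write_analysis(res, "stallscan_out")
```
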