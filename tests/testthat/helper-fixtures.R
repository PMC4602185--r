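# Shared fixtures: hand-built genes, toy bundles and the exhaustive
# peak-placement enumeration oracle used against the permutation machinery.

# One representative codon per amino acid (reverse genetic code).
AA_TO_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                 M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                 S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

# Build a coding_region from an amino-acid string (no terminal stop).
gene_from_protein <- function(id, protein) {
  aa <- strsplit(protein, "")[[1]]
  coding_region(id, paste(AA_TO_CODON[aa], collapse = ""))
}

# Raw bundle from per-gene codon vectors; mrna defaults to flat coverage.
toy_bundle <- function(ribo, mrna = NULL, domain = "eukaryote") {
  if (is.null(mrna)) mrna <- lapply(ribo, function(v) rep(1, length(v)))
  dataset_bundle(ribo, mrna, dataset_id = "toy", domain = domain)
}

# Build a prokaryotic gene whose peak at codon `peak` has `hex` ending
# `spacing` nt upstream of the A-site first nucleotide.
sd_gene <- function(hex, peak = 30L, spacing = 9L) {
  seq <- strrep("GCT", 120)
  a <- 3 * (peak - 1) + 1
  from <- a - spacing - 6
  substr(seq, from, from + 5) <- hex
  coding_region("g", seq)
}

# Exhaustive null of the per-amino-acid score statistic: enumerate every
# combination of peak placements over the genes' eligible sets and return
# the exact score distribution for the given target amino acid.
enumerate_null_scores <- function(genes, eligible, peaks_per_gene, target,
                                  tunnel_window = 31L) {
  per_gene_choices <- lapply(names(peaks_per_gene), function(g) {
    utils::combn(eligible[[g]], peaks_per_gene[[g]], simplify = FALSE)
  })
  contains_target <- function(g, pos) {
    aa <- translate_codons(genes[[g]]$codons[(pos - tunnel_window):(pos - 1)])
    any(aa %in% target)
  }
  grids <- expand.grid(lapply(per_gene_choices, seq_along))
  apply(grids, 1, function(row) {
    s <- 0L
    for (gi in seq_along(row)) {
      g <- names(peaks_per_gene)[gi]
      for (pos in per_gene_choices[[gi]][[row[gi]]])
        s <- s + contains_target(g, pos)
    }
    s
  })
}
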