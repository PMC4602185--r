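Package: stallscan
Title: Detection of Ribosome Stalling Sites and Exit-Tunnel Amino Acid
    Enrichment from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating extreme ribosome stalling events in paired
    ribo-seq/mRNA-seq coverage profiles and for testing which amino acids are
    enriched in the nascent-peptide exit tunnel at those events. Footprints
    are mapped to ribosomal A-site positions (5' offset for eukaryotes,
    weighted-center rule for prokaryotes), profiles are converted to codon
    resolution, coverage-filtered and normalized to ribosomal density over
    mRNA, and stalling peaks are called as codons exceeding the gene mean by
    a standard-deviation threshold. The 31 codons upstream of each peak (the
    exit-tunnel occupancy window) are scored for per-amino-acid and
    charged-class enrichment against a permutation null that redraws peak
    positions gene by gene, with Benjamini-Hochberg FDR control,
    position-specific tunnel occupancy maps, Shine-Dalgarno controls for
    bacteria, and a tRNA adaptation index confound check. A synthetic-data
    module generates coding sequences and count profiles with planted
    stalling signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
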