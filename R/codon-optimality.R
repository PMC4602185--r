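# tRNA adaptation index (tAI) and the rare-codon confound check: the
# Spearman correlation between per-codon P-site occupancy at stalling peaks
# and tAI. A strong negative correlation would mean peaks are trivially
# explained by slowly decoded (rare) codons rather than the nascent peptide.

#' Default wobble selective constraints (s-values)
#'
#' The standard constraint set for the tAI pairing classes: Watson-Crick
#' pairings are unpenalized; wobble pairings are penalized by class
#' (anticodon G reading codon U, inosine reading C, inosine reading A,
#' anticodon U reading codon G, and lysidine-modified CAU reading AUA in
#' bacteria).
#'
#' @return Named numeric vector of s-values in `[0, 1]`.
#' @export
default_s_values <- function() {
  c("G:U" = 0.41, "I:C" = 0.28, "I:A" = 0.9999, "U:G" = 0.68,
    "L:A" = 0.89)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""),
                function(s) paste(rev(s), collapse = ""), ""))
}

#' Compute per-codon tAI relative adaptiveness
#'
#' For each sense codon, the absolute adaptiveness W sums `(1 - s) * tGCN`
#' over the anticodons able to decode it: the Watson-Crick anticodon plus
#' the class-specific wobble anticodon (codon ending U also read by the
#' anticodon starting G; ending C and A by the inosine-modified anticodon
#' starting A; ending G by the anticodon starting U). In prokaryotes the
#' isoleucine codon AUA additionally gains `(1 - s[L:A]) * tGCN(CAU)`
#' through lysidine modification. Relative adaptiveness is `w = W / max(W)`;
#' codons with W = 0 are assigned the geometric mean of the non-zero w
#' values (the usual convention, so missing anticodons do not zero out the
#' index).
#'
#' @param tgcn Named non-negative vector of tRNA gene copy numbers per
#'   anticodon (5'->3', DNA or RNA alphabet).
#' @param s_values Named s-value vector as in [default_s_values()].
#' @param domain `"eukaryote"` or `"prokaryote"`.
#' @return Named numeric vector `w` over the 61 sense codons, max 1.
#' @export
compute_tai <- function(tgcn, s_values = default_s_values(),
                        domain = c("eukaryote", "prokaryote")) {
  domain <- match.arg(domain)
  names(tgcn) <- toupper(gsub("U", "T", names(tgcn)))
  if (all(tgcn == 0)) stop("all tRNA gene copy numbers are zero")
  cn <- function(ac) if (ac %in% names(tgcn)) tgcn[[ac]] else 0
  codons <- sense_codons()
  W <- vapply(codons, function(c3) {
    stem <- substr(c3, 1, 2)
    third <- substr(c3, 3, 3)
    w <- cn(revcomp(c3))  # Watson-Crick anticodon
    w <- w + switch(third,
      T = (1 - s_values[["G:U"]]) * cn(revcomp(paste0(stem, "C"))),
      C = (1 - s_values[["I:C"]]) * cn(revcomp(paste0(stem, "T"))),
      A = (1 - s_values[["I:A"]]) * cn(revcomp(paste0(stem, "T"))),
      G = (1 - s_values[["U:G"]]) * cn(revcomp(paste0(stem, "A"))))
    w
  }, numeric(1))
  if (domain == "prokaryote")
    W[["ATA"]] <- W[["ATA"]] + (1 - s_values[["L:A"]]) * cn("CAT")
  w <- W / max(W)
  zero <- w == 0
  if (any(zero) && any(!zero))
    w[zero] <- exp(mean(log(w[!zero])))
  w
}

#' Read a tRNA gene copy number table
#'
#' Tab-separated with columns `anticodon` and `copy_number`.
#'
#' @param path File path.
#' @return Named numeric vector per anticodon.
#' @export
read_tgcn <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df$copy_number, df$anticodon)
}

#' Per-codon P-site occupancy probability at peaks
#'
#' The probability that each of the 61 sense codons sits in the ribosomal
#' P-site when a stall occurs. Peak coordinates denote the A-site, so the
#' P-site codon is one codon upstream of the peak (`site = "psite"`,
#' default); `site = "asite"` uses the peak codon itself.
#'
#' @param peaks Peak data frame (`gene_id`, `codon_index`).
#' @param genes Named list of [coding_region()] objects.
#' @param site `"psite"` or `"asite"`.
#' @return Named probability vector over the 61 sense codons (sums to 1).
#' @export
psite_occupancy <- function(peaks, genes, site = c("psite", "asite")) {
  site <- match.arg(site)
  if (!nrow(peaks)) stop("no peaks")
  shift <- if (site == "psite") 1L else 0L
  cod <- vapply(seq_len(nrow(peaks)), function(k) {
    g <- genes[[peaks$gene_id[k]]]
    i <- peaks$codon_index[k] - shift
    if (i < 1L) NA_character_ else g$codons[i]
  }, "")
  cod <- cod[!is.na(cod) & cod %in% sense_codons()]
  if (!length(cod)) stop("no peaks with a defined sense codon at the site")
  tab <- table(factor(cod, levels = sense_codons()))
  stats::setNames(as.numeric(tab) / length(cod), sense_codons())
}

#' Spearman correlation between P-site occupancy and tAI
#'
#' @param occupancy Named vector from [psite_occupancy()].
#' @param tai Named `w` vector from [compute_tai()].
#' @return List with `rho`, `p` and `n` (codons used). Constant input gives
#'   `rho = NA` with a message.
#' @export
tai_occupancy_correlation <- function(occupancy, tai) {
  codons <- intersect(names(occupancy), names(tai))
  x <- occupancy[codons]
  y <- tai[codons]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(codons)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(codons))
}
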