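# Stalling-peak detection in RD/mRNA codon profiles, extraction of the
# 31-codon upstream stalling region (USR), USR-coverage bookkeeping and the
# Shine-Dalgarno confound filter for prokaryotes.

#' Call stalling peaks in a codon profile
#'
#' The gene's mean and standard deviation are computed over unmasked codons
#' with value > 0; a codon is a peak iff its value strictly exceeds
#' `mean + k_sd * sd`. With fewer than two positive unmasked codons the SD
#' is undefined and no peaks are returned (warning).
#'
#' @param x Numeric per-codon profile (typically RD/mRNA, `NA` at masked
#'   codons) or a [dataset_bundle()] with an `rd` slot.
#' @param mask Logical validity vector (numeric method only); masked codons
#'   can be neither peaks nor part of the mean/SD.
#' @param k_sd Threshold in standard deviations above the mean (default 4).
#' @param ... Passed to methods.
#' @return Data frame with columns `gene_id` (bundle method), `codon_index`
#'   (1-based), `value`, sorted by position.
#' @export
call_peaks <- function(x, ...) UseMethod("call_peaks")

#' @rdname call_peaks
#' @export
call_peaks.numeric <- function(x, mask = rep(TRUE, length(x)), k_sd = 4,
                               ...) {
  ok <- mask & !is.na(x)
  pos <- ok & x > 0
  if (sum(pos) < 2L) {
    warning("fewer than 2 positive unmasked codons; no peaks called")
    return(data.frame(codon_index = integer(0), value = numeric(0)))
  }
  mu <- mean(x[pos])
  sigma <- stats::sd(x[pos])
  idx <- which(ok & x > mu + k_sd * sigma)
  data.frame(codon_index = idx, value = x[idx])
}

#' @rdname call_peaks
#' @export
call_peaks.dataset_bundle <- function(x, k_sd = 4, ...) {
  if (is.null(x$rd)) stop("bundle has no rd profiles; run ",
                          "normalize_rd_over_mrna() first")
  per_gene <- lapply(names(x$rd), function(g) {
    p <- suppressWarnings(
      call_peaks(x$rd[[g]], mask = x$mask[[g]], k_sd = k_sd))
    if (nrow(p)) cbind(gene_id = g, p) else NULL
  })
  out <- do.call(rbind, per_gene)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), codon_index = integer(0),
                      value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Attach upstream stalling regions (USRs) to peaks
#'
#' The USR of a peak at codon i is the translation of codons
#' `(i - tunnel_window) ... (i - 1)` -- the amino acids filling the exit
#' tunnel while codon i sits in the A-site -- written N- to C-terminal (the
#' last character is the P-site-proximal residue). Peaks too close to the
#' start for a full window are marked `usr_complete = FALSE` and must be
#' excluded from enrichment statistics.
#'
#' @param peaks Peak data frame from [call_peaks()] (with `gene_id`).
#' @param genes Named list of [coding_region()] objects.
#' @param tunnel_window USR length in codons (default 31).
#' @return `peaks` with `usr` (character, `NA` when incomplete) and
#'   `usr_complete` columns.
#' @export
extract_usr <- function(peaks, genes, tunnel_window = 31L) {
  usr <- character(nrow(peaks))
  complete <- logical(nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    g <- genes[[peaks$gene_id[k]]]
    i <- peaks$codon_index[k]
    if (i > g$n_codons)
      stop("peak at codon ", i, " beyond gene ", g$gene_id)
    if (i >= tunnel_window + 1L) {
      aa <- translate_codons(g$codons[(i - tunnel_window):(i - 1L)])
      usr[k] <- paste(aa, collapse = "")
      complete[k] <- TRUE
    } else {
      usr[k] <- NA_character_
      complete[k] <- FALSE
    }
  }
  peaks$usr <- usr
  peaks$usr_complete <- complete
  peaks
}

#' Fraction of a protein covered by its USRs
#'
#' Computes, per gene, the fraction of the protein covered by the union of
#' the USR intervals of its peaks. The peak-threshold choice is anchored to
#' this quantity: genes where USRs cover more than `max_coverage` of the
#' protein cannot be meaningfully randomized and are flagged (and by
#' default excluded from the permutation tests).
#'
#' @param peaks Peak data frame (with `gene_id`, `codon_index`).
#' @param genes Named list of [coding_region()] objects.
#' @param tunnel_window USR length (codons).
#' @param max_coverage Flag threshold (default 0.20).
#' @return Data frame `gene_id`, `coverage`, `flagged`, one row per gene in
#'   `genes` (coverage 0 for peakless genes).
#' @export
usr_coverage <- function(peaks, genes, tunnel_window = 31L,
                         max_coverage = 0.20) {
  ids <- names(genes)
  cov <- vapply(ids, function(gid) {
    g <- genes[[gid]]
    n_aa <- length(g$protein)
    covered <- logical(n_aa)
    for (i in peaks$codon_index[peaks$gene_id == gid]) {
      lo <- max(i - tunnel_window, 1L)
      hi <- min(i - 1L, n_aa)
      if (lo <= hi) covered[lo:hi] <- TRUE
    }
    mean(covered)
  }, numeric(1))
  data.frame(gene_id = ids, coverage = as.numeric(cov),
             flagged = as.numeric(cov) > max_coverage, row.names = NULL)
}

hexamer_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Flag peaks explainable by Shine-Dalgarno-like pausing (prokaryotes)
#'
#' Internal hexamers resembling the Shine-Dalgarno motif hybridize with the
#' 16S rRNA and pause elongation independently of the nascent peptide, so
#' such peaks are a confound. A peak is flagged if, for any spacing s in
#' `spacings`, the hexamer whose 3' end lies s nucleotides upstream of the
#' first nucleotide of the A-site codon is within `max_mismatch`
#' substitutions of the canonical motif. Windows extending before the CDS
#' start are skipped.
#'
#' @param peaks Peak data frame (with `gene_id`, `codon_index`).
#' @param genes Named list of [coding_region()] objects.
#' @param canonical Canonical SD hexamer (RNA or DNA alphabet).
#' @param max_mismatch Maximum substitutions (default 1).
#' @param spacings Spacings (nt) between the hexamer 3' end and the A-site
#'   codon. Default `c(8, 9, 10, 11)`, the optimal anti-SD spacing range;
#'   `c(8, 9, 11)` reproduces a stricter literal variant.
#' @return `peaks` with a logical `sd_flagged` column (flagged = SD-like
#'   motif found; exclude these from enrichment).
#' @export
filter_sd_peaks <- function(peaks, genes, canonical = "GGAGGU",
                            max_mismatch = 1L, spacings = c(8L, 9L, 10L, 11L)) {
  canonical <- toupper(gsub("U", "T", canonical))
  w <- nchar(canonical)
  flagged <- logical(nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    g <- genes[[peaks$gene_id[k]]]
    a <- 3L * (peaks$codon_index[k] - 1L) + 1L  # first nt of A-site codon
    for (s in spacings) {
      from <- a - s - w
      if (from < 1L) next
      hex <- substr(g$sequence, from, a - s - 1L)
      if (hexamer_mismatches(hex, canonical) <= max_mismatch) {
        flagged[k] <- TRUE
        break
      }
    }
  }
  peaks$sd_flagged <- flagged
  peaks
}

#' Write peaks as a BED-like tab-separated table
#'
#' @param peaks Peak data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
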