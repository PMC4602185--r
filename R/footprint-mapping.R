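# Mapping raw footprint intervals (per-gene CDS coordinates) to
# nucleotide-resolution A-site density tracks.

#' Map eukaryotic footprints to A-site positions (5' offset rule)
#'
#' Each footprint contributes +1 at `start + offset` nucleotides: the
#' ribosomal A-site of a eukaryotic fragment is located at a fixed 15-nt
#' offset from its 5' end. Reads whose offset position falls outside the
#' CDS are dropped and counted in the `n_dropped` attribute.
#'
#' @param reads Data frame with columns `start` (1-based first nucleotide of
#'   the footprint in CDS coordinates) and `length` (nt); all reads belong
#'   to one gene.
#' @param cds_length CDS length in nucleotides.
#' @param offset A-site offset from the 5' end (default 15 nt, so a read
#'   starting at position 1 maps to position 16).
#' @return Numeric vector of length `cds_length` (class attribute-free
#'   nucleotide profile) with attribute `n_dropped`.
#' @export
map_eukaryotic <- function(reads, cds_length, offset = 15L) {
  if (cds_length < 0) stop("cds_length must be non-negative")
  pos <- reads$start + offset
  keep <- pos >= 1L & pos <= cds_length
  prof <- numeric(cds_length)
  if (any(keep)) {
    tab <- tabulate(pos[keep], nbins = cds_length)
    prof <- as.numeric(tab)
  }
  attr(prof, "n_dropped") <- sum(!keep)
  prof
}

#' Map prokaryotic footprints to A-site positions (weighted-center rule)
#'
#' Prokaryotic fragment ends are imprecise (micrococcal nuclease), so 12 nt
#' are trimmed from each end and each of the N = length - 24 remaining
#' central positions receives a score of 1/N, blurring the read's unit mass
#' uniformly across them. Reads with length <= 24 (N <= 0) are dropped with
#' a warning; central positions falling outside the CDS are clipped (mass
#' at clipped positions is lost).
#'
#' @inheritParams map_eukaryotic
#' @param trim Nucleotides trimmed from each end (default 12).
#' @return Numeric vector of length `cds_length` with attribute `n_dropped`.
#' @export
map_prokaryotic <- function(reads, cds_length, trim = 12L) {
  if (cds_length < 0) stop("cds_length must be non-negative")
  prof <- numeric(cds_length)
  n_central <- reads$length - 2L * trim
  drop <- n_central <= 0L
  if (any(drop))
    warning(sum(drop), " read(s) shorter than ", 2L * trim + 1L,
            " nt dropped (no central positions after trimming)")
  keep <- which(!drop)
  for (i in keep) {
    from <- reads$start[i] + trim
    to <- reads$start[i] + reads$length[i] - 1L - trim
    w <- 1 / n_central[i]
    rng <- max(from, 1L):min(to, cds_length)
    if (length(rng) && rng[1] <= rng[length(rng)])
      prof[rng] <- prof[rng] + w
  }
  attr(prof, "n_dropped") <- sum(drop)
  prof
}

#' Read a footprint table
#'
#' Tab-separated with columns `gene_id`, `start` (1-based CDS coordinate of
#' the 5' end) and `length` (nt).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_footprints <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Map a footprint table to per-gene nucleotide profiles
#'
#' @param reads Data frame from [read_footprints()].
#' @param cds_lengths Named integer vector of CDS lengths (nt) per gene.
#' @param rule `"eukaryotic"` (5' offset) or `"prokaryotic"`
#'   (weighted center).
#' @param ... Passed to the per-gene mapper.
#' @return Named list of nucleotide profiles.
#' @export
map_footprints <- function(reads, cds_lengths,
                           rule = c("eukaryotic", "prokaryotic"), ...) {
  rule <- match.arg(rule)
  mapper <- if (rule == "eukaryotic") map_eukaryotic else map_prokaryotic
  out <- lapply(names(cds_lengths), function(g) {
    mapper(reads[reads$gene_id == g, , drop = FALSE], cds_lengths[[g]], ...)
  })
  names(out) <- names(cds_lengths)
  out
}
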