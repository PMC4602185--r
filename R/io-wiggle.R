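# Wiggle-track I/O. Per-gene coverage is exchanged as fixed-step wiggle
# (one track per gene, step 1, 1-based positions along the CDS).

#' Write per-gene coverage as a fixed-step wiggle file
#'
#' One `fixedStep` track per gene, `chrom` set to the gene id, start 1,
#' step 1, one value per CDS nucleotide.
#'
#' @param profiles Named list of numeric per-nucleotide vectors.
#' @param path Output file.
#' @param name Track name recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_wiggle_tracks <- function(profiles, path, name = "coverage") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=%s", name), con)
  for (g in names(profiles)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", g), con)
    writeLines(format(profiles[[g]], trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' Read per-gene coverage from a wiggle file
#'
#' Parses with `rtracklayer` and expands the scored ranges to one value per
#' nucleotide. Track `chrom` names are taken as gene ids.
#'
#' @param path Wiggle file.
#' @param cds_lengths Optional named vector of CDS lengths (nt); profiles
#'   are padded/clipped to these lengths. If omitted, each profile ends at
#'   the last covered position.
#' @return Named list of numeric per-nucleotide vectors.
#' @export
read_wiggle_tracks <- function(path, cds_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "wig")
  df <- as.data.frame(gr)
  genes <- unique(as.character(df$seqnames))
  out <- lapply(genes, function(g) {
    d <- df[df$seqnames == g, , drop = FALSE]
    len <- if (is.null(cds_lengths)) max(d$end) else cds_lengths[[g]]
    v <- numeric(len)
    for (i in seq_len(nrow(d))) {
      rng <- d$start[i]:min(d$end[i], len)
      if (d$start[i] <= len) v[rng] <- d$score[i]
    }
    v
  })
  names(out) <- genes
  if (!is.null(cds_lengths)) out <- out[names(cds_lengths)]
  out
}
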