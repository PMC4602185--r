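# End-to-end orchestration: codon conversion -> filtering -> RD/mRNA
# normalization -> peak calling -> USR extraction and filters -> permutation
# enrichment -> tunnel positions -> optional tAI confound check.

#' Run the full stalling analysis on one dataset
#'
#' Takes a raw codon-resolution [dataset_bundle()] (or a
#' [simulate_dataset()] result, whose nucleotide profiles are averaged to
#' codons first), applies the filtering and normalization cascade, calls
#' stalling peaks, applies the USR-completeness, USR-coverage and (for
#' prokaryotes) Shine-Dalgarno filters, and runs the permutation enrichment
#' tests and the tunnel-position analysis on the retained peaks. One shared
#' set of randomized peak placements drives the per-amino-acid, charged
#' class and positional tests, so the whole report is reproducible from one
#' seed.
#'
#' @param x A raw [dataset_bundle()] or a [simulate_dataset()] result.
#' @param genes Named list of [coding_region()] objects (ignored when `x`
#'   is a simulation, which carries its own).
#' @param min_nonzero_fraction,exclude_first Coverage filter parameters
#'   (defaults 0.40 and 20 codons).
#' @param k_sd Peak threshold in SDs above the gene mean (default 4).
#' @param tunnel_window USR length in codons (default 31).
#' @param alpha Significance level for classification (default 0.05).
#' @param n_randomizations Null draws (default 1000).
#' @param max_usr_coverage Genes whose USRs cover more of the protein than
#'   this are excluded from the permutation tests (default 0.20).
#' @param ribo_only Skip the mRNA normalization (control mode).
#' @param sd_spacings Shine-Dalgarno spacing set (prokaryotes only).
#' @param positional Also compute the tunnel-position matrices and flags.
#' @param tgcn Optional named tRNA gene copy number vector; when given, the
#'   tAI/P-site-occupancy Spearman check is run.
#' @param seed RNG seed for the randomizations.
#' @return Object of class `stalling_analysis`: list with the processed
#'   `bundle`, `peaks` (all called peaks, annotated), `peaks_tested` (the
#'   subset entering the statistics), `enrichment`, `charge`, `positional`
#'   (or `NULL`), `tai` (or `NULL`) and a `manifest` of per-stage counts
#'   and parameters.
#' @export
run_stalling_analysis <- function(x, genes = NULL,
                                  min_nonzero_fraction = 0.40,
                                  exclude_first = 20L, k_sd = 4,
                                  tunnel_window = 31L, alpha = 0.05,
                                  n_randomizations = 1000L,
                                  max_usr_coverage = 0.20,
                                  ribo_only = FALSE,
                                  sd_spacings = c(8L, 9L, 10L, 11L),
                                  positional = FALSE, tgcn = NULL,
                                  seed = 1L) {
  if (inherits(x, "stalling_simulation")) {
    genes <- x$genes
    x <- dataset_bundle(lapply(x$ribo, to_codon_resolution),
                        lapply(x$mrna, to_codon_resolution),
                        dataset_id = "simulation")
  }
  stopifnot(inherits(x, "dataset_bundle"), !is.null(genes))
  n_in <- length(x$ribo)

  bundle <- filter_profiles(x, min_nonzero_fraction, exclude_first)
  n_filtered <- length(bundle$ribo)
  bundle <- normalize_rd_over_mrna(
    bundle, mode = if (ribo_only) "ribo_only" else "rd_over_mrna")
  n_normalized <- length(bundle$ribo)

  peaks <- call_peaks(bundle, k_sd = k_sd)
  peaks <- extract_usr(peaks, genes, tunnel_window)
  if (bundle$domain == "prokaryote" && nrow(peaks)) {
    peaks <- filter_sd_peaks(peaks, genes, spacings = sd_spacings)
  } else {
    peaks$sd_flagged <- rep(FALSE, nrow(peaks))
  }
  coverage <- usr_coverage(peaks, genes, tunnel_window, max_usr_coverage)
  over_covered <- coverage$gene_id[coverage$flagged]

  tested <- peaks[peaks$usr_complete & !peaks$sd_flagged &
                  !(peaks$gene_id %in% over_covered), , drop = FALSE]

  eligible <- eligible_positions(bundle, tunnel_window)
  eligible <- eligible[setdiff(names(eligible), over_covered)]

  randomized <- NULL
  if (nrow(tested)) {
    randomized <- randomize_peaks(tested, eligible, n_randomizations,
                                  seed = seed)
  }
  enrichment <- suppressWarnings(
    classify_amino_acids(tested, genes, eligible, n_randomizations, alpha,
                         tunnel_window, randomized = randomized))
  charge <- suppressWarnings(
    charged_enrichment(tested, genes, eligible,
                       n_randomizations = n_randomizations,
                       tunnel_window = tunnel_window,
                       randomized = randomized))
  pos <- NULL
  if (positional && nrow(tested) && !is.null(randomized)) {
    pos <- flag_extreme_positions(tested, genes, randomized,
                                  level = alpha,
                                  tunnel_window = tunnel_window)
  }
  tai <- NULL
  if (!is.null(tgcn) && nrow(tested)) {
    w <- compute_tai(tgcn, domain = if (bundle$domain == "prokaryote")
      "prokaryote" else "eukaryote")
    occ <- psite_occupancy(tested, genes)
    tai <- c(tai_occupancy_correlation(occ, w),
             list(occupancy = occ, w = w))
  }
  manifest <- list(
    dataset_id = bundle$dataset_id, domain = bundle$domain,
    parameters = list(min_nonzero_fraction = min_nonzero_fraction,
                      exclude_first = exclude_first, k_sd = k_sd,
                      tunnel_window = tunnel_window, alpha = alpha,
                      n_randomizations = n_randomizations,
                      max_usr_coverage = max_usr_coverage,
                      ribo_only = ribo_only, sd_spacings = sd_spacings,
                      seed = seed),
    counts = list(genes_in = n_in, genes_after_filter = n_filtered,
                  genes_after_normalization = n_normalized,
                  peaks_called = nrow(peaks),
                  peaks_usr_incomplete = sum(!peaks$usr_complete),
                  peaks_sd_flagged = sum(peaks$sd_flagged),
                  genes_over_covered = length(over_covered),
                  peaks_tested = nrow(tested)))
  structure(list(bundle = bundle, peaks = peaks, peaks_tested = tested,
                 enrichment = enrichment, charge = charge,
                 positional = pos, tai = tai, manifest = manifest),
            class = "stalling_analysis")
}

#' @export
print.stalling_analysis <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("<stalling_analysis>", x$manifest$dataset_id, "\n",
      " genes:", cnt$genes_in, "->", cnt$genes_after_normalization,
      "after filters\n",
      " peaks:", cnt$peaks_called, "called,", cnt$peaks_tested,
      "tested\n")
  sig <- x$enrichment[x$enrichment$classification != "not_significant", ]
  if (nrow(sig)) {
    cat(" significant amino acids:",
        paste(sprintf("%s(%s, p=%.3g)", sig$amino_acid,
                      substr(sig$classification, 1, 4), sig$p_enriched),
              collapse = " "), "\n")
  } else cat(" significant amino acids: none\n")
  invisible(x)
}

#' Write analysis result tables to a directory
#'
#' Writes the enrichment classification table, the charge-class table, the
#' annotated peak table, the per-gene RD/mRNA profiles, the filter report,
#' optional positional matrices, and a JSON run manifest. Re-running with
#' the same inputs and seed reproduces the files byte for byte.
#'
#' @param res A [run_stalling_analysis()] result.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_analysis <- function(res, outdir) {
  stopifnot(inherits(res, "stalling_analysis"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(res$enrichment, "enrichment.tsv")
  wt(res$charge, "charge.tsv")
  wt(res$peaks, "peaks.tsv")
  wt(res$bundle$filter_report, "filter_report.tsv")
  prof <- do.call(rbind, lapply(names(res$bundle$rd), function(g) {
    v <- res$bundle$rd[[g]]
    data.frame(gene_id = g, codon_index = seq_along(v),
               rd_over_mrna = round(v, 6),
               mask = res$bundle$mask[[g]])
  }))
  if (!is.null(prof)) wt(prof, "rd_profiles.tsv")
  if (!is.null(res$positional)) {
    utils::write.table(res$positional$probs,
                       file.path(outdir, "positional_probs.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(res$positional$flags,
                       file.path(outdir, "positional_flags.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(res$manifest,
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(outdir)
}
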