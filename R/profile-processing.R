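# Codon-resolution conversion, coverage filtering, RD/mRNA normalization
# and multi-dataset aggregation.

#' Average a nucleotide profile into codon resolution
#'
#' The value at codon i is the mean of the read counts at its three
#' nucleotides. A trailing remainder of 1-2 nucleotides is dropped with a
#' warning.
#'
#' @param p Numeric per-nucleotide vector.
#' @return Numeric per-codon vector of length `floor(length(p) / 3)`.
#' @export
to_codon_resolution <- function(p) {
  if (!length(p)) stop("empty profile")
  n <- length(p) %/% 3L
  if (length(p) %% 3L != 0L) {
    warning("profile length not a multiple of 3; trailing ",
            length(p) %% 3L, " nt dropped")
    p <- p[seq_len(3L * n)]
  }
  colMeans(matrix(p, nrow = 3L))
}

#' Bundle paired ribo-seq and mRNA-seq codon profiles for one dataset
#'
#' @param ribo,mrna Named lists of per-codon numeric vectors covering the
#'   same genes with equal lengths.
#' @param dataset_id,organism Identifiers.
#' @param domain `"eukaryote"` or `"prokaryote"` (controls the
#'   Shine-Dalgarno peak filter downstream).
#' @return Object of class `dataset_bundle`: list with the profiles, a
#'   per-gene validity `mask` (all-`TRUE` until [filter_profiles()]), an
#'   `rd` slot (`NULL` until [normalize_rd_over_mrna()]) and a
#'   `filter_report` data frame.
#' @export
dataset_bundle <- function(ribo, mrna, dataset_id = "dataset",
                           organism = "organism",
                           domain = c("eukaryote", "prokaryote")) {
  domain <- match.arg(domain)
  if (!setequal(names(ribo), names(mrna)))
    stop("ribo and mrna must cover the same gene set")
  mrna <- mrna[names(ribo)]
  len_ok <- vapply(names(ribo),
                   function(g) length(ribo[[g]]) == length(mrna[[g]]),
                   logical(1))
  if (!all(len_ok))
    stop("ribo/mrna length mismatch for gene(s): ",
         paste(names(ribo)[!len_ok], collapse = ", "))
  mask <- lapply(ribo, function(v) rep(TRUE, length(v)))
  structure(list(dataset_id = dataset_id, organism = organism,
                 domain = domain, ribo = ribo, mrna = mrna, rd = NULL,
                 mask = mask,
                 filter_report = data.frame(gene_id = character(0),
                                            reason = character(0))),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("<dataset_bundle>", x$dataset_id, "(", x$organism, ",", x$domain, ")",
      length(x$ribo), "genes;",
      if (is.null(x$rd)) "raw" else "normalized", "\n")
  invisible(x)
}

#' Coverage-filter a dataset and mask the ramp region
#'
#' Ribosome density is systematically elevated (and biased) over the first
#' codons of a gene, so the first `exclude_first` codons are masked out of
#' every downstream statistic. Genes whose ribo-seq codon profile has fewer
#' than `min_nonzero_fraction` non-zero codons over the unmasked region are
#' removed (sparse coverage); optionally the mRNA profile must pass the same
#' bar.
#'
#' @param bundle A [dataset_bundle()].
#' @param min_nonzero_fraction Minimum fraction of non-zero codons
#'   (default 0.40).
#' @param exclude_first Number of leading codons to mask (default 20).
#' @param require_mrna Also apply the non-zero filter to the mRNA profile.
#' @return The filtered bundle; removed genes are listed in
#'   `$filter_report`.
#' @export
filter_profiles <- function(bundle, min_nonzero_fraction = 0.40,
                            exclude_first = 20L, require_mrna = FALSE) {
  stopifnot(inherits(bundle, "dataset_bundle"),
            min_nonzero_fraction >= 0, min_nonzero_fraction <= 1)
  nz_frac <- function(v) {
    idx <- seq_along(v) > exclude_first
    if (!any(idx)) return(0)
    mean(v[idx] > 0)
  }
  frac_r <- vapply(bundle$ribo, nz_frac, numeric(1))
  keep <- frac_r >= min_nonzero_fraction
  reason <- ifelse(keep, "", "sparse_ribo")
  if (require_mrna) {
    frac_m <- vapply(bundle$mrna, nz_frac, numeric(1))
    fail_m <- frac_m < min_nonzero_fraction
    reason[keep & fail_m] <- "sparse_mrna"
    keep <- keep & !fail_m
  }
  report <- data.frame(gene_id = names(bundle$ribo)[!keep],
                       reason = reason[!keep])
  bundle$ribo <- bundle$ribo[keep]
  bundle$mrna <- bundle$mrna[keep]
  bundle$mask <- lapply(bundle$ribo, function(v) {
    m <- rep(TRUE, length(v))
    m[seq_len(min(exclude_first, length(v)))] <- FALSE
    m
  })
  bundle$filter_report <- rbind(bundle$filter_report, report)
  bundle
}

#' Normalize to ribosomal density over mRNA (RD/mRNA)
#'
#' Each profile (ribo and mRNA) is first scaled by its own gene coverage --
#' the mean over unmasked codons (zeros included by default) -- and the
#' output per codon is `scaled_ribo / scaled_mrna`. Codons with zero mRNA
#' signal are masked invalid (never imputed); genes with an all-zero mRNA
#' profile over the unmasked region are dropped with a warning. In
#' `ribo_only` mode the mRNA normalization is skipped and the output is the
#' coverage-scaled ribo profile (control analysis for mRNA-independent
#' biases).
#'
#' @param bundle A filtered [dataset_bundle()].
#' @param mode `"rd_over_mrna"` (default) or `"ribo_only"`.
#' @param zero_excluded_mean Compute the per-profile scaling mean over
#'   non-zero unmasked codons instead of all unmasked codons.
#' @return The bundle with an `rd` slot (named list of per-codon vectors,
#'   `NA` at masked codons) and updated masks.
#' @export
normalize_rd_over_mrna <- function(bundle,
                                   mode = c("rd_over_mrna", "ribo_only"),
                                   zero_excluded_mean = FALSE) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  mode <- match.arg(mode)
  rd <- vector("list", length(bundle$ribo))
  names(rd) <- names(bundle$ribo)
  drop <- character(0)
  for (g in names(bundle$ribo)) {
    m <- bundle$mask[[g]]
    cov_of <- function(v) {
      sel <- if (zero_excluded_mean) m & v > 0 else m
      if (!any(sel)) 0 else mean(v[sel])
    }
    r <- bundle$ribo[[g]]
    cr <- cov_of(r)
    if (cr == 0) { drop <- c(drop, g); next }
    scaled_r <- r / cr
    if (mode == "ribo_only") {
      val <- scaled_r
    } else {
      q <- bundle$mrna[[g]]
      cm <- cov_of(q)
      if (cm == 0) { drop <- c(drop, g); next }
      scaled_m <- q / cm
      m <- m & scaled_m > 0
      val <- ifelse(scaled_m > 0, scaled_r / scaled_m, NA_real_)
    }
    val[!m] <- NA_real_
    bundle$mask[[g]] <- m
    rd[[g]] <- val
  }
  if (length(drop)) {
    warning(length(drop), " gene(s) dropped: no usable signal over ",
            "unmasked codons")
    bundle$ribo <- bundle$ribo[setdiff(names(bundle$ribo), drop)]
    bundle$mrna <- bundle$mrna[names(bundle$ribo)]
    bundle$mask <- bundle$mask[names(bundle$ribo)]
    rd <- rd[names(bundle$ribo)]
    bundle$filter_report <- rbind(
      bundle$filter_report,
      data.frame(gene_id = drop, reason = "zero_signal"))
  }
  bundle$rd <- rd
  bundle$mode <- mode
  bundle
}

#' Aggregate several datasets of one organism
#'
#' Two steps: (1) each dataset's profiles are divided by the dataset's total
#' read count (summed over all genes, per assay) to cancel depth
#' differences; (2) per gene, the depth-normalized profiles are averaged
#' across the datasets that contain the gene. The aggregate is a raw-stage
#' bundle; apply [filter_profiles()] and [normalize_rd_over_mrna()] to it as
#' to any dataset.
#'
#' @param bundles Non-empty list of raw [dataset_bundle()] objects from one
#'   organism.
#' @param dataset_id Identifier for the aggregate.
#' @return A [dataset_bundle()].
#' @export
aggregate_datasets <- function(bundles, dataset_id = "aggregate") {
  if (!length(bundles)) stop("empty bundle list")
  stopifnot(all(vapply(bundles, inherits, logical(1), "dataset_bundle")))
  norm <- lapply(bundles, function(b) {
    tr <- sum(unlist(b$ribo))
    tm <- sum(unlist(b$mrna))
    if (tr == 0 || tm == 0) stop("dataset ", b$dataset_id,
                                 " has zero total reads")
    list(ribo = lapply(b$ribo, `/`, tr), mrna = lapply(b$mrna, `/`, tm))
  })
  genes <- unique(unlist(lapply(norm, function(n) names(n$ribo))))
  avg <- function(assay) {
    out <- lapply(genes, function(g) {
      per <- lapply(norm, function(n) n[[assay]][[g]])
      per <- per[!vapply(per, is.null, logical(1))]
      Reduce(`+`, per) / length(per)
    })
    names(out) <- genes
    out
  }
  dataset_bundle(avg("ribo"), avg("mrna"), dataset_id = dataset_id,
                 organism = bundles[[1]]$organism,
                 domain = bundles[[1]]$domain)
}
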