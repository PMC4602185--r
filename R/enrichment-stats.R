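# Permutation enrichment tests: per-amino-acid and charged-class occurrence
# in USRs versus a null that redraws peak positions gene by gene, with
# empirical p-values and Benjamini-Hochberg FDR control.

#' Eligible codon positions for randomized peaks
#'
#' Positions from which null peaks may be drawn: unmasked codons far enough
#' into the gene for a complete upstream window (`index > tunnel_window`).
#' mRNA-invalid codons are excluded through the mask.
#'
#' @param bundle A normalized [dataset_bundle()].
#' @param tunnel_window USR length (codons).
#' @return Named list of integer position vectors, one per gene.
#' @export
eligible_positions <- function(bundle, tunnel_window = 31L) {
  lapply(bundle$mask, function(m) {
    idx <- which(m)
    idx[idx >= tunnel_window + 1L]
  })
}

#' Randomize peak positions gene by gene
#'
#' Draws `n_randomizations` null peak sets. Each draw samples, per gene and
#' without replacement, as many positions from that gene's eligible set as
#' the gene has real peaks, so every randomization preserves the per-gene
#' peak count exactly. Genes with more peaks than eligible positions are
#' skipped with a warning.
#'
#' @param peaks Peak data frame (only `gene_id` is used; one row per peak).
#' @param eligible Named list from [eligible_positions()].
#' @param n_randomizations Number of draws (default 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @return Object of class `randomized_peaks`: named list (per gene with
#'   peaks) of k x n_randomizations integer matrices of codon positions,
#'   with attribute `n_randomizations`.
#' @export
randomize_peaks <- function(peaks, eligible, n_randomizations = 1000L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- table(peaks$gene_id)
  out <- list()
  skipped <- character(0)
  for (g in names(counts)) {
    k <- as.integer(counts[[g]])
    e <- eligible[[g]]
    if (is.null(e) || length(e) < k) {
      skipped <- c(skipped, g)
      next
    }
    if (k == 1L) {
      m <- matrix(e[sample.int(length(e), n_randomizations, replace = TRUE)],
                  nrow = 1L)
    } else {
      m <- vapply(seq_len(n_randomizations),
                  function(r) e[sample.int(length(e), k)],
                  integer(k))
      if (is.null(dim(m))) m <- matrix(m, nrow = k)
    }
    out[[g]] <- m
  }
  if (length(skipped))
    warning(length(skipped), " gene(s) skipped: more peaks than eligible ",
            "positions")
  structure(out, n_randomizations = as.integer(n_randomizations),
            skipped = skipped, class = "randomized_peaks")
}

# L x 20 logical matrix: row i says, per amino acid, whether the acid occurs
# in the upstream window (i - w) .. (i - 1). Rows with incomplete windows
# are FALSE.
usr_presence_matrix <- function(gene, tunnel_window = 31L) {
  pidx <- protein_index(gene)
  n <- gene$n_codons
  pres <- matrix(FALSE, n, length(AA_ALPHABET),
                 dimnames = list(NULL, AA_ALPHABET))
  valid <- seq_len(n) >= tunnel_window + 1L
  if (!any(valid)) return(pres)
  for (a in seq_along(AA_ALPHABET)) {
    cs <- c(0L, cumsum(!is.na(pidx) & pidx == a))
    i <- which(valid)
    pres[i, a] <- (cs[i] - cs[i - tunnel_window]) > 0L
  }
  pres
}

#' Count peaks whose USR contains a target amino acid
#'
#' Each peak scores +1 if at least one member of `target` occurs anywhere in
#' its USR (for the charged-class tests the score is +1 as soon as any
#' member of the class appears, regardless of which other residues co-occur)
#' and 0 otherwise.
#'
#' @param usrs Character vector of complete USR strings.
#' @param target Character vector of single-letter amino-acid codes (a
#'   singleton for the per-amino-acid tests).
#' @return Integer count in `0 .. length(usrs)`.
#' @export
score_usrs <- function(usrs, target) {
  if (!length(usrs)) {
    warning("no USRs to score")
    return(0L)
  }
  pat <- paste0("[", paste(target, collapse = ""), "]")
  sum(grepl(pat, usrs, perl = TRUE))
}

#' Empirical permutation p-value
#'
#' `enriched`: fraction of null scores >= the observed score;
#' `depleted`: fraction of null scores <= the observed score. Ties count in
#' both directions and no pseudo-count is added, so a score above every null
#' value gives an enrichment p of exactly 0.
#'
#' @param observed Observed score.
#' @param null_scores Numeric vector of null scores.
#' @param direction `"enriched"` or `"depleted"`.
#' @return p-value in `[0, 1]`.
#' @export
empirical_p <- function(observed, null_scores,
                        direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  if (!length(null_scores)) stop("null_scores is empty")
  if (direction == "enriched") mean(null_scores >= observed)
  else mean(null_scores <= observed)
}

# n_randomizations x 20 matrix of null scores for all amino acids at once,
# using per-gene presence matrices and a rowsum over draw indices.
null_aa_scores <- function(randomized, genes, tunnel_window = 31L) {
  n_rand <- attr(randomized, "n_randomizations")
  total <- matrix(0L, n_rand, length(AA_ALPHABET),
                  dimnames = list(NULL, AA_ALPHABET))
  for (g in names(randomized)) {
    pres <- usr_presence_matrix(genes[[g]], tunnel_window)
    pos <- randomized[[g]]               # k x n_rand
    k <- nrow(pos)
    draw <- rep(seq_len(n_rand), each = k)
    contrib <- rowsum(pres[as.vector(pos), , drop = FALSE] + 0L, draw)
    total <- total + contrib
  }
  total
}

# Observed per-amino-acid scores from complete USR strings.
observed_aa_scores <- function(usrs) {
  chars <- strsplit(usrs, "")
  vapply(AA_ALPHABET,
         function(a) sum(vapply(chars, function(x) a %in% x, logical(1))),
         integer(1))
}

#' Classify the 20 amino acids by USR enrichment
#'
#' For each amino acid, the observed score (number of peaks whose USR
#' contains it) is compared with its distribution over randomized peak
#' placements. One shared set of null draws serves all 20 tests, making the
#' full table jointly reproducible under one seed. An amino acid is
#' `overrepresented` when the enrichment p-value is below `alpha`,
#' `underrepresented` when the depletion p-value is, and `not_significant`
#' otherwise. The 20 enrichment p-values are Benjamini-Hochberg adjusted
#' and FDR pass flags reported at the 0.05 and 0.10 levels.
#'
#' @param peaks Peak data frame with complete USRs (`usr`, `usr_complete`).
#' @param genes Named list of [coding_region()] objects.
#' @param eligible Named list from [eligible_positions()].
#' @param n_randomizations Number of null draws (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param tunnel_window USR length (codons).
#' @param seed Optional RNG seed.
#' @param randomized Optional precomputed [randomize_peaks()] result (shared
#'   with the charge and tunnel-position analyses).
#' @return Data frame, one row per amino acid: observed score, number of
#'   peaks, observed probability, null mean/SD, both one-sided p-values,
#'   BH-adjusted q, classification and FDR flags. The null score matrix and
#'   randomized draws are attached as attributes `null_scores` and
#'   `randomized`.
#' @export
classify_amino_acids <- function(peaks, genes, eligible,
                                 n_randomizations = 1000L, alpha = 0.05,
                                 tunnel_window = 31L, seed = NULL,
                                 randomized = NULL) {
  peaks <- peaks[peaks$usr_complete, , drop = FALSE]
  base <- data.frame(amino_acid = AA_ALPHABET, observed = NA_integer_,
                     n_peaks = nrow(peaks), observed_probability = NA_real_,
                     null_mean = NA_real_, null_sd = NA_real_,
                     p_enriched = NA_real_, p_depleted = NA_real_,
                     q_value = NA_real_,
                     classification = "not_significant",
                     fdr05 = FALSE, fdr10 = FALSE)
  if (nrow(peaks) < 1L) {
    warning("no complete-USR peaks; all amino acids not_significant")
    return(base)
  }
  if (is.null(randomized))
    randomized <- randomize_peaks(peaks, eligible, n_randomizations, seed)
  # drop peaks of genes skipped during randomization (peak count mismatch)
  peaks <- peaks[peaks$gene_id %in% names(randomized), , drop = FALSE]
  if (!nrow(peaks)) {
    warning("all peak-bearing genes skipped in randomization")
    return(base)
  }
  obs <- observed_aa_scores(peaks$usr)
  nulls <- null_aa_scores(randomized, genes, tunnel_window)
  p_enr <- vapply(seq_along(AA_ALPHABET),
                  function(a) empirical_p(obs[a], nulls[, a], "enriched"),
                  numeric(1))
  p_dep <- vapply(seq_along(AA_ALPHABET),
                  function(a) empirical_p(obs[a], nulls[, a], "depleted"),
                  numeric(1))
  q <- stats::p.adjust(p_enr, method = "BH")
  cls <- ifelse(p_enr < alpha, "overrepresented",
                ifelse(p_dep < alpha, "underrepresented", "not_significant"))
  out <- data.frame(amino_acid = AA_ALPHABET,
                    observed = as.integer(obs),
                    n_peaks = nrow(peaks),
                    observed_probability = obs / nrow(peaks),
                    null_mean = colMeans(nulls),
                    null_sd = apply(nulls, 2, stats::sd),
                    p_enriched = p_enr, p_depleted = p_dep, q_value = q,
                    classification = cls,
                    fdr05 = q <= 0.05, fdr10 = q <= 0.10,
                    row.names = NULL)
  attr(out, "null_scores") <- nulls
  attr(out, "randomized") <- randomized
  out
}

#' Charged-class USR enrichment
#'
#' Composite tests for the positively charged amino acids (K, R, H) and the
#' negatively charged ones (E, D): a peak scores +1 when any member of the
#' class occurs in its USR. Reported per class: observed score and
#' probability, null mean and SD over the randomizations, and both
#' one-sided empirical p-values (these are not FDR-corrected).
#'
#' @inheritParams classify_amino_acids
#' @param charge Subset of `c("positive", "negative")` (default both).
#' @return Data frame with one row per charge class.
#' @export
charged_enrichment <- function(peaks, genes, eligible,
                               charge = c("positive", "negative"),
                               n_randomizations = 1000L,
                               tunnel_window = 31L, seed = NULL,
                               randomized = NULL) {
  charge <- match.arg(charge, several.ok = TRUE)
  peaks <- peaks[peaks$usr_complete, , drop = FALSE]
  if (nrow(peaks) < 1L) {
    warning("no complete-USR peaks")
    return(data.frame(charge = charge, observed = 0L, n_peaks = 0L,
                      observed_probability = NA_real_,
                      null_mean = NA_real_, null_sd = NA_real_,
                      p_enriched = NA_real_, p_depleted = NA_real_))
  }
  if (is.null(randomized))
    randomized <- randomize_peaks(peaks, eligible, n_randomizations, seed)
  peaks <- peaks[peaks$gene_id %in% names(randomized), , drop = FALSE]
  n_rand <- attr(randomized, "n_randomizations")
  rows <- lapply(charge, function(ch) {
    members <- CHARGE_CLASSES[[ch]]
    obs <- score_usrs(peaks$usr, members)
    null <- numeric(n_rand)
    for (g in names(randomized)) {
      pres <- usr_presence_matrix(genes[[g]], tunnel_window)
      hit <- rowSums(pres[, members, drop = FALSE]) > 0
      pos <- randomized[[g]]
      k <- nrow(pos)
      null <- null + rowsum(hit[as.vector(pos)] + 0L,
                            rep(seq_len(n_rand), each = k))[, 1]
    }
    data.frame(charge = ch, observed = obs, n_peaks = nrow(peaks),
               observed_probability = obs / nrow(peaks),
               null_mean = mean(null), null_sd = stats::sd(null),
               p_enriched = empirical_p(obs, null, "enriched"),
               p_depleted = empirical_p(obs, null, "depleted"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
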