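# Position-specific amino-acid occupancy along the exit tunnel at stall
# events: 20 x 31 probability matrix, per-amino-acid standardization, and
# empirical flagging of extreme positions.

usr_char_matrix <- function(usrs) {
  t(vapply(strsplit(usrs, ""), identity,
           character(nchar(usrs[1]))))
}

#' Position-specific amino-acid occupancy probabilities
#'
#' Entry (a, j) is the probability that amino acid a occupies tunnel
#' position j across all complete USRs. Position j = 1 is the
#' P-site-proximal codon (immediately upstream of the peak) and j = 31 the
#' most distal; USR strings are written N- to C-terminal, so position j maps
#' to string character `tunnel_window + 1 - j`. Every USR has exactly one
#' amino acid per position, so each column sums to 1.
#'
#' @param usrs Character vector of complete USR strings (equal length).
#' @return 20 x `tunnel_window` numeric matrix (rows = amino acids, columns
#'   = tunnel positions 1..w).
#' @export
positional_probabilities <- function(usrs) {
  if (!length(usrs)) stop("no USRs")
  w <- nchar(usrs[1])
  chars <- usr_char_matrix(usrs)
  probs <- matrix(0, length(AA_ALPHABET), w,
                  dimnames = list(AA_ALPHABET, seq_len(w)))
  for (j in seq_len(w)) {
    tab <- table(factor(chars[, w + 1L - j], levels = AA_ALPHABET))
    probs[, j] <- as.numeric(tab) / length(usrs)
  }
  probs
}

#' Center positional probabilities per amino acid
#'
#' Subtracts each amino acid's mean probability across the tunnel, so rows
#' sum to zero and entries show where along the tunnel the amino acid is
#' over- or under-observed relative to its own average.
#'
#' @param m Matrix from [positional_probabilities()].
#' @return Row-centered matrix of the same shape.
#' @export
standardize_positional <- function(m) {
  m - rowMeans(m)
}

#' Flag tunnel positions with extreme occupancy
#'
#' Two readings of "extreme" are available. `mode = "null"` (default)
#' compares each entry of the observed probability matrix with the
#' distribution of the same entry over randomized peak placements (reusing
#' the enrichment null draws) and flags entries outside the central
#' `1 - level` band -- a two-sided empirical test at `level`.
#' `mode = "row_percentile"` instead compares each entry with the other 30
#' positions of its own row, flagging entries outside the row's empirical
#' `level/2` and `1 - level/2` quantiles; this needs no randomizations but
#' flags a fixed fraction of every row.
#'
#' @param peaks Peak data frame with complete USRs.
#' @param genes Named list of [coding_region()] objects.
#' @param randomized A [randomize_peaks()] result (required for
#'   `mode = "null"`).
#' @param level Two-sided significance level (default 0.05).
#' @param tunnel_window USR length (codons).
#' @param mode `"null"` or `"row_percentile"`.
#' @return List with matrices `probs`, `standardized` and character matrix
#'   `flags` (entries `"high"`, `"low"`, `"none"`).
#' @export
flag_extreme_positions <- function(peaks, genes, randomized = NULL,
                                   level = 0.05, tunnel_window = 31L,
                                   mode = c("null", "row_percentile")) {
  mode <- match.arg(mode)
  peaks <- peaks[peaks$usr_complete, , drop = FALSE]
  probs <- positional_probabilities(peaks$usr)
  flags <- matrix("none", nrow(probs), ncol(probs),
                  dimnames = dimnames(probs))
  if (mode == "row_percentile") {
    for (a in seq_len(nrow(probs))) {
      lo <- stats::quantile(probs[a, ], level / 2)
      hi <- stats::quantile(probs[a, ], 1 - level / 2)
      flags[a, probs[a, ] > hi] <- "high"
      flags[a, probs[a, ] < lo] <- "low"
    }
  } else {
    if (is.null(randomized)) stop("mode='null' needs randomized peaks")
    null_counts <- null_positional_counts(randomized, genes, tunnel_window)
    n_rand <- attr(randomized, "n_randomizations")
    n_null_peaks <- sum(vapply(randomized, nrow, integer(1)))
    for (a in seq_len(nrow(probs))) {
      for (j in seq_len(ncol(probs))) {
        null_p <- null_counts[, a, j] / n_null_peaks
        lo <- stats::quantile(null_p, level / 2, names = FALSE)
        hi <- stats::quantile(null_p, 1 - level / 2, names = FALSE)
        if (probs[a, j] > hi) flags[a, j] <- "high"
        else if (probs[a, j] < lo) flags[a, j] <- "low"
      }
    }
  }
  list(probs = probs, standardized = standardize_positional(probs),
       flags = flags)
}

# n_rand x 20 x w array of null occupancy counts: for each draw, how many
# random USRs carry amino acid a at tunnel position j. Indices over
# (draw, amino acid, position) are accumulated across genes and tabulated
# once.
null_positional_counts <- function(randomized, genes, tunnel_window = 31L) {
  n_rand <- attr(randomized, "n_randomizations")
  n_aa <- length(AA_ALPHABET)
  idx_parts <- vector("list", length(randomized))
  for (gi in seq_along(randomized)) {
    g <- names(randomized)[gi]
    pidx <- protein_index(genes[[g]])
    pos <- as.vector(randomized[[g]])          # k * n_rand positions
    k <- nrow(randomized[[g]])
    draw <- rep(rep(seq_len(n_rand), each = k), times = tunnel_window)
    j <- rep(seq_len(tunnel_window), each = k * n_rand)
    aa <- pidx[rep(pos, times = tunnel_window) - j]
    ok <- !is.na(aa)
    idx_parts[[gi]] <- (j[ok] - 1L) * n_aa * n_rand +
      (aa[ok] - 1L) * n_rand + draw[ok]
  }
  tab <- tabulate(unlist(idx_parts), nbins = n_rand * n_aa * tunnel_window)
  array(tab, c(n_rand, n_aa, tunnel_window))
}
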