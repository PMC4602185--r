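# Synthetic coding sequences and paired ribo-seq/mRNA-seq count profiles
# with planted stalling signals. The generator is the ground-truth source
# for parameter-recovery tests of the whole pipeline.

#' Configuration for the synthetic ribosome-profiling generator
#'
#' Defines the study conditions a simulated dataset emulates: gene number and
#' length, codon usage, per-gene mRNA abundance spread, count noise, and the
#' planted stalling signal. Count noise is negative-binomial for both assays
#' (overdispersion is the norm in ribo-seq); `mrna_noise_dispersion` is the
#' NB dispersion (variance = mu + dispersion * mu^2; 0 gives Poisson).
#' Per-gene mean mRNA coverage is drawn log-uniformly over `mrna_mean_range`
#' so that simulated datasets span the coverage spectrum the 40% non-zero
#' filter acts on.
#'
#' The planted signal: every codon whose upstream window of `tunnel_window`
#' codons (the exit-tunnel occupancy region) contains at least one amino acid
#' from `stalling_amino_acids` gets dwell time `base_dwell * stall_multiplier`
#' instead of `base_dwell` (`stall_mode = "window"`). The alternative
#' `stall_mode = "adjacent"` elevates only the codon immediately downstream
#' of a trigger occurrence, i.e. the trigger sits at the P-site-proximal
#' tunnel position of the stall; this models position-specific pausing and
#' gives the tunnel-position analysis a localized signal to recover.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Min/max gene length in sense codons (start codon
#'   included, terminal stop excluded); lengths are drawn uniformly.
#' @param codon_usage Named probability vector over the 61 sense codons used
#'   for internal codons; default uniform. Zero mass on every codon of some
#'   amino acid is allowed (that amino acid then never occurs).
#' @param mrna_mean_range Min/max per-gene mean mRNA-seq coverage in reads
#'   per nucleotide (log-uniform draw).
#' @param mrna_noise_dispersion Negative-binomial dispersion for both assays.
#' @param base_dwell Baseline relative dwell time per codon.
#' @param stalling_amino_acids Character vector of single-letter codes that
#'   trigger stalling (empty = null model).
#' @param stall_multiplier Dwell-time multiplier (>= 1) at stalled codons.
#' @param tunnel_window Length of the upstream trigger window in codons.
#' @param reads_per_gene_scale Sequencing-depth factor for the ribo-seq
#'   assay; expected ribo reads scale linearly in it.
#' @param stall_mode `"window"` (default) or `"adjacent"`, see Details.
#' @param seed Integer RNG seed; all draws are reproducible under it.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_genes = 200L,
                             gene_length_range = c(300L, 300L),
                             codon_usage = NULL,
                             mrna_mean_range = c(0.1, 10),
                             mrna_noise_dispersion = 0.05,
                             base_dwell = 1,
                             stalling_amino_acids = character(0),
                             stall_multiplier = 1,
                             tunnel_window = 31L,
                             reads_per_gene_scale = 1,
                             stall_mode = c("window", "adjacent"),
                             seed = 1L) {
  stall_mode <- match.arg(stall_mode)
  sense <- sense_codons()
  if (is.null(codon_usage)) {
    codon_usage <- stats::setNames(rep(1 / length(sense), length(sense)),
                                   sense)
  }
  if (!all(names(codon_usage) %in% sense) ||
      length(codon_usage) != length(sense))
    stop("codon_usage must be a named vector over the 61 sense codons")
  codon_usage <- codon_usage[sense]
  if (any(codon_usage < 0) || abs(sum(codon_usage) - 1) > 1e-8)
    stop("codon_usage must be non-negative and sum to 1")
  if (length(gene_length_range) != 2L || any(gene_length_range < 40L))
    stop("gene_length_range must be two codon counts >= 40")
  if (stall_multiplier < 1) stop("stall_multiplier must be >= 1")
  bad_aa <- setdiff(stalling_amino_acids, AA_ALPHABET)
  if (length(bad_aa)) stop("unknown amino acid(s): ",
                           paste(bad_aa, collapse = ", "))
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              codon_usage = codon_usage,
              mrna_mean_range = as.numeric(mrna_mean_range),
              mrna_noise_dispersion = as.numeric(mrna_noise_dispersion),
              base_dwell = as.numeric(base_dwell),
              stalling_amino_acids = as.character(stalling_amino_acids),
              stall_multiplier = as.numeric(stall_multiplier),
              tunnel_window = as.integer(tunnel_window),
              reads_per_gene_scale = as.numeric(reads_per_gene_scale),
              stall_mode = stall_mode,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# Deterministic per-gene substream seed so results do not depend on the
# order in which genes are simulated.
gene_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 1009) %% 2147483629)
}

rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate synthetic coding sequences
#'
#' Each gene starts with ATG, has internal codons drawn i.i.d. from
#' `config$codon_usage`, and ends with a single stop codon (TAA). Lengths
#' (in sense codons) are drawn uniformly over `gene_length_range`, so the
#' nucleotide length is `3 * (length + 1)` including the stop.
#'
#' @param config A [synthetic_config()].
#' @return Named list of [coding_region()] objects (`gene_1`, `gene_2`, ...).
#' @export
generate_cds <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  lens <- if (config$gene_length_range[1] == config$gene_length_range[2])
    rep(config$gene_length_range[1], config$n_genes)
  else
    sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
           config$n_genes, replace = TRUE)
  sense <- names(config$codon_usage)
  genes <- lapply(seq_len(config$n_genes), function(i) {
    internal <- sample(sense, lens[i] - 1L, replace = TRUE,
                       prob = config$codon_usage)
    coding_region(paste0("gene_", i),
                  paste(c("ATG", internal, "TAA"), collapse = ""))
  })
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  genes
}

# Relative dwell time per codon under the planted stalling model.
codon_dwell_times <- function(gene, config) {
  n <- gene$n_codons
  dwell <- rep(config$base_dwell, n)
  if (!length(config$stalling_amino_acids) || config$stall_multiplier == 1)
    return(dwell)
  aa <- translate_codons(gene$codons)
  trig <- as.integer(aa %in% config$stalling_amino_acids)
  if (config$stall_mode == "adjacent") {
    hit <- which(trig == 1L) + 1L
    hit <- hit[hit <= n]
  } else {
    w <- config$tunnel_window
    csum <- c(0L, cumsum(trig))
    i <- seq_len(n)
    lo <- pmax(i - w, 1L)
    hit <- i[csum[i] - csum[lo] > 0L]  # any trigger in codons (i-w)..(i-1)
  }
  dwell[hit] <- config$base_dwell * config$stall_multiplier
  dwell
}

#' Simulate paired ribo-seq and mRNA-seq nucleotide profiles
#'
#' For each gene, a mean mRNA coverage `m` (reads/nt) is drawn log-uniformly
#' over `mrna_mean_range`; mRNA counts per nucleotide are NB(mu = m). Ribo
#' counts are drawn per codon with mean
#' `reads_per_gene_scale * 3 * m * dwell` (dwell from the planted stalling
#' model) and the codon's reads are then split multinomially over its three
#' nucleotides, so profiles are count-valued at nucleotide resolution.
#'
#' @param genes Named list of [coding_region()] objects.
#' @param config The [synthetic_config()] used to generate them.
#' @return List with named-list elements `ribo` and `mrna` (integer vectors,
#'   one value per CDS nucleotide) and `gene_means` (numeric).
#' @export
simulate_profiles <- function(genes, config) {
  stopifnot(inherits(config, "synthetic_config"), length(genes) > 0)
  ribo <- vector("list", length(genes))
  mrna <- vector("list", length(genes))
  gene_means <- numeric(length(genes))
  lr <- log(config$mrna_mean_range)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    set.seed(gene_seed(config$seed, i))
    m <- exp(stats::runif(1, lr[1], lr[2]))
    gene_means[i] <- m
    n_nt <- 3L * g$n_codons
    mrna[[i]] <- rnbinom_disp(n_nt, m, config$mrna_noise_dispersion)
    dwell <- codon_dwell_times(g, config)
    mu_codon <- config$reads_per_gene_scale * 3 * m * dwell
    counts <- rnbinom_disp(g$n_codons, mu_codon, config$mrna_noise_dispersion)
    # multinomial split of each codon's reads over its 3 nucleotides
    n1 <- stats::rbinom(g$n_codons, counts, 1 / 3)
    n2 <- stats::rbinom(g$n_codons, counts - n1, 1 / 2)
    ribo[[i]] <- as.integer(rbind(n1, n2, counts - n1 - n2))
  }
  names(ribo) <- names(mrna) <- names(gene_means) <- names(genes)
  list(ribo = ribo, mrna = mrna, gene_means = gene_means)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_cds()] + [simulate_profiles()] +
#' [ground_truth()].
#'
#' @param config A [synthetic_config()].
#' @return Object of class `stalling_simulation`: list with `genes`, `ribo`,
#'   `mrna` (nucleotide-resolution named lists), `gene_means`, `truth` and
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  genes <- generate_cds(config)
  prof <- simulate_profiles(genes, config)
  structure(list(genes = genes, ribo = prof$ribo, mrna = prof$mrna,
                 gene_means = prof$gene_means,
                 truth = ground_truth(config), config = config),
            class = "stalling_simulation")
}

#' @export
print.stalling_simulation <- function(x, ...) {
  cat("<stalling_simulation>", length(x$genes), "genes; planted:",
      if (length(x$truth$stalling_amino_acids))
        paste(x$truth$stalling_amino_acids, collapse = ",") else "none",
      "(x", x$truth$stall_multiplier, ")\n")
  invisible(x)
}

#' Planted ground truth of a synthetic configuration
#'
#' @param config A [synthetic_config()] or [simulate_dataset()] result.
#' @return List with `stalling_amino_acids`, `stall_multiplier`,
#'   `tunnel_window` and `stall_mode`.
#' @export
ground_truth <- function(config) {
  if (inherits(config, "stalling_simulation")) config <- config$config
  stopifnot(inherits(config, "synthetic_config"))
  list(stalling_amino_acids = config$stalling_amino_acids,
       stall_multiplier = config$stall_multiplier,
       tunnel_window = config$tunnel_window,
       stall_mode = config$stall_mode)
}

#' Planted stalling-scenario configuration
#'
#' Builds a recovery-scenario configuration in which the trigger amino acids
#' are rare (total codon-usage mass `trigger_usage` per trigger amino acid,
#' remaining mass uniform over the other codons) so that stalls are sparse
#' events, as extreme pausing is in real data. Sparsity is forced by the
#' peak-calling arithmetic: a block of codons at multiplier M only exceeds
#' the gene mean by 4 SD if the elevated fraction f of the gene satisfies
#' f + 4*sqrt(f(1-f)) < 1 (f below ~6%); one trigger elevates a full
#' 31-codon window, hence long genes and rare triggers.
#'
#' @param stalling_amino_acids Trigger set, e.g. `"P"` or `c("K", "R")`.
#' @param seed RNG seed.
#' @param n_genes,gene_length Scenario size (codons per gene).
#' @param stall_multiplier Dwell multiplier at stalled codons.
#' @param trigger_usage Total codon-usage probability per trigger amino acid.
#' @param stall_mode Passed to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
stalling_scenario <- function(stalling_amino_acids, seed = 1L,
                              n_genes = 200L, gene_length = 600L,
                              stall_multiplier = 50,
                              trigger_usage = 0.001,
                              stall_mode = "window") {
  sense <- sense_codons()
  aa <- translate_codons(sense)
  usage <- stats::setNames(numeric(length(sense)), sense)
  trig <- aa %in% stalling_amino_acids
  if (!any(trig)) stop("no sense codons encode the trigger set")
  total_trig <- trigger_usage * length(stalling_amino_acids)
  for (a in stalling_amino_acids) {
    idx <- aa == a
    usage[idx] <- trigger_usage / sum(idx)
  }
  usage[!trig] <- (1 - total_trig) / sum(!trig)
  synthetic_config(n_genes = n_genes,
                   gene_length_range = c(gene_length, gene_length),
                   codon_usage = usage,
                   mrna_mean_range = c(2, 20),
                   stalling_amino_acids = stalling_amino_acids,
                   stall_multiplier = stall_multiplier,
                   stall_mode = stall_mode,
                   seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Writes the CDS FASTA, one fixed-step wiggle file per assay (one track per
#' gene, 1-based positions along the CDS) and a tab-separated ground-truth
#' file (gene, planted stalling set, multiplier, per-gene trigger codon
#' positions).
#'
#' @param sim A [simulate_dataset()] result.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "stalling_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_cds_fasta(sim$genes, file.path(outdir, "cds.fasta"))
  write_wiggle_tracks(sim$ribo, file.path(outdir, "ribo.wig"), name = "ribo")
  write_wiggle_tracks(sim$mrna, file.path(outdir, "mrna.wig"), name = "mrna")
  trig <- vapply(sim$genes, function(g) {
    pos <- which(translate_codons(g$codons) %in%
                 sim$truth$stalling_amino_acids)
    paste(pos, collapse = ",")
  }, "")
  utils::write.table(
    data.frame(gene_id = names(sim$genes),
               trigger_codons = trig,
               stalling_amino_acids =
                 paste(sim$truth$stalling_amino_acids, collapse = ","),
               stall_multiplier = sim$truth$stall_multiplier),
    file.path(outdir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
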