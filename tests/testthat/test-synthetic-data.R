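# Synthetic generator: sequence validity, codon usage convergence, planted
# dwell signal, depth scaling and reproducibility.

test_that("generated CDSs have the requested structure", {
  cfg <- synthetic_config(n_genes = 5, gene_length_range = c(100, 100),
                          seed = 7)
  genes <- generate_cds(cfg)
  expect_length(genes, 5)
  for (g in genes) {
    expect_equal(nchar(g$sequence), 303)  # 100 sense codons + stop
    expect_equal(g$codons[1], "ATG")
    expect_true(g$codons[g$n_codons] %in% c("TAA", "TAG", "TGA"))
    # coding_region() itself rejects internal stops, so construction
    # succeeding implies none are present
    expect_length(g$protein, 100)
  }
})

test_that("degenerate codon usage makes every internal codon that codon", {
  usage <- setNames(numeric(61), stallscan:::sense_codons())
  usage["AAA"] <- 1
  cfg <- synthetic_config(n_genes = 3, gene_length_range = c(50, 50),
                          codon_usage = usage, seed = 1)
  genes <- generate_cds(cfg)
  for (g in genes)
    expect_true(all(g$codons[2:50] == "AAA"))
})

test_that("empirical codon frequencies converge to uniform usage", {
  cfg <- synthetic_config(n_genes = 200, gene_length_range = c(100, 100),
                          seed = 42)
  genes <- generate_cds(cfg)
  internal <- unlist(lapply(genes, function(g) g$codons[2:100]))
  n <- length(internal)
  p <- 1 / 61
  se <- sqrt(p * (1 - p) / n)
  freq <- table(factor(internal, levels = stallscan:::sense_codons())) / n
  expect_true(all(abs(freq - p) <= 3.5 * se))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(stall_multiplier = 0.5), "stall_multiplier")
  expect_error(synthetic_config(stalling_amino_acids = "B"), "amino acid")
  usage <- setNames(rep(1 / 61, 61), stallscan:::sense_codons())
  expect_error(synthetic_config(codon_usage = usage * 2), "sum to 1")
})

test_that("planted stall elevates ribo density downstream of the trigger", {
  # one W at codon 40, no other trigger; window model elevates 41..71
  protein <- paste(c(rep("A", 39), "W", rep("A", 160)), collapse = "")
  gene <- gene_from_protein("g1", protein)
  cfg <- synthetic_config(n_genes = 1, gene_length_range = c(200, 200),
                          stalling_amino_acids = "W", stall_multiplier = 50,
                          mrna_mean_range = c(5, 5), seed = 3)
  dwell <- stallscan:::codon_dwell_times(gene, cfg)
  expect_equal(which(dwell > 1), 41:71)
  prof <- simulate_profiles(list(g1 = gene), cfg)
  codon_ribo <- to_codon_resolution(prof$ribo$g1)
  expect_gt(mean(codon_ribo[41:71]), 5 * mean(codon_ribo[-(41:71)]))
})

test_that("adjacent stall mode elevates only the trigger-adjacent codon", {
  protein <- paste(c(rep("A", 39), "W", rep("A", 160)), collapse = "")
  gene <- gene_from_protein("g1", protein)
  cfg <- synthetic_config(n_genes = 1, gene_length_range = c(200, 200),
                          stalling_amino_acids = "W", stall_multiplier = 50,
                          stall_mode = "adjacent", seed = 3)
  dwell <- stallscan:::codon_dwell_times(gene, cfg)
  expect_equal(which(dwell > 1), 41L)
})

test_that("no planted signal means flat dwell times", {
  gene <- gene_from_protein("g1", paste(rep("KW", 50), collapse = ""))
  cfg <- synthetic_config(n_genes = 1, gene_length_range = c(100, 100),
                          seed = 1)
  expect_true(all(stallscan:::codon_dwell_times(gene, cfg) == 1))
})

test_that("simulation is reproducible under a seed and total reads scale", {
  cfg <- synthetic_config(n_genes = 20, gene_length_range = c(100, 100),
                          mrna_mean_range = c(1, 5), seed = 9)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$ribo, s2$ribo)
  expect_identical(s1$mrna, s2$mrna)

  cfg5 <- synthetic_config(n_genes = 20, gene_length_range = c(100, 100),
                           mrna_mean_range = c(1, 5),
                           reads_per_gene_scale = 5, seed = 9)
  s5 <- simulate_dataset(cfg5)
  ratio <- sum(unlist(s5$ribo)) / sum(unlist(s1$ribo))
  expect_gt(ratio, 4.5)
  expect_lt(ratio, 5.5)
})

test_that("ground truth round-trips through the configuration", {
  cfg <- synthetic_config(stalling_amino_acids = c("K", "R"),
                          stall_multiplier = 30, seed = 2)
  expect_equal(ground_truth(cfg)$stalling_amino_acids, c("K", "R"))
  expect_equal(ground_truth(synthetic_config())$stalling_amino_acids,
               character(0))
  # rebuild the config from its plain-list form
  plain <- unclass(cfg)
  cfg2 <- do.call(synthetic_config, plain)
  expect_identical(ground_truth(cfg2), ground_truth(cfg))
})

test_that("simulation files round-trip through FASTA and wiggle", {
  cfg <- synthetic_config(n_genes = 4, gene_length_range = c(60, 60),
                          mrna_mean_range = c(2, 4), seed = 5)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  genes <- read_cds_fasta(file.path(dir, "cds.fasta"))
  expect_equal(vapply(genes, `[[`, "", "sequence"),
               vapply(sim$genes, `[[`, "", "sequence"))
  lens <- vapply(sim$ribo, length, integer(1))
  ribo <- read_wiggle_tracks(file.path(dir, "ribo.wig"), lens)
  expect_equal(lapply(ribo, as.numeric), lapply(sim$ribo, as.numeric))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 4)
})
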