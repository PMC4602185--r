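# Permutation enrichment machinery: scoring, null generation, empirical
# p-values, the BH correction and classification.

test_that("USR scoring counts peaks containing the target at least once", {
  usrs <- c(strrep("K", 31), paste0(strrep("A", 30), "K"), strrep("K", 31))
  expect_equal(score_usrs(usrs, "K"), 3L)
  expect_equal(score_usrs(strrep("A", 31), c("K", "R", "H")), 0L)
  # a USR with both charges scores +1 for the negative test too
  mixed <- paste0(strrep("A", 29), "KD")
  expect_equal(score_usrs(mixed, c("E", "D")), 1L)
  expect_equal(score_usrs(mixed, c("K", "R", "H")), 1L)
  expect_warning(expect_equal(score_usrs(character(0), "K"), 0L), "no USRs")
})

test_that("empirical p-values follow the counting formula", {
  null <- c(rep(60, 37), rep(10, 963))
  expect_equal(empirical_p(50, null, "enriched"), 0.037)
  expect_equal(empirical_p(100, null, "enriched"), 0)
  expect_equal(empirical_p(100, null, "depleted"), 1)
  expect_equal(empirical_p(5, null, "enriched"), 1)
  expect_equal(empirical_p(5, null, "depleted"), 0)
  # ECDF identity on integer scores
  set.seed(6)
  ns <- rpois(500, 20)
  obs <- 23
  expect_equal(empirical_p(obs, ns, "enriched"), 1 - ecdf(ns)(obs - 1))
  # ties count in both directions
  expect_gte(empirical_p(20, ns, "enriched") +
             empirical_p(20, ns, "depleted"), 1)
})

test_that("randomized draws preserve per-gene peak counts exactly", {
  eligible <- list(a = 32:45, b = 32:40)
  peaks <- data.frame(gene_id = c("a", "a", "b"), codon_index = c(33, 40, 35))
  r <- randomize_peaks(peaks, eligible, n_randomizations = 50, seed = 1)
  expect_equal(nrow(r$a), 2L)
  expect_equal(nrow(r$b), 1L)
  expect_true(all(r$a %in% eligible$a))
  expect_true(all(apply(r$a, 2, anyDuplicated) == 0))  # without replacement
  # saturated draw: as many peaks as eligible positions
  sat <- randomize_peaks(data.frame(gene_id = c("c", "c"), codon_index = 1:2),
                         list(c = c(40L, 41L)), 10, seed = 2)
  expect_true(all(apply(sat$c, 2, sort) == c(40L, 41L)))
  # more peaks than eligible positions: gene skipped with warning
  expect_warning(
    sk <- randomize_peaks(data.frame(gene_id = rep("d", 3)),
                          list(d = c(40L, 41L)), 5),
    "skipped")
  expect_null(sk$d)
  # reproducible under seed
  r2 <- randomize_peaks(peaks, eligible, n_randomizations = 50, seed = 1)
  expect_identical(r, r2)
})

test_that("empirical p converges to the exhaustive-enumeration oracle", {
  set.seed(21)
  cfg <- synthetic_config(n_genes = 2, gene_length_range = c(45, 45),
                          seed = 33)
  genes <- generate_cds(cfg)
  eligible <- list(gene_1 = 32:37, gene_2 = 32:37)
  peaks <- data.frame(gene_id = c("gene_1", "gene_2", "gene_2"),
                      codon_index = c(34L, 33L, 36L), value = 1)
  peaks <- extract_usr(peaks, genes)
  target <- "L"
  obs <- score_usrs(peaks$usr, target)
  exact_null <- enumerate_null_scores(
    genes, eligible, c(gene_1 = 1L, gene_2 = 2L), target)
  p_exact <- mean(exact_null >= obs)
  r <- randomize_peaks(peaks, eligible, n_randomizations = 1000, seed = 5)
  nulls <- stallscan:::null_aa_scores(r, genes)
  p_emp <- empirical_p(obs, nulls[, target], "enriched")
  mc_se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(p_emp - p_exact), 3 * mc_se + 1e-12)
})

test_that("classification recovers a planted stalling amino acid", {
  cfg <- stalling_scenario("P", seed = 19, n_genes = 60)
  sim <- simulate_dataset(cfg)
  res <- run_stalling_analysis(sim, n_randomizations = 300, seed = 19)
  e <- res$enrichment
  row <- e[e$amino_acid == "P", ]
  expect_equal(row$classification, "overrepresented")
  expect_lt(row$p_enriched, 0.05)
  expect_true(row$fdr05)
  # q-values match a textbook BH step-up computed by hand
  p <- e$p_enriched
  n <- length(p)
  o <- order(p)
  stepped <- rev(cummin(rev(p[o] * n / seq_len(n))))
  manual_q <- numeric(n)
  manual_q[o] <- pmin(stepped, 1)
  expect_equal(e$q_value, manual_q)
  # invariants of the result table
  expect_true(all(e$observed <= e$n_peaks))
  expect_true(all(e$p_enriched + e$p_depleted >= 1))
  expect_equal(e$observed_probability, e$observed / e$n_peaks)
})

test_that("charged-class tests report the statistics of their score", {
  cfg <- stalling_scenario(c("K", "R"), seed = 23, n_genes = 60)
  sim <- simulate_dataset(cfg)
  res <- run_stalling_analysis(sim, n_randomizations = 300, seed = 23)
  ch <- res$charge
  pos <- ch[ch$charge == "positive", ]
  expect_lt(pos$p_enriched, 0.05)
  expect_equal(pos$observed_probability, pos$observed / pos$n_peaks)
  expect_true(all(c("null_mean", "null_sd") %in% names(ch)))
})

test_that("classification is deterministic under a seed and order-invariant", {
  cfg <- synthetic_config(n_genes = 40, gene_length_range = c(200, 200),
                          mrna_mean_range = c(2, 10), seed = 31)
  sim <- simulate_dataset(cfg)
  r1 <- run_stalling_analysis(sim, n_randomizations = 200, seed = 7)
  r2 <- run_stalling_analysis(sim, n_randomizations = 200, seed = 7)
  expect_identical(r1$enrichment, r2$enrichment)
  expect_identical(r1$charge, r2$charge)
})

test_that("no peaks gives an all-not-significant table with warning", {
  genes <- list(g = gene_from_protein("g", strrep("A", 60)))
  empty <- data.frame(gene_id = character(0), codon_index = integer(0),
                      usr = character(0), usr_complete = logical(0))
  expect_warning(
    out <- classify_amino_acids(empty, genes, list(g = 32:50),
                                n_randomizations = 10),
    "no complete-USR peaks")
  expect_true(all(out$classification == "not_significant"))
})
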