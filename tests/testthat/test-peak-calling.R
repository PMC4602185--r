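# Peak detection (mean + 4 SD over positive unmasked codons), USR
# extraction, USR coverage bookkeeping and the Shine-Dalgarno filter.

test_that("constant profiles yield no peaks", {
  p <- call_peaks(rep(2, 50))
  expect_equal(nrow(p), 0)
})

test_that("a single extreme codon is the unique peak (hand oracle)", {
  x <- c(rep(NA, 20), rep(1, 100), 50)
  mask <- c(rep(FALSE, 20), rep(TRUE, 101))
  vals <- c(rep(1, 100), 50)
  mu <- mean(vals); sigma <- sd(vals)
  expect_gt(50, mu + 4 * sigma)       # 50 clears the threshold
  expect_lt(1, mu + 4 * sigma)        # baseline does not
  p <- call_peaks(x, mask = mask)
  expect_equal(p$codon_index, 121L)
  expect_equal(p$value, 50)
})

test_that("degenerate profiles warn and return no peaks", {
  expect_warning(p <- call_peaks(c(0, 0, 5, 0)), "fewer than 2")
  expect_equal(nrow(p), 0)
})

test_that("lowering the SD threshold never removes a peak", {
  set.seed(8)
  x <- rexp(200) + c(rep(0, 190), rep(20, 10))
  p4 <- call_peaks(x, k_sd = 4)$codon_index
  p3 <- call_peaks(x, k_sd = 3)$codon_index
  expect_true(all(p4 %in% p3))
})

test_that("masked codons are excluded from both statistics and peaks", {
  x <- c(rep(1, 40), 100, rep(1, 20))
  mask <- rep(TRUE, 61); mask[41] <- FALSE
  p <- call_peaks(x, mask = mask)
  expect_false(41 %in% p$codon_index)
})

test_that("USRs are the translated 31 codons upstream of the peak", {
  gene <- gene_from_protein("g", strrep("K", 80))
  peaks <- data.frame(gene_id = "g", codon_index = 40L, value = 10)
  out <- extract_usr(peaks, list(g = gene))
  expect_equal(out$usr, strrep("K", 31))
  expect_true(out$usr_complete)
})

test_that("peaks closer than the tunnel window to the start are incomplete", {
  gene <- gene_from_protein("g", strrep("A", 80))
  peaks <- data.frame(gene_id = "g", codon_index = c(26L, 32L), value = 10)
  out <- extract_usr(peaks, list(g = gene))
  expect_equal(out$usr_complete, c(FALSE, TRUE))
  expect_true(is.na(out$usr[1]))
})

test_that("USR equals the protein slice for random genes", {
  set.seed(11)
  cfg <- synthetic_config(n_genes = 5, gene_length_range = c(90, 90),
                          seed = 12)
  genes <- generate_cds(cfg)
  for (g in names(genes)) {
    i <- sample(32:85, 1)
    out <- extract_usr(data.frame(gene_id = g, codon_index = i, value = 1),
                       genes)
    expect_equal(out$usr,
                 paste(genes[[g]]$protein[(i - 31):(i - 1)], collapse = ""))
  }
  expect_error(
    extract_usr(data.frame(gene_id = "gene_1", codon_index = 99L, value = 1),
                genes),
    "beyond")
})

test_that("USR coverage is the union fraction of the protein", {
  gene <- gene_from_protein("g", strrep("A", 310))
  one <- usr_coverage(data.frame(gene_id = "g", codon_index = 100L),
                      list(g = gene))
  expect_equal(one$coverage, 31 / 310)
  expect_false(one$flagged)
  # overlapping USRs are not double counted
  two <- usr_coverage(data.frame(gene_id = "g", codon_index = c(100L, 110L)),
                      list(g = gene))
  expect_equal(two$coverage, 41 / 310)
  none <- usr_coverage(data.frame(gene_id = character(0),
                                  codon_index = integer(0)),
                       list(g = gene))
  expect_equal(none$coverage, 0)
})

test_that("SD-like hexamers upstream of the A-site exclude peaks", {
  peaks <- data.frame(gene_id = "g", codon_index = 30L, value = 10)
  for (case in list(c("GGAGGT", TRUE),   # canonical, 0 mismatches
                    c("GGAGGA", TRUE),   # 1 substitution
                    c("GGAAAT", FALSE))) # 2 substitutions: retained
  {
    g <- sd_gene(case[1])
    out <- filter_sd_peaks(peaks, list(g = g))
    expect_equal(out$sd_flagged, as.logical(case[2]), label = case[1])
    expect_equal(out$codon_index, 30L)  # membership only, never position
  }
})

test_that("SD spacing set is honored and start-of-CDS windows skipped", {
  peaks <- data.frame(gene_id = "g", codon_index = 30L, value = 10)
  g10 <- sd_gene("GGAGGT", spacing = 10L)
  expect_true(filter_sd_peaks(peaks, list(g = g10))$sd_flagged)
  strict <- filter_sd_peaks(peaks, list(g = g10),
                            spacings = c(8L, 9L, 11L))
  expect_false(strict$sd_flagged)
  # peak too close to the start: all windows precede the CDS
  early <- data.frame(gene_id = "g", codon_index = 2L, value = 10)
  expect_false(filter_sd_peaks(early, list(g = sd_gene("GGAGGT")))$sd_flagged)
})

test_that("bundle peak calling annotates gene ids and sorts by position", {
  set.seed(3)
  ribo <- list(a = c(rep(1, 60), 80, rep(1, 19)),
               b = rep(1, 80))
  b <- toy_bundle(ribo)
  b <- normalize_rd_over_mrna(filter_profiles(b, exclude_first = 10))
  p <- call_peaks(b)
  expect_equal(p$gene_id, "a")
  expect_equal(p$codon_index, 61L)
  # every returned peak satisfies the rule recomputed independently
  vals <- b$rd$a[b$mask$a & b$rd$a > 0 & !is.na(b$rd$a)]
  expect_true(all(p$value > mean(vals) + 4 * sd(vals)))
})
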