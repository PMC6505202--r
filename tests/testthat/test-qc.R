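make_panel <- function(dos, chrom = NULL, pos = NULL) {
  m <- ncol(dos)
  genotype_panel(sprintf("s%02d", seq_len(nrow(dos))),
                 data.frame(snp_id = sprintf("m%03d", seq_len(m)),
                            chromosome = if (is.null(chrom)) rep("1", m) else chrom,
                            position = if (is.null(pos)) seq_len(m) * 10L else pos,
                            allele_a = "A", allele_b = "G",
                            stringsAsFactors = FALSE),
                 dos)
}

test_that("positional duplicates are removed entirely, including triples", {
  p <- make_panel(matrix(0L, 2, 3), pos = c(100L, 100L, 200L))
  r <- remove_duplicate_snps(p)
  expect_equal(n_snps(r$panel), 1)
  expect_equal(r$panel$snps$position, 200L)
  expect_equal(length(r$removed_ids), 2)

  p3 <- make_panel(matrix(0L, 2, 4), pos = c(50L, 50L, 50L, 60L))
  r3 <- remove_duplicate_snps(p3)
  expect_equal(n_snps(r3$panel), 1)
  expect_equal(length(r3$removed_ids), 3)

  clean <- make_panel(matrix(0L, 2, 3))
  expect_equal(remove_duplicate_snps(clean)$panel$snps, clean$snps)
})

test_that("chromosome filter keeps only the requested labels and rejects empty sets", {
  p <- make_panel(matrix(0L, 2, 4), chrom = c("1", "2", "Z", "NA"))
  f <- filter_chromosomes(p, autosomes_default())
  expect_equal(f$snps$chromosome, c("1", "2"))
  expect_equal(filter_chromosomes(p, c("1", "2", "Z", "NA"))$snps, p$snps)
  expect_error(filter_chromosomes(p, character(0)), "non-empty")
})

test_that("call-rate filtering removes samples first, then SNPs", {
  # sample 3 has 2/4 missing (cr 0.5); one SNP missing only in sample 3
  dos <- matrix(1L, 3, 4)
  dos[3, 1] <- NA; dos[3, 2] <- NA
  p <- make_panel(dos)
  r <- filter_call_rates(p, 0.95, 0.99)
  expect_equal(r$removed_samples, "s03")
  expect_equal(r$n_snps_removed, 0)   # SNP 1,2 fully observed after drop
  expect_equal(n_snps(r$panel), 4)

  full <- make_panel(matrix(1L, 3, 4))
  rf <- filter_call_rates(full, 0.95, 0.99)
  expect_equal(n_samples(rf$panel), 3)
  expect_equal(n_snps(rf$panel), 4)

  one <- make_panel(matrix(1L, 3, 4)); one$dosages[2, 3] <- NA
  r1 <- filter_call_rates(one, 1, 1)
  expect_equal(r1$removed_samples, "s02")
  expect_equal(r1$n_snps_removed, 0)

  allmiss <- make_panel(matrix(NA_integer_, 2, 2))
  expect_error(filter_call_rates(allmiss, 0.95, 0.99), "all samples")
})

test_that("pairwise r-squared matches the direct Pearson formula and flags undefined cases", {
  g1 <- c(0, 1, 2, 2, 0, 1); g2 <- c(0, 1, 2, 1, 0, 2)
  # hand evaluation: deviations (-1,0,1,1,-1,0) and (-1,0,1,0,-1,1),
  # sum xy = 3, sum x^2 = sum y^2 = 4, r = 3/4
  expect_equal(pairwise_r2(g1, g2), 0.5625, tolerance = 1e-12)
  expect_equal(pairwise_r2(g1, g1), 1)
  expect_true(is.na(pairwise_r2(c(0, 0, 0, 0), c(0, 1, 2, 1))))
  expect_true(is.na(pairwise_r2(c(0, NA, NA, 1), c(0, 1, 2, NA))))
  expect_error(pairwise_r2(c(0, 1), c(0, 1, 2)), "length")
  # pairwise-complete: the NA pair is dropped, not propagated
  expect_equal(pairwise_r2(c(g1, NA), c(g2, 0)), 0.5625, tolerance = 1e-12)
})

test_that("duplicate columns collapse to one survivor under pruning", {
  dos <- cbind(c(0L, 1L, 2L, 0L, 1L), c(0L, 1L, 2L, 0L, 1L), c(2L, 0L, 1L, 2L, 0L))
  p <- make_panel(dos)
  out <- ld_prune(p, window_size = 3, window_shift = 1, r2_threshold = 0.2)
  expect_equal(length(intersect(out$kept, 1:2)), 1)
})

test_that("windowed pruning equals the brute-force reference on block panels", {
  for (seed in 1:6) {
    p <- block_panel(n = 25, n_blocks = 12, block_size = 4, seed = seed)
    mine <- ld_prune(p, 20, 5, 0.2)$kept
    oracle <- naive_ld_prune(p, 20, 5, 0.2)
    expect_identical(mine, oracle)
  }
})

test_that("pruned panels contain no within-window pair above the threshold", {
  p <- block_panel(n = 20, n_blocks = 8, block_size = 5, seed = 11)
  out <- ld_prune(p, 15, 3, 0.2)
  kept <- out$kept
  for (start in seq(1, n_snps(p) - 14, by = 3)) {
    win <- intersect(start:(start + 14), kept)
    if (length(win) < 2) next
    for (a in seq_len(length(win) - 1)) {
      for (b in (a + 1):length(win)) {
        r2 <- pairwise_r2(p$dosages[, win[a]], p$dosages[, win[b]])
        expect_false(isTRUE(r2 > 0.2))
      }
    }
  }
})

test_that("independent SNPs survive pruning untouched", {
  # n large enough that chance r2 > 0.2 between independent SNPs is
  # essentially impossible (|r| would need to exceed 0.45 at n = 150)
  p <- hwe_panel(150, 40, 0.4, seed = 20)
  # verify independence with a brute-force all-pairs check first
  all_low <- TRUE
  for (a in 1:39) for (b in (a + 1):40) {
    r2 <- pairwise_r2(p$dosages[, a], p$dosages[, b])
    if (!is.na(r2) && r2 > 0.2) all_low <- FALSE
  }
  expect_true(all_low)  # fixture is genuinely LD-free at this seed
  out <- ld_prune(p, 15, 5, 0.2)
  expect_equal(out$kept, 1:40)
})

test_that("unsorted SNP positions are rejected by ld_prune", {
  p <- make_panel(matrix(0:2, 3, 3), pos = c(30L, 10L, 20L))
  expect_error(ld_prune(p, 2, 1, 0.2), "sorted")
})

test_that("imputation draws from within-population frequencies and touches only missing cells", {
  # q = 0 and q = 1 populations give deterministic imputations
  dos <- rbind(c(0L, 2L), c(0L, 2L), c(NA, NA))
  p <- make_panel(dos)
  pm <- uniform_pop_map(p)
  imp <- impute_missing(p, pm, seed = 1)
  expect_equal(unname(imp$dosages[3, ]), c(0L, 2L))
  expect_identical(imp$dosages[1:2, ], p$dosages[1:2, ])
  expect_false(anyNA(imp$dosages))
  # reproducible
  expect_identical(impute_missing(p, pm, seed = 5)$dosages,
                   impute_missing(p, pm, seed = 5)$dosages)
})

test_that("imputation preserves per-population allele frequencies under MCAR masking", {
  sim <- simulate_panel(sim_config(n_populations = 2, samples_per_population = 50,
                                   n_snps = 2000, drift_f = 0.2, seed = 31))
  before <- allele_frequencies(sim$panel, sim$pops)
  masked <- inject_missingness(sim$panel, 0.1, seed = 32)$panel
  imp <- impute_missing(masked, sim$pops, seed = 33)
  after <- allele_frequencies(imp, sim$pops)
  pop_mean_before <- rowMeans(before$freq)
  pop_mean_after <- rowMeans(after$freq)
  expect_true(all(abs(pop_mean_before - pop_mean_after) < 0.02))
})

test_that("the QC cascade reconciles counts stage by stage", {
  sim <- simulate_panel(sim_config(n_populations = 2, samples_per_population = 15,
                                   n_snps = 300, drift_f = 0.2,
                                   n_duplicate_snps = 5, n_nonautosomal_snps = 10,
                                   n_low_callrate_samples = 2, seed = 41))
  qc <- qc_pipeline(sim$panel, sim$pops, seed = 42)
  rep <- qc$report
  expect_equal(rep$n_input_snps, 305)
  expect_equal(rep$n_duplicates_removed, 10)        # both members of 5 pairs
  expect_equal(rep$n_nonautosomal_removed, 10)
  expect_equal(rep$n_samples_removed_callrate, 2)
  expect_equal(rep$n_input_snps - rep$n_duplicates_removed -
                 rep$n_nonautosomal_removed - rep$n_ambiguous_removed -
                 rep$n_snps_removed_callrate,
               rep$n_snps_after_callrate)
  expect_lte(rep$n_snps_after_prune, rep$n_snps_after_callrate)
  expect_equal(n_snps(qc$panel), rep$n_snps_after_prune)
  expect_false(anyNA(qc$panel$dosages))
})
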