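# shared fixtures and independent reference implementations

# random panel with arbitrary dosages; polarity_safe = TRUE constrains every
# SNP's first non-missing call to dosage 0 or 1 so that the PED counting
# allele is identifiable (see write_plink_text docs)
random_panel <- function(n = 6, m = 10, missing_rate = 0, seed = 1,
                         polarity_safe = FALSE) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missing_rate > 0) dos[runif(n * m) < missing_rate] <- NA
  if (polarity_safe) {
    for (j in seq_len(m)) {
      first <- which(!is.na(dos[, j]))[1]
      if (is.na(first)) dos[1, j] <- 0L
      else if (dos[first, j] == 2) dos[first, j] <- sample(0:1, 1)
    }
  }
  alle <- matrix(replicate(m, sample(c("A", "C", "G", "T"), 2)), nrow = 2)
  genotype_panel(
    samples = sprintf("s%02d", seq_len(n)),
    snps = data.frame(snp_id = sprintf("m%03d", seq_len(m)),
                      chromosome = "1", position = seq_len(m) * 10L,
                      allele_a = alle[1, ], allele_b = alle[2, ],
                      stringsAsFactors = FALSE),
    dosages = dos
  )
}

uniform_pop_map <- function(panel, n_pops = 1) {
  pop <- paste0("pop", rep_len(seq_len(n_pops), n_samples(panel)))
  population_map(panel$samples, pop, "cat1")
}

# HWE population: dosages ~ Binomial(2, q) at every SNP
hwe_panel <- function(n, m, q, seed = 1) {
  set.seed(seed)
  genotype_panel(
    samples = sprintf("s%03d", seq_len(n)),
    snps = data.frame(snp_id = sprintf("m%05d", seq_len(m)),
                      chromosome = "1", position = seq_len(m) * 10L,
                      allele_a = "A", allele_b = "G",
                      stringsAsFactors = FALSE),
    dosages = matrix(rbinom(n * m, 2, q), n, m)
  )
}

# independent brute-force LD pruning: same greedy rule as ld_prune but
# recomputing every r2 from scratch with pairwise_r2 on each scan
naive_ld_prune <- function(panel, window_size, window_shift, r2_threshold) {
  keep <- rep(TRUE, n_snps(panel))
  cr <- colMeans(!is.na(panel$dosages))
  chrom <- panel$snps$chromosome
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- length(idx)
    start <- 1
    repeat {
      win <- idx[start:min(start + window_size - 1, m)]
      repeat {
        act <- win[keep[win]]
        found <- FALSE
        if (length(act) >= 2) {
          for (a in 1:(length(act) - 1)) {
            for (b in (a + 1):length(act)) {
              r2 <- pairwise_r2(panel$dosages[, act[a]], panel$dosages[, act[b]])
              if (!is.na(r2) && r2 > r2_threshold) {
                drop <- if (cr[act[a]] < cr[act[b]]) act[a]
                        else if (cr[act[b]] < cr[act[a]]) act[b]
                        else act[b]
                keep[drop] <- FALSE
                found <- TRUE
                break
              }
            }
            if (found) break
          }
        }
        if (!found) break
      }
      if (start + window_size - 1 >= m) break
      start <- start + window_shift
    }
  }
  which(keep)
}

# panel with correlated SNP blocks for pruning tests: within a block each
# SNP copies a template column with a small flip probability
block_panel <- function(n = 30, n_blocks = 40, block_size = 5, seed = 1) {
  set.seed(seed)
  m <- n_blocks * block_size
  dos <- matrix(0L, n, m)
  for (b in seq_len(n_blocks)) {
    q <- runif(1, 0.2, 0.8)
    template <- rbinom(n, 2, q)
    for (s in seq_len(block_size)) {
      j <- (b - 1) * block_size + s
      flip <- runif(n) < 0.1
      dos[, j] <- ifelse(flip, rbinom(n, 2, q), template)
    }
  }
  genotype_panel(
    samples = sprintf("s%03d", seq_len(n)),
    snps = data.frame(snp_id = sprintf("m%04d", seq_len(m)),
                      chromosome = "1", position = seq_len(m) * 100L,
                      allele_a = "A", allele_b = "G",
                      stringsAsFactors = FALSE),
    dosages = dos
  )
}

# additive distance matrix from a random unrooted topology (oracle for NJ)
random_additive_matrix <- function(n_taxa = 8, seed = 1) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 1)))
  list(tree = tr, d = stats::cophenetic(tr))
}

write_test_vcf <- function(path, gts = c("0/0", "0/1"),
                           alt = "G", ref = "A") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", seq_along(gts))), collapse = "\t"),
    paste(c("1", "100", "rs1", ref, alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  )
  writeLines(lines, path)
  path
}
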