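#' Simulation configuration
#'
#' Parameters of the synthetic genotype-panel generator. The generator
#' emulates the statistical structure of a multi-population SNP-array
#' diversity panel: populations diverged to varying degrees from a shared
#' ancestral gene pool (Balding-Nichols drift model), a fraction of admixed
#' individuals, missing calls concentrated in some samples, local LD blocks,
#' exactly duplicated SNPs, and SNPs annotated to a non-autosomal
#' chromosome.
#'
#' @param n_populations number of source populations.
#' @param samples_per_population diploid individuals drawn from each pure
#'   population.
#' @param n_snps number of base SNPs (duplicated SNPs are added on top).
#' @param drift_f per-population drift parameter F in (0,1); recycled to
#'   `n_populations`. Under the Balding-Nichols model the population allele
#'   frequency is Beta-distributed around the ancestral frequency `p0` with
#'   variance `F * p0 * (1 - p0)`.
#' @param n_admixed number of additional admixed individuals.
#' @param admix_dirichlet_alpha Dirichlet concentration vector (length
#'   `n_populations`) for admixed ancestry proportions.
#' @param missing_rate fraction in \[0,1) of cells set missing completely at
#'   random.
#' @param n_low_callrate_samples samples whose call rate is forced to 90%
#'   (below the usual 95% animal-call-rate threshold).
#' @param ld_block_size SNPs per LD block (1 = independent SNPs). SNPs in a
#'   block share one latent frequency draw and copy a per-individual
#'   template haplotype with small noise, giving pairwise r-squared well
#'   above 0.5 in expectation.
#' @param n_duplicate_snps exact column copies (same chromosome and
#'   position) appended next to randomly chosen autosomal SNPs.
#' @param n_nonautosomal_snps trailing base SNPs relabelled to chromosome
#'   "Z".
#' @param seed integer root seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 3,
                       samples_per_population = 20,
                       n_snps = 1000,
                       drift_f = 0.2,
                       n_admixed = 0,
                       admix_dirichlet_alpha = rep(1, n_populations),
                       missing_rate = 0,
                       n_low_callrate_samples = 0,
                       ld_block_size = 1,
                       n_duplicate_snps = 0,
                       n_nonautosomal_snps = 0,
                       seed = 1) {
  drift_f <- rep_len(drift_f, n_populations)
  if (any(drift_f <= 0 | drift_f >= 1)) {
    stop("drift_f must lie in the open interval (0, 1)")
  }
  counts <- c(n_populations = n_populations,
              samples_per_population = samples_per_population,
              n_snps = n_snps, n_admixed = n_admixed,
              n_low_callrate_samples = n_low_callrate_samples,
              n_duplicate_snps = n_duplicate_snps,
              n_nonautosomal_snps = n_nonautosomal_snps)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_populations < 1) stop("need at least one population")
  if (length(admix_dirichlet_alpha) != n_populations) {
    stop("admix_dirichlet_alpha must have length n_populations")
  }
  if (any(admix_dirichlet_alpha <= 0)) stop("Dirichlet alpha must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (n_nonautosomal_snps > n_snps) stop("n_nonautosomal_snps exceeds n_snps")
  structure(list(
    n_populations = n_populations,
    samples_per_population = samples_per_population,
    n_snps = n_snps, drift_f = drift_f, n_admixed = n_admixed,
    admix_dirichlet_alpha = admix_dirichlet_alpha,
    missing_rate = missing_rate,
    n_low_callrate_samples = n_low_callrate_samples,
    ld_block_size = ld_block_size,
    n_duplicate_snps = n_duplicate_snps,
    n_nonautosomal_snps = n_nonautosomal_snps,
    seed = as.integer(seed)
  ), class = "sim_config")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a genotype panel with known population structure
#'
#' Ancestral allele frequencies are drawn uniform on (0.05, 0.95); each
#' population's frequencies come from the Balding-Nichols distribution
#' `Beta(p0 (1 - F) / F, (1 - p0)(1 - F) / F)`. Pure individuals' dosages
#' are Binomial(2, pop_freq); admixed individuals draw each allele copy from
#' a population sampled by their Dirichlet ancestry vector. LD blocks,
#' duplicate SNPs, non-autosomal labels and missingness are injected per the
#' configuration. The result is fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` ([genotype_panel()]), `pops`
#'   ([population_map()]; populations "pop1".. in category "simulated",
#'   admixed individuals in population "admixed"), and `truth` — a list with
#'   `ancestral_freq`, `pop_freq` (population x SNP), `true_q` (individual x
#'   population ancestry), `duplicate_pairs` (two-column index matrix into
#'   the final SNP list) and `nonautosomal_ids`.
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  P <- config$n_populations
  M <- config$n_snps
  n_pure <- P * config$samples_per_population
  N <- n_pure + config$n_admixed

  # block structure: latent ancestral frequency shared within a block
  n_auto <- M - config$n_nonautosomal_snps
  block_of <- ceiling(seq_len(M) / config$ld_block_size)
  n_blocks <- max(block_of, 0)
  block_p0 <- stats::runif(n_blocks, 0.05, 0.95)
  p0 <- block_p0[block_of]

  # Balding-Nichols population frequencies, per block then expanded
  pop_freq <- matrix(NA_real_, P, M)
  for (k in seq_len(P)) {
    f <- config$drift_f[k]
    bp <- stats::rbeta(n_blocks, block_p0 * (1 - f) / f,
                       (1 - block_p0) * (1 - f) / f)
    # guard against numerical 0/1 from extreme Beta draws
    bp <- pmin(pmax(bp, 1e-12), 1 - 1e-12)
    pop_freq[k, ] <- bp[block_of]
  }

  # ancestry
  true_q <- matrix(0, N, P)
  pop_label <- character(N)
  for (k in seq_len(P)) {
    idx <- ((k - 1) * config$samples_per_population + 1):(k * config$samples_per_population)
    if (config$samples_per_population > 0) {
      true_q[idx, k] <- 1
      pop_label[idx] <- paste0("pop", k)
    }
  }
  if (config$n_admixed > 0) {
    idx <- (n_pure + 1):N
    true_q[idx, ] <- rdirichlet(config$n_admixed, config$admix_dirichlet_alpha)
    pop_label[idx] <- "admixed"
  }

  # genotypes: pure individuals copy a block template haplotype with noise;
  # admixed individuals draw each allele copy allele-wise from q
  eps <- 0.05  # per-SNP template copy-noise
  dos <- matrix(NA_integer_, N, M)
  for (k in seq_len(P)) {
    rows <- which(pop_label == paste0("pop", k))
    n <- length(rows)
    if (n == 0) next
    if (config$ld_block_size == 1) {
      dos[rows, ] <- matrix(
        stats::rbinom(n * M, 2, rep(pop_freq[k, ], each = n)), n, M)
    } else {
      bp <- pop_freq[k, !duplicated(block_of)]  # one freq per block
      h1t <- matrix(stats::rbinom(n * n_blocks, 1, rep(bp, each = n)), n, n_blocks)
      h2t <- matrix(stats::rbinom(n * n_blocks, 1, rep(bp, each = n)), n, n_blocks)
      pj <- matrix(rep(pop_freq[k, ], each = n), n, M)
      flip1 <- matrix(stats::runif(n * M) < eps, n, M)
      flip2 <- matrix(stats::runif(n * M) < eps, n, M)
      h1 <- ifelse(flip1, stats::rbinom(n * M, 1, pj), h1t[, block_of])
      h2 <- ifelse(flip2, stats::rbinom(n * M, 1, pj), h2t[, block_of])
      dos[rows, ] <- h1 + h2
    }
  }
  if (config$n_admixed > 0) {
    rows <- which(pop_label == "admixed")
    for (i in rows) {
      z1 <- sample.int(P, M, replace = TRUE, prob = true_q[i, ])
      z2 <- sample.int(P, M, replace = TRUE, prob = true_q[i, ])
      p1 <- pop_freq[cbind(z1, seq_len(M))]
      p2 <- pop_freq[cbind(z2, seq_len(M))]
      dos[i, ] <- stats::rbinom(M, 1, p1) + stats::rbinom(M, 1, p2)
    }
  }

  samples <- sprintf("%s_i%03d", pop_label, seq_len(N))
  chrom <- rep("1", M)
  if (n_auto > 0) {
    n_chr <- max(1L, min(4L, n_auto %/% 50L))
    chrom[seq_len(n_auto)] <- as.character(ceiling(seq_len(n_auto) / ceiling(n_auto / n_chr)))
  }
  nonauto_idx <- if (config$n_nonautosomal_snps > 0) (n_auto + 1):M else integer(0)
  chrom[nonauto_idx] <- "Z"
  pos <- integer(M)
  for (ch in unique(chrom)) {
    w <- which(chrom == ch)
    pos[w] <- seq_along(w) * 1000L
  }
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(M)),
                     chromosome = chrom, position = pos,
                     allele_a = "A", allele_b = "G",
                     stringsAsFactors = FALSE)

  # duplicate SNPs: exact column copies adjacent to the original
  duplicate_pairs <- matrix(integer(0), 0, 2)
  if (config$n_duplicate_snps > 0) {
    if (n_auto < 1) stop("cannot duplicate SNPs: no autosomal SNPs")
    src <- sort(sample(seq_len(n_auto),
                       min(config$n_duplicate_snps, n_auto)))
    ord <- integer(0); dup_flag <- logical(0)
    for (j in seq_len(M)) {
      ord <- c(ord, j); dup_flag <- c(dup_flag, FALSE)
      if (j %in% src) { ord <- c(ord, j); dup_flag <- c(dup_flag, TRUE) }
    }
    dos <- dos[, ord, drop = FALSE]
    snps <- snps[ord, , drop = FALSE]
    snps$snp_id[dup_flag] <- paste0(snps$snp_id[dup_flag], "_dup")
    rownames(snps) <- NULL
    pop_freq <- pop_freq[, ord, drop = FALSE]
    new_idx <- seq_along(ord)
    duplicate_pairs <- cbind(which(dup_flag) - 1L, which(dup_flag))
    nonauto_idx <- which(snps$chromosome == "Z")
  }

  # missingness: MCAR, then force low-call-rate samples to 90% call rate
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(dos)) < config$missing_rate,
                   nrow(dos), ncol(dos))
    dos[mask] <- NA_integer_
  }
  if (config$n_low_callrate_samples > 0) {
    low <- sample.int(N, min(config$n_low_callrate_samples, N))
    m_tot <- ncol(dos)
    for (i in low) {
      need <- ceiling(0.10 * m_tot) - sum(is.na(dos[i, ]))
      if (need > 0) {
        obs <- which(!is.na(dos[i, ]))
        dos[i, sample(obs, min(need, length(obs)))] <- NA_integer_
      }
    }
    attr_low <- samples[low]
  } else attr_low <- character(0)

  panel <- genotype_panel(samples, snps, dos)
  pops <- population_map(samples, pop_label,
                         ifelse(pop_label == "admixed", "admixed", "simulated"))
  truth <- list(ancestral_freq = p0, pop_freq = pop_freq, true_q = true_q,
                duplicate_pairs = duplicate_pairs,
                nonautosomal_ids = panel$snps$snp_id[nonauto_idx],
                low_callrate_samples = attr_low)
  list(panel = panel, pops = pops, truth = truth)
}

#' Hide additional cells of a panel at random
#'
#' Sets exactly `round(rate * #non-missing cells)` currently observed cells
#' to missing, chosen uniformly without replacement. Used for imputation and
#' cross-validation checks.
#'
#' @param panel a [genotype_panel()].
#' @param rate fraction in \[0, 1) of observed cells to hide.
#' @param seed integer seed; the same seed yields the same mask.
#' @return A list with `panel` (masked) and `mask` (two-column matrix of
#'   sample/SNP indices of the hidden cells).
#' @export
inject_missingness <- function(panel, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  obs <- which(!is.na(panel$dosages))
  n_hide <- round(rate * length(obs))
  if (n_hide == 0) {
    return(list(panel = panel, mask = matrix(integer(0), 0, 2,
                dimnames = list(NULL, c("sample", "snp")))))
  }
  set.seed(seed)
  hide <- sort(sample(obs, n_hide))
  dos <- panel$dosages
  dos[hide] <- NA_integer_
  mask <- cbind(sample = ((hide - 1L) %% nrow(dos)) + 1L,
                snp = ((hide - 1L) %/% nrow(dos)) + 1L)
  list(panel = genotype_panel(panel$samples, panel$snps, dos), mask = mask)
}
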