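#' Per-population allele-b frequencies
#'
#' For each population and SNP, `q = sum(dosages) / (2 * n_obs)` over the
#' non-missing calls. Cells with no observed call are `NA` (undefined).
#'
#' @param panel a [genotype_panel()].
#' @param pops a [population_map()] covering the panel.
#' @return A list with `freq` and `n_obs`, both population x SNP matrices
#'   (row names = population labels in order of first appearance).
#' @export
allele_frequencies <- function(panel, pops) {
  pm <- match_population_map(pops, panel)
  pop_levels <- unique(pm$population)
  g <- factor(pm$population, levels = pop_levels)
  if (any(table(g) == 0)) stop("population with zero samples")
  obs <- !is.na(panel$dosages)
  dos0 <- panel$dosages
  dos0[!obs] <- 0L
  sums <- rowsum(dos0, g)                 # population x SNP allele-b counts
  n_obs <- rowsum(obs + 0L, g)
  freq <- sums / (2 * n_obs)
  freq[n_obs == 0] <- NA_real_
  rownames(freq) <- rownames(n_obs) <- pop_levels
  colnames(freq) <- colnames(n_obs) <- panel$snps$snp_id
  list(freq = freq, n_obs = n_obs)
}

#' Observed heterozygosity per population
#'
#' Per SNP, the fraction of non-missing calls equal to 1 (heterozygous),
#' then averaged over SNPs; SNPs with no observed call in a population are
#' excluded from that population's mean.
#'
#' @param panel a [genotype_panel()].
#' @param pops a [population_map()] covering the panel.
#' @return Named numeric vector of Ho per population.
#' @export
observed_heterozygosity <- function(panel, pops) {
  pm <- match_population_map(pops, panel)
  pop_levels <- unique(pm$population)
  g <- factor(pm$population, levels = pop_levels)
  het <- (panel$dosages == 1L) + 0L
  obs <- !is.na(panel$dosages)
  het[!obs] <- 0L
  het_counts <- rowsum(het, g)
  n_obs <- rowsum(obs + 0L, g)
  per_snp <- het_counts / n_obs          # NaN where n_obs = 0
  ho <- apply(per_snp, 1, function(x) mean(x[is.finite(x)]))
  stats::setNames(ho, pop_levels)
}

#' Expected heterozygosity per population
#'
#' `He = 2 q (1 - q)` at each SNP, averaged over the SNPs where the
#' population's frequency is defined. Maximum 0.5 for biallelic loci.
#'
#' @param freqs output of [allele_frequencies()].
#' @return Named numeric vector of He per population.
#' @export
expected_heterozygosity <- function(freqs) {
  he_mat <- 2 * freqs$freq * (1 - freqs$freq)
  apply(he_mat, 1, function(x) mean(x, na.rm = TRUE))
}

#' Proportion of polymorphic loci per population
#'
#' A SNP is polymorphic in a population when both alleles are observed
#' there (0 < q < 1); the proportion is taken over SNPs with defined q.
#' No minor-allele-frequency threshold is applied.
#'
#' @param freqs output of [allele_frequencies()].
#' @return Named numeric vector of p per population.
#' @export
polymorphic_proportion <- function(freqs) {
  apply(freqs$freq, 1, function(q) {
    q <- q[!is.na(q)]
    if (length(q) == 0) return(NA_real_)
    mean(q > 0 & q < 1)
  })
}

#' Per-population diversity table
#'
#' Combines sample counts, observed and expected heterozygosity and the
#' proportion of polymorphic loci into one table (the per-population shape
#' of a supplementary diversity table).
#'
#' @param panel a [genotype_panel()] (imputed or not).
#' @param pops a [population_map()] covering the panel.
#' @return Data frame with columns `population`, `category`, `n_samples`,
#'   `ho`, `he`, `prop_polymorphic`.
#' @export
diversity_table <- function(panel, pops) {
  pm <- match_population_map(pops, panel)
  freqs <- allele_frequencies(panel, pm)
  ho <- observed_heterozygosity(panel, pm)
  he <- expected_heterozygosity(freqs)
  p <- polymorphic_proportion(freqs)
  pop_levels <- names(ho)
  cat_of <- pm$category[match(pop_levels, pm$population)]
  data.frame(population = pop_levels, category = cat_of,
             n_samples = as.integer(table(factor(pm$population, pop_levels))),
             ho = unname(ho), he = unname(he[pop_levels]),
             prop_polymorphic = unname(p[pop_levels]),
             stringsAsFactors = FALSE)
}

#' Category-level diversity summaries
#'
#' Unweighted means over member populations of the proportion of
#' polymorphic loci and observed heterozygosity (each population counts
#' once regardless of its sample size), plus the overall unweighted mean Ho
#' across all populations as attribute `overall_mean_ho`.
#'
#' @param records output of [diversity_table()].
#' @return Data frame with columns `category`, `mean_prop_polymorphic`,
#'   `mean_ho`, `n_populations`.
#' @export
category_summary <- function(records) {
  if (nrow(records) == 0) stop("empty diversity table")
  if (anyNA(records$category)) stop("population without category")
  cats <- unique(records$category)
  out <- do.call(rbind, lapply(cats, function(cc) {
    r <- records[records$category == cc, , drop = FALSE]
    data.frame(category = cc,
               mean_prop_polymorphic = mean(r$prop_polymorphic),
               mean_ho = mean(r$ho),
               n_populations = nrow(r),
               stringsAsFactors = FALSE)
  }))
  attr(out, "overall_mean_ho") <- mean(records$ho)
  out
}
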