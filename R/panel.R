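#' Construct a genotype panel
#'
#' A `genotype_panel` is the central container of the package: a set of
#' diploid individuals typed at biallelic SNPs. Genotypes are stored as
#' allele-b dosages, i.e. the number of copies (0, 1 or 2) of the designated
#' "b" allele (the ALT allele for VCF input, the second-observed allele for
#' PLINK text input). Missing calls are `NA`.
#'
#' @param samples character vector of unique sample identifiers.
#' @param snps data frame with columns `snp_id`, `chromosome`, `position`,
#'   `allele_a`, `allele_b`. Positions are 1-based. `snp_id` may contain
#'   duplicates before QC; [remove_duplicate_snps()] resolves them.
#' @param dosages integer matrix, samples x SNPs, entries in `{0, 1, 2, NA}`.
#'
#' @return An object of class `genotype_panel` with elements `samples`,
#'   `snps` and `dosages` (row names = samples, column names = snp ids).
#' @export
#' @examples
#' p <- genotype_panel(
#'   samples = c("s1", "s2"),
#'   snps = data.frame(snp_id = "rs1", chromosome = "1", position = 100L,
#'                     allele_a = "A", allele_b = "G"),
#'   dosages = matrix(c(0L, 1L), nrow = 2)
#' )
#' n_snps(p)
genotype_panel <- function(samples, snps, dosages) {
  samples <- as.character(samples)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  required <- c("snp_id", "chromosome", "position", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position <- as.integer(snps$position)
  snps$allele_a <- as.character(snps$allele_a)
  snps$allele_b <- as.character(snps$allele_b)
  rownames(snps) <- NULL
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  panel <- structure(
    list(samples = samples, snps = snps, dosages = dosages),
    class = "genotype_panel"
  )
  validate_panel(panel)
  panel
}

#' Validate a genotype panel
#'
#' Checks the structural invariants: matrix dimensions match the sample and
#' SNP lists, every dosage is in `{0, 1, 2, NA}`, sample identifiers are
#' unique, positions are >= 1 and the two alleles of each SNP differ.
#'
#' @param panel a [genotype_panel()].
#' @return The panel, invisibly; an error is raised on violation.
#' @export
validate_panel <- function(panel) {
  if (!inherits(panel, "genotype_panel")) stop("not a genotype_panel")
  n <- length(panel$samples)
  m <- nrow(panel$snps)
  if (!identical(dim(panel$dosages), c(n, m))) {
    stop("dosage matrix is ", nrow(panel$dosages), "x", ncol(panel$dosages),
         " but panel declares ", n, " samples x ", m, " SNPs")
  }
  if (anyDuplicated(panel$samples)) {
    stop("duplicate sample identifiers: ",
         paste(unique(panel$samples[duplicated(panel$samples)]), collapse = ", "))
  }
  vals <- panel$dosages[!is.na(panel$dosages)]
  if (length(vals) > 0 && !all(vals %in% 0:2)) {
    stop("dosages contain values outside {0, 1, 2, NA}")
  }
  if (m > 0) {
    if (any(panel$snps$position < 1L, na.rm = TRUE)) {
      stop("SNP positions must be >= 1")
    }
    same <- panel$snps$allele_a == panel$snps$allele_b
    if (any(same, na.rm = TRUE)) {
      stop("allele_a equals allele_b for SNP(s): ",
           paste(utils::head(panel$snps$snp_id[which(same)], 5), collapse = ", "))
    }
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat("genotype_panel: ", length(x$samples), " samples x ", nrow(x$snps),
      " SNPs (", sprintf("%.1f", 100 * miss), "% missing)\n", sep = "")
  invisible(x)
}

#' Number of samples / SNPs in a panel
#' @param panel a [genotype_panel()].
#' @return integer count.
#' @export
n_samples <- function(panel) length(panel$samples)

#' @rdname n_samples
#' @export
n_snps <- function(panel) nrow(panel$snps)

#' Subset a panel by SNP and/or sample index
#'
#' Keeps the relative order of the retained rows/columns.
#'
#' @param panel a [genotype_panel()].
#' @param snp_idx integer or logical index into the SNP list (default: all).
#' @param sample_idx integer or logical index into the sample list.
#' @return The subsetted [genotype_panel()].
#' @export
subset_panel <- function(panel, snp_idx = NULL, sample_idx = NULL) {
  if (is.null(snp_idx)) snp_idx <- seq_len(n_snps(panel))
  if (is.null(sample_idx)) sample_idx <- seq_len(n_samples(panel))
  genotype_panel(
    samples = panel$samples[sample_idx],
    snps = panel$snps[snp_idx, , drop = FALSE],
    dosages = panel$dosages[sample_idx, snp_idx, drop = FALSE]
  )
}

#' Construct a population map
#'
#' Assigns every sample to exactly one population and every population to
#' exactly one category (e.g. "commercial white layer", "wild", "fancy").
#'
#' @param sample character vector of sample identifiers (unique).
#' @param population character vector, same length: population label.
#' @param category character vector, same length: category label of the
#'   sample's population.
#' @return A data frame of class `population_map` with columns `sample`,
#'   `population`, `category`.
#' @export
population_map <- function(sample, population, category) {
  pm <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   category = as.character(category),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pm$sample)) {
    stop("duplicate sample assignment: ",
         paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", "))
  }
  pc <- unique(pm[, c("population", "category")])
  dup <- pc$population[duplicated(pc$population)]
  if (length(dup) > 0) {
    stop("population(s) assigned to more than one category: ",
         paste(unique(dup), collapse = ", "))
  }
  class(pm) <- c("population_map", "data.frame")
  pm
}

#' Check that a population map covers a panel
#'
#' @param pops a [population_map()].
#' @param panel a [genotype_panel()].
#' @return Invisibly, the map reordered to the panel's sample order.
#' @export
match_population_map <- function(pops, panel) {
  idx <- match(panel$samples, pops$sample)
  if (anyNA(idx)) {
    stop("samples absent from population map: ",
         paste(panel$samples[is.na(idx)], collapse = ", "))
  }
  out <- pops[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("population_map", "data.frame")
  invisible(out)
}
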