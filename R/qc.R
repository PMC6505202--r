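#' Remove positionally duplicated SNPs
#'
#' Any group of SNPs sharing both chromosome and position is removed
#' entirely — every member of the group is deleted, not just the extra
#' copies. Survivor order is preserved.
#'
#' @param panel a [genotype_panel()].
#' @return A list with `panel` (filtered) and `removed_ids` (character
#'   vector of deleted snp ids, in panel order).
#' @export
remove_duplicate_snps <- function(panel) {
  key <- paste(panel$snps$chromosome, panel$snps$position, sep = "\r")
  dup_key <- unique(key[duplicated(key)])
  drop <- key %in% dup_key
  list(panel = subset_panel(panel, snp_idx = !drop),
       removed_ids = panel$snps$snp_id[drop])
}

#' Restrict a panel to a set of chromosomes
#'
#' Removes SNPs whose chromosome label is not in `keep` (sex-linked,
#' unplaced or ambiguously annotated markers). The default keep set
#' elsewhere in the package is the autosomes "1".."28".
#'
#' @param panel a [genotype_panel()].
#' @param keep non-empty character vector of chromosome labels to retain.
#' @return The filtered [genotype_panel()].
#' @export
filter_chromosomes <- function(panel, keep) {
  if (length(keep) == 0) stop("keep set of chromosomes must be non-empty")
  subset_panel(panel, snp_idx = panel$snps$chromosome %in% as.character(keep))
}

#' Autosome labels "1".."28"
#' @return character vector.
#' @export
autosomes_default <- function() as.character(1:28)

#' Filter samples then SNPs by call rate
#'
#' Order matters and is fixed: samples with call rate (fraction of
#' non-missing calls over the current SNPs) below `min_sample_cr` are
#' removed first; SNP call rates are then computed over the remaining
#' samples and SNPs below `min_snp_cr` removed. Thresholds are inclusive
#' (call rate >= threshold survives).
#'
#' @param panel a [genotype_panel()].
#' @param min_sample_cr minimum sample (animal) call rate, in (0, 1].
#' @param min_snp_cr minimum SNP call rate, in (0, 1].
#' @return A list with `panel`, `removed_samples`, `removed_snps` (ids) and
#'   counts `n_samples_removed`, `n_snps_removed`.
#' @export
filter_call_rates <- function(panel, min_sample_cr = 0.95, min_snp_cr = 0.99) {
  stopifnot(min_sample_cr > 0, min_sample_cr <= 1,
            min_snp_cr > 0, min_snp_cr <= 1)
  m <- n_snps(panel)
  sample_cr <- if (m > 0) rowMeans(!is.na(panel$dosages)) else rep(1, n_samples(panel))
  keep_s <- sample_cr >= min_sample_cr
  if (!any(keep_s)) {
    stop("all samples fall below the sample call-rate threshold of ",
         min_sample_cr)
  }
  removed_samples <- panel$samples[!keep_s]
  panel2 <- subset_panel(panel, sample_idx = keep_s)
  snp_cr <- if (n_samples(panel2) > 0) colMeans(!is.na(panel2$dosages)) else numeric(m)
  keep_m <- snp_cr >= min_snp_cr
  removed_snps <- panel2$snps$snp_id[!keep_m]
  list(panel = subset_panel(panel2, snp_idx = keep_m),
       removed_samples = removed_samples,
       removed_snps = removed_snps,
       n_samples_removed = sum(!keep_s),
       n_snps_removed = sum(!keep_m))
}

#' Pairwise genotypic r-squared of two dosage vectors
#'
#' Squared Pearson correlation of unphased dosages over pairwise-complete
#' entries (composite LD). Returns `NA` (undefined) when fewer than two
#' complete pairs exist or either vector is constant over them; undefined
#' pairs are never pruned.
#'
#' @param g1,g2 numeric dosage vectors of equal length (`NA` = missing).
#' @return r-squared in \[0, 1\], or `NA` if undefined.
#' @export
pairwise_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) {
    stop("dosage vectors differ in length: ", length(g1), " vs ", length(g2))
  }
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- stats::cor(x, y)
  min(r * r, 1)
}

# r^2 matrix over pairwise-complete entries for a dosage submatrix
# (columns = SNPs); undefined entries NA
r2_matrix <- function(g) {
  suppressWarnings(cm <- stats::cor(g, use = "pairwise.complete.obs"))
  n_pair <- crossprod(!is.na(g))
  cm[n_pair < 2] <- NA
  cm * cm
}

#' LD pruning with a sliding SNP window
#'
#' Greedy scan per chromosome, with windows of `window_size` SNPs advanced
#' by `window_shift`: within each window, while some retained pair has
#' r-squared above `r2_threshold`, one SNP of the offending pair is removed
#' (the one with the lower call rate; ties remove the later index). Removed
#' SNPs stay removed; windows never span chromosomes. The output is
#' deterministic for a fixed input.
#'
#' @param panel a [genotype_panel()] with SNPs sorted by (chromosome,
#'   position); unsorted input is an error.
#' @param window_size window size in SNPs.
#' @param window_shift window shift in SNPs (1 <= shift <= size).
#' @param r2_threshold pruning threshold in (0, 1]; pairs with r-squared
#'   strictly greater are broken up.
#' @return A list with `panel` (pruned) and `kept` (integer indices into the
#'   input SNP list, increasing).
#' @export
ld_prune <- function(panel, window_size = 50, window_shift = 5,
                     r2_threshold = 0.2) {
  stopifnot(window_shift >= 1, window_shift <= window_size,
            r2_threshold > 0, r2_threshold <= 1)
  chrom <- panel$snps$chromosome
  pos <- panel$snps$position
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) stop("SNPs not sorted by position on chromosome ", ch)
  }
  if (is.unsorted(match(chrom, unique(chrom)))) {
    stop("SNPs of one chromosome must be contiguous")
  }
  call_rate <- colMeans(!is.na(panel$dosages))
  keep <- rep(TRUE, n_snps(panel))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- length(idx)
    start <- 1
    repeat {
      win <- idx[start:min(start + window_size - 1, m)]
      active <- win[keep[win]]
      if (length(active) >= 2) {
        r2 <- r2_matrix(panel$dosages[, active, drop = FALSE])
        alive <- rep(TRUE, length(active))
        repeat {
          viol <- which(r2 > r2_threshold & upper.tri(r2), arr.ind = TRUE)
          if (nrow(viol) == 0) break
          # first violating pair in column-major scan order (i < j)
          viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
          i <- viol[1, 1]; j <- viol[1, 2]
          drop_local <- if (call_rate[active[i]] < call_rate[active[j]]) i
                        else if (call_rate[active[j]] < call_rate[active[i]]) j
                        else j  # tie: remove the later index
          alive[drop_local] <- FALSE
          r2[drop_local, ] <- NA
          r2[, drop_local] <- NA
        }
        keep[active[!alive]] <- FALSE
      }
      if (start + window_size - 1 >= m) break
      start <- start + window_shift
    }
  }
  kept <- which(keep)
  list(panel = subset_panel(panel, snp_idx = kept), kept = kept)
}

#' Impute missing genotypes from within-population allele frequencies
#'
#' Each missing cell is replaced by a draw from Binomial(2, q) where q is
#' the allele-b frequency of the sample's population at that SNP, computed
#' from the non-missing calls. When a population has no observed call at a
#' SNP the panel-wide frequency is used; a SNP observed nowhere falls back
#' to q = 0.5. Non-missing cells are never touched; the result contains no
#' missing values and is reproducible from `seed`.
#'
#' @param panel a [genotype_panel()].
#' @param pops a [population_map()] covering the panel.
#' @param seed integer seed for the binomial draws.
#' @return The imputed [genotype_panel()].
#' @export
impute_missing <- function(panel, pops, seed = 1) {
  pm <- match_population_map(pops, panel)
  dos <- panel$dosages
  miss <- which(is.na(dos))
  if (length(miss) == 0) return(panel)
  ft <- allele_frequencies(panel, pm)
  panel_q <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  panel_q[!is.finite(panel_q)] <- 0.5
  pop_idx <- match(pm$population, rownames(ft$freq))
  mi <- ((miss - 1L) %% nrow(dos)) + 1L   # sample row
  mj <- ((miss - 1L) %/% nrow(dos)) + 1L  # snp column
  q <- ft$freq[cbind(pop_idx[mi], mj)]
  q[is.na(q)] <- panel_q[mj[is.na(q)]]
  set.seed(seed)
  dos[miss] <- stats::rbinom(length(miss), 2, q)
  genotype_panel(panel$samples, panel$snps, dos)
}

#' Run the full QC cascade
#'
#' Fixed stage order: positional-duplicate removal, chromosome restriction,
#' sample then SNP call-rate filtering, sliding-window LD pruning, and
#' optional within-population imputation of the remaining missing calls.
#' Counts are accumulated in a `qc_report` that reconciles exactly:
#' input minus removals equals output at every stage.
#'
#' @param panel a [genotype_panel()].
#' @param pops a [population_map()]; required when `impute = TRUE`.
#' @param autosomes chromosome labels to keep (default "1".."28").
#' @param min_sample_cr,min_snp_cr call-rate thresholds (defaults 0.95 and
#'   0.99).
#' @param window_size,window_shift,r2_threshold LD-pruning parameters
#'   (defaults 50, 5, 0.2).
#' @param impute logical: run the seeded imputer after pruning.
#' @param seed seed for the imputer.
#' @return A list with `panel` (post-QC) and `report` (class `qc_report`).
#' @export
qc_pipeline <- function(panel, pops = NULL,
                        autosomes = autosomes_default(),
                        min_sample_cr = 0.95, min_snp_cr = 0.99,
                        window_size = 50, window_shift = 5,
                        r2_threshold = 0.2,
                        impute = TRUE, seed = 1) {
  report <- list(n_input_snps = n_snps(panel),
                 n_input_samples = n_samples(panel))
  d <- remove_duplicate_snps(panel)
  report$n_duplicates_removed <- length(d$removed_ids)
  ch <- filter_chromosomes(d$panel, autosomes)
  gone <- !(d$panel$snps$chromosome %in% as.character(autosomes))
  ambiguous <- d$panel$snps$chromosome %in% c("", "0", "NA", "?") |
    is.na(d$panel$snps$chromosome)
  report$n_ambiguous_removed <- sum(gone & ambiguous)
  report$n_nonautosomal_removed <- sum(gone & !ambiguous)
  cr <- filter_call_rates(ch, min_sample_cr, min_snp_cr)
  report$n_samples_removed_callrate <- cr$n_samples_removed
  report$n_snps_removed_callrate <- cr$n_snps_removed
  report$n_snps_after_callrate <- n_snps(cr$panel)
  pr <- ld_prune(cr$panel, window_size, window_shift, r2_threshold)
  report$n_snps_after_prune <- n_snps(pr$panel)
  out <- pr$panel
  if (impute && any(is.na(out$dosages))) {
    if (is.null(pops)) stop("impute = TRUE requires a population map")
    out <- impute_missing(out, pops, seed = seed)
  }
  report$n_output_samples <- n_samples(out)
  class(report) <- "qc_report"
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  for (k in names(x)) cat(k, "=", x[[k]], "\n")
  invisible(x)
}

#' Write a QC report as key=value text
#' @param report a `qc_report`.
#' @param path output path.
#' @return Invisibly, `NULL`.
#' @export
write_qc_report <- function(report, path) {
  writeLines(paste0(names(report), "=",
                    vapply(report, as.character, character(1))), path)
  invisible(NULL)
}
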