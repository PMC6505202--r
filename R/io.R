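#' Read a VCF file into a genotype panel
#'
#' Consumes only the GT field. Dosage counts copies of the ALT allele
#' (allele_b = ALT); `./.` and `.|.` become missing. Sample order follows
#' the VCF header. Only biallelic SNP records are accepted.
#'
#' @param path path to a VCF file (plain text or gzip).
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  bad_alt <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(bad_alt)) {
    stop("multi-allelic record not supported: ",
         fix$CHROM[which(bad_alt)[1]], ":", fix$POS[which(bad_alt)[1]],
         " ALT=", fix$ALT[which(bad_alt)[1]])
  }
  nuc <- c("A", "C", "G", "T", "a", "c", "g", "t")
  not_snp <- !(fix$REF %in% nuc) | !(fix$ALT %in% nuc)
  if (any(not_snp)) {
    stop("non-SNP record not supported: ",
         fix$CHROM[which(not_snp)[1]], ":", fix$POS[which(not_snp)[1]],
         " REF=", fix$REF[which(not_snp)[1]], " ALT=", fix$ALT[which(not_snp)[1]])
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")          # SNP x sample
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  # strip phasing, count ALT ("1") alleles; gt is SNP x sample
  alleles1 <- substr(gt, 1, 1)
  alleles2 <- substr(gt, 3, 3)
  dos <- (alleles1 == "1") + (alleles2 == "1")
  dos[alleles1 == "." | alleles2 == "." | is.na(c(gt))] <- NA
  dos_mat <- matrix(as.integer(dos), nrow = nrow(gt), ncol = ncol(gt))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  genotype_panel(
    samples = colnames(gt),
    snps = data.frame(snp_id = ids, chromosome = fix$CHROM,
                      position = as.integer(fix$POS),
                      allele_a = toupper(fix$REF), allele_b = toupper(fix$ALT),
                      stringsAsFactors = FALSE),
    dosages = t(dos_mat)
  )
}

#' Read PLINK text (PED/MAP) files into a genotype panel
#'
#' The PED file has six leading columns (family, individual, paternal,
#' maternal, sex, phenotype) followed by two allele columns per SNP; the MAP
#' file has four columns (chromosome, snp id, genetic distance, position).
#' For each SNP, `allele_a` is the first allele observed scanning samples in
#' file order and `allele_b` the second-observed; dosage counts `allele_b`.
#' `0 0` is missing; half-missing calls (e.g. `A 0`) are rejected.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A [genotype_panel()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character",
                           col.names = c("chromosome", "snp_id", "cm", "position"))
  m <- nrow(map)
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6 + 2 * m)) {
    bad <- which(nf != 6 + 2 * m)[1]
    stop("PED line ", bad, " has ", nf[bad], " fields; MAP declares ", m,
         " SNPs (expected ", 6 + 2 * m, ")")
  }
  samples <- vapply(fields, `[`, character(1), 2L)
  dos <- matrix(NA_integer_, n, m)
  allele_a <- rep(NA_character_, m)
  allele_b <- rep(NA_character_, m)
  if (m > 0 && n > 0) {
    al <- matrix(unlist(lapply(fields, `[`, -(1:6))), nrow = n, byrow = TRUE)
    a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
    a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
    half <- xor(a1 == "0", a2 == "0")
    if (any(half)) {
      w <- which(half, arr.ind = TRUE)[1, ]
      stop("half-missing genotype '", a1[w[1], w[2]], " ", a2[w[1], w[2]],
           "' for sample ", samples[w[1]], ", SNP ", map$snp_id[w[2]])
    }
    for (j in seq_len(m)) {
      obs <- c(rbind(a1[, j], a2[, j]))  # sample order, both copies
      obs <- obs[obs != "0"]
      uniq <- unique(obs)
      if (length(uniq) > 2) {
        stop("more than two alleles observed for SNP ", map$snp_id[j], ": ",
             paste(uniq, collapse = ","))
      }
      allele_a[j] <- if (length(uniq) >= 1) uniq[1] else "A"
      allele_b[j] <- if (length(uniq) >= 2) uniq[2] else
        setdiff(c("A", "C", "G", "T", "N"), allele_a[j])[1]
      d <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
      d[a1[, j] == "0"] <- NA
      dos[, j] <- as.integer(d)
    }
  }
  genotype_panel(
    samples = samples,
    snps = data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                      position = as.integer(map$position),
                      allele_a = allele_a, allele_b = allele_b,
                      stringsAsFactors = FALSE),
    dosages = dos
  )
}

#' Write a genotype panel as PLINK text (PED/MAP)
#'
#' Round-trip contract: `read_plink_text()` on the written files reproduces
#' the genotypes, sample order and SNP order exactly. Dosages reproduce
#' exactly whenever the first non-missing call of a SNP has dosage 0 or 1;
#' because PED stores only allele letters, a column whose first non-missing
#' call is homozygous for allele_b reads back with the allele labels
#' swapped and dosages flipped to `2 - d` (the counting-allele polarity is
#' not representable in the format). All statistics in this package are
#' invariant to that flip. Missing calls are written as `0 0`.
#'
#' @param panel a [genotype_panel()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, `NULL`.
#' @export
write_plink_text <- function(panel, ped_path, map_path) {
  validate_panel(panel)
  map <- data.frame(panel$snps$chromosome, panel$snps$snp_id,
                    rep(0L, n_snps(panel)), panel$snps$position)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- n_samples(panel); m <- n_snps(panel)
  geno <- character(n)
  if (m > 0) {
    a <- matrix(rep(panel$snps$allele_a, each = n), n, m)
    b <- matrix(rep(panel$snps$allele_b, each = n), n, m)
    # d=0 -> "a a", d=1 -> "a b" (allele_a first), d=2 -> "b b"
    c1 <- ifelse(is.na(panel$dosages), "0", ifelse(panel$dosages == 2, b, a))
    c2 <- ifelse(is.na(panel$dosages), "0", ifelse(panel$dosages >= 1, b, a))
    inter <- matrix(paste(c1, c2), n, m)
    geno <- apply(inter, 1, paste, collapse = " ")
  }
  lead <- paste(panel$samples, panel$samples, 0, 0, 0, -9)
  lines <- if (m > 0) paste(lead, geno) else lead
  writeLines(lines, ped_path)
  invisible(NULL)
}

#' Read a sample-to-population-to-category mapping table
#'
#' Expects a tab-separated file with header columns `sample`, `population`
#' and `category`. Every sample of `panel` must be assigned; a population
#' listed under two categories is an error.
#'
#' @param path path to the TSV file.
#' @param panel a [genotype_panel()] whose samples must all be covered.
#' @return A [population_map()] in the file's row order.
#' @export
read_population_map <- function(path, panel = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample", "population", "category")
  if (!all(need %in% names(tab))) {
    stop("population map must have columns sample, population, category; got: ",
         paste(names(tab), collapse = ", "))
  }
  pm <- population_map(tab$sample, tab$population, tab$category)
  if (!is.null(panel)) match_population_map(pm, panel)
  pm
}

#' Write a population map as TSV
#' @param pops a [population_map()].
#' @param path output path.
#' @return Invisibly, `NULL`.
#' @export
write_population_map <- function(pops, path) {
  utils::write.table(pops, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(NULL)
}
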