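#' Build a pipeline run configuration
#'
#' Exactly one of a genotype input (`ped`/`map` or `vcf`, plus `pop_map`)
#' or a `simulate` block (arguments for [sim_config()]) must be given.
#' All stage parameters default to the standard analysis settings:
#' autosomes "1".."28", animal call rate >= 0.95, SNP call rate >= 0.99,
#' LD pruning "50 5 0.2", Reynolds theta distances, Patterson-normalized
#' PCA. A single root `seed` fans out deterministically to the per-stage
#' seeds.
#'
#' @param ped,map,vcf,pop_map input file paths (PED/MAP or VCF, plus the
#'   sample-population-category TSV).
#' @param simulate named list of [sim_config()] arguments.
#' @param out_dir output directory, created if needed.
#' @param autosomes chromosome labels retained by QC.
#' @param min_sample_cr,min_snp_cr call-rate thresholds.
#' @param window_size,window_shift,r2_threshold LD-pruning parameters.
#' @param distance_transform `"theta"` or `"log"` (`-ln(1 - theta)`).
#' @param pca_components,pca_normalization PCA settings.
#' @param admixture_k integer vector of K values (`NULL` skips admixture).
#' @param cv_folds,cv_mask_fraction cross-validation settings.
#' @param run_pca logical; the PCA stage may be disabled, QC never.
#' @param seed root seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ped = NULL, map = NULL, vcf = NULL, pop_map = NULL,
                       simulate = NULL, out_dir = "snpdiv_run",
                       autosomes = autosomes_default(),
                       min_sample_cr = 0.95, min_snp_cr = 0.99,
                       window_size = 50, window_shift = 5, r2_threshold = 0.2,
                       distance_transform = "theta",
                       pca_components = 10, pca_normalization = "patterson",
                       admixture_k = 2:5, cv_folds = 5, cv_mask_fraction = 0.1,
                       run_pca = TRUE, seed = 1) {
  has_files <- !is.null(vcf) || (!is.null(ped) && !is.null(map))
  if (has_files && !is.null(simulate)) {
    stop("give either input file paths or a simulate block, not both")
  }
  if (!has_files && is.null(simulate)) {
    stop("one of input file paths or a simulate block is required")
  }
  if (has_files && is.null(pop_map)) stop("pop_map path is required with file input")
  stopifnot(min_sample_cr > 0, min_sample_cr <= 1,
            min_snp_cr > 0, min_snp_cr <= 1)
  structure(list(ped = ped, map = map, vcf = vcf, pop_map = pop_map,
                 simulate = simulate, out_dir = out_dir,
                 autosomes = as.character(autosomes),
                 min_sample_cr = min_sample_cr, min_snp_cr = min_snp_cr,
                 window_size = window_size, window_shift = window_shift,
                 r2_threshold = r2_threshold,
                 distance_transform = distance_transform,
                 pca_components = pca_components,
                 pca_normalization = pca_normalization,
                 admixture_k = admixture_k, cv_folds = cv_folds,
                 cv_mask_fraction = cv_mask_fraction,
                 run_pca = run_pca, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# deterministic per-stage seeds fanned out from the root seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, impute = 211L, admixture = 307L, cv = 401L)
  (seed * 1009L + offsets[[stage]]) %% 2147483647L
}

fmt_num <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)

write_tsv_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stage order is fixed: QC cascade (duplicates, chromosomes, call rates,
#' LD pruning), within-population imputation, diversity tables, Reynolds
#' distance matrix and NJ tree, PCA with population means, admixture fits
#' with cross-validated K selection. All artifacts are written under
#' `config$out_dir`; runs with identical config and seed produce
#' byte-identical outputs.
#'
#' Artifacts: `qc_report.txt`, `diversity_populations.tsv`,
#' `diversity_categories.tsv`, `reynolds.tsv`, `reynolds.phy`,
#' `nj_tree.nwk`, `pca_scores.tsv`, `pca_pop_means.tsv`,
#' `admixture_K<k>.Q`, `admixture_K<k>.P`, `admixture_cv.tsv`, `run_log.txt`
#' (and, for simulated input, `panel.ped`/`panel.map`/`populations.tsv`).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`panel`, `report`,
#'   `diversity`, `distances`, `tree`, `pca`, `admixture`, `cv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("snpdiv_version=", as.character(utils::packageVersion("snpdiv"))),
                 paste0("seed=", config$seed))
  logf <- function(...) log_lines <<- c(log_lines, paste0(...))

  # --- input ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_panel(do.call(sim_config, sim_args))
    panel <- sim$panel; pops <- sim$pops
    write_plink_text(panel, file.path(config$out_dir, "panel.ped"),
                     file.path(config$out_dir, "panel.map"))
    write_population_map(pops, file.path(config$out_dir, "populations.tsv"))
    logf("input=simulated n_samples=", n_samples(panel),
         " n_snps=", n_snps(panel))
  } else {
    panel <- if (!is.null(config$vcf)) read_vcf(config$vcf)
             else read_plink_text(config$ped, config$map)
    pops <- read_population_map(config$pop_map, panel)
    logf("input=files n_samples=", n_samples(panel), " n_snps=", n_snps(panel))
  }

  # --- QC + imputation ----------------------------------------------
  qc <- qc_pipeline(panel, pops, autosomes = config$autosomes,
                    min_sample_cr = config$min_sample_cr,
                    min_snp_cr = config$min_snp_cr,
                    window_size = config$window_size,
                    window_shift = config$window_shift,
                    r2_threshold = config$r2_threshold,
                    impute = TRUE, seed = stage_seed(config$seed, "impute"))
  panel_qc <- qc$panel
  write_qc_report(qc$report, file.path(config$out_dir, "qc_report.txt"))
  for (k in names(qc$report)) logf("qc.", k, "=", qc$report[[k]])
  pops_qc <- pops[pops$sample %in% panel_qc$samples, , drop = FALSE]
  class(pops_qc) <- c("population_map", "data.frame")

  # --- diversity -----------------------------------------------------
  div <- diversity_table(panel_qc, pops_qc)
  cs <- category_summary(div)
  write_tsv_det(div, file.path(config$out_dir, "diversity_populations.tsv"))
  write_tsv_det(cs, file.path(config$out_dir, "diversity_categories.tsv"))
  logf("diversity.overall_mean_ho=", fmt_num(attr(cs, "overall_mean_ho")))

  # --- distances + tree ---------------------------------------------
  freqs <- allele_frequencies(panel_qc, pops_qc)
  n_per_pop <- table(pops_qc$population[match(panel_qc$samples, pops_qc$sample)])
  dist_ok <- nrow(freqs$freq) >= 2 && all(n_per_pop >= 2)
  dm <- NULL; tree <- NULL
  if (dist_ok) {
    dm <- reynolds_matrix(freqs, stats::setNames(as.integer(n_per_pop),
                                                 names(n_per_pop)),
                          transform = config$distance_transform)
    write_distance_matrix(dm, file.path(config$out_dir, "reynolds.tsv"),
                          file.path(config$out_dir, "reynolds.phy"))
    tree <- neighbor_joining(dm)
    write_newick(tree, file.path(config$out_dir, "nj_tree.nwk"))
    logf("distance.n_populations=", nrow(dm))
  } else {
    logf("distance.skipped=insufficient populations or samples")
  }

  # --- PCA -----------------------------------------------------------
  pca <- NULL
  if (isTRUE(config$run_pca)) {
    pca <- pca_panel(panel_qc, n_components = config$pca_components,
                     normalization = config$pca_normalization)
    pca <- population_mean_scores(pca, pops_qc)
    sc <- data.frame(sample = rownames(pca$scores), pca$scores,
                     check.names = FALSE)
    write_tsv_det(sc, file.path(config$out_dir, "pca_scores.tsv"))
    pm <- data.frame(population = rownames(pca$pop_mean_scores),
                     pca$pop_mean_scores, check.names = FALSE)
    write_tsv_det(pm, file.path(config$out_dir, "pca_pop_means.tsv"))
    logf("pca.explained_pc1=", fmt_num(pca$explained[1]))
  }

  # --- admixture -----------------------------------------------------
  fits <- NULL; cv <- NULL
  if (!is.null(config$admixture_k) && length(config$admixture_k) > 0) {
    fits <- lapply(config$admixture_k, function(k) {
      fit <- admixture_fit(panel_qc, k,
                           seed = stage_seed(config$seed, "admixture") + k)
      utils::write.table(format(fit$q_matrix, digits = 6, trim = TRUE),
                  file.path(config$out_dir, sprintf("admixture_K%d.Q", k)),
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
      utils::write.table(format(t(fit$f_matrix), digits = 6, trim = TRUE),
                  file.path(config$out_dir, sprintf("admixture_K%d.P", k)),
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
      logf("admixture.K", k, ".loglik=", fmt_num(fit$loglik))
      fit
    })
    if (length(config$admixture_k) > 1) {
      cv <- admixture_cv(panel_qc, config$admixture_k,
                         mask_fraction = config$cv_mask_fraction,
                         n_folds = config$cv_folds,
                         seed = stage_seed(config$seed, "cv"))
      write_tsv_det(cv$cv_table, file.path(config$out_dir, "admixture_cv.tsv"))
      logf("admixture.best_k=", cv$best_k)
    }
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(panel = panel_qc, report = qc$report, diversity = div,
                 category_summary = cs, distances = dm, tree = tree,
                 pca = pca, admixture = fits, cv = cv))
}
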