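#' Principal component analysis of a genotype panel
#'
#' Columns are centered at the mean dosage `2 p̂` and, with the default
#' Patterson normalization, scaled by `sqrt(2 p̂ (1 - p̂))` where `p̂` is
#' the sample allele frequency; monomorphic columns are dropped. Scores are
#' the projections on the eigenvectors of the individual covariance;
#' `explained` is each component's fraction of total variance. The sign of
#' each component is fixed so that its largest-magnitude SNP loading is
#' positive.
#'
#' @param panel an imputed [genotype_panel()] (no missing calls).
#' @param n_components number of components to keep (default 10, capped at
#'   the available rank).
#' @param normalization `"patterson"` (default) or `"center"`.
#' @return A list of class `pca_result` with `scores` (individual x
#'   component, rownames = samples), `explained`, `loadings`, and
#'   `pop_mean_scores` (`NULL` until [population_mean_scores()]).
#' @export
pca_panel <- function(panel, n_components = 10,
                      normalization = c("patterson", "center")) {
  normalization <- match.arg(normalization)
  if (anyNA(panel$dosages)) {
    stop("panel contains missing calls; run impute_missing() first")
  }
  g <- panel$dosages
  storage.mode(g) <- "double"
  p_hat <- colMeans(g) / 2
  poly <- p_hat > 0 & p_hat < 1
  if (!any(poly)) stop("no polymorphic SNPs")
  g <- g[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  x <- sweep(g, 2, 2 * p_hat)
  if (normalization == "patterson") {
    x <- sweep(x, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  }
  sv <- svd(x)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  k <- min(n_components, rank)
  if (k < 1) stop("no polymorphic SNPs")
  ev <- sv$d^2
  explained <- ev[seq_len(k)] / sum(ev)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| positive per component
  for (c in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, c])), c])
    if (s < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  dimnames(scores) <- list(panel$samples, paste0("PC", seq_len(k)))
  structure(list(scores = scores, explained = explained,
                 loadings = loadings, pop_mean_scores = NULL),
            class = "pca_result")
}

#' Population-averaged principal component scores
#'
#' Arithmetic mean of the member individuals' scores for every population,
#' all components. Used to display many populations on one PCA plot
#' without drawing thousands of individual points.
#'
#' @param result a `pca_result` from [pca_panel()].
#' @param pops a [population_map()] covering the scored samples.
#' @return The `pca_result` with `pop_mean_scores` filled in (population x
#'   component matrix).
#' @export
population_mean_scores <- function(result, pops) {
  sc <- result$scores
  idx <- match(rownames(sc), pops$sample)
  if (anyNA(idx)) {
    stop("scored samples absent from population map: ",
         paste(rownames(sc)[is.na(idx)], collapse = ", "))
  }
  pop <- pops$population[idx]
  pop_levels <- unique(pop)
  means <- rowsum(sc, factor(pop, pop_levels)) /
    as.vector(table(factor(pop, pop_levels)))
  rownames(means) <- pop_levels
  result$pop_mean_scores <- means
  result
}

#' Log-likelihood of the admixture model
#'
#' Binomial likelihood of allele-b dosages given ancestry-weighted
#' frequencies `h_ij = sum_k q_ik f_kj`:
#' `sum_ij [ g_ij log h_ij + (2 - g_ij) log(1 - h_ij) ]`, with h clipped to
#' `[1e-10, 1 - 1e-10]`. Missing cells (NA) are skipped.
#'
#' @param panel a [genotype_panel()].
#' @param q_matrix individual x K ancestry proportions.
#' @param f_matrix K x SNP ancestral allele-b frequencies.
#' @return The log-likelihood (a scalar).
#' @export
admixture_loglik <- function(panel, q_matrix, f_matrix) {
  g <- panel$dosages
  storage.mode(g) <- "double"
  q_matrix <- as.matrix(q_matrix); f_matrix <- as.matrix(f_matrix)
  if (nrow(q_matrix) != nrow(g) || ncol(f_matrix) != ncol(g) ||
      ncol(q_matrix) != nrow(f_matrix)) {
    stop("dimension mismatch between panel, Q and F")
  }
  h <- q_matrix %*% f_matrix
  h <- pmin(pmax(h, 1e-10), 1 - 1e-10)
  ll <- g * log(h) + (2 - g) * log(1 - h)
  sum(ll[!is.na(g)])
}

# one EM pass; W = 0/1 observed-cell weight matrix; returns updated q, f
admixture_em_step <- function(g, w, q, f) {
  K <- ncol(q)
  h <- q %*% f
  h <- pmin(pmax(h, 1e-10), 1 - 1e-10)
  gb <- g * w          # observed allele-b copies
  ga <- (2 - g) * w    # observed allele-a copies
  rb <- gb / h         # shared factors of the responsibilities
  ra <- ga / (1 - h)
  q_new <- matrix(0, nrow(q), K)
  f_num <- matrix(0, K, ncol(f))
  f_den <- matrix(0, K, ncol(f))
  for (k in seq_len(K)) {
    u <- rb * tcrossprod(q[, k], f[k, ])        # E[#b copies from k]
    v <- ra * tcrossprod(q[, k], 1 - f[k, ])    # E[#a copies from k]
    q_new[, k] <- rowSums(u) + rowSums(v)
    f_num[k, ] <- colSums(u)
    f_den[k, ] <- colSums(u) + colSums(v)
  }
  rs <- rowSums(q_new)
  bad <- rs <= 0          # individual with no observed cell: keep uniform q
  rs[bad] <- 1
  q_new <- q_new / rs
  q_new[bad, ] <- 1 / K
  # exact M-step (no clipping) keeps the EM monotonicity guarantee;
  # the likelihood itself clips h away from 0/1
  f_new <- ifelse(f_den > 0, f_num / f_den, f)
  list(q = q_new, f = f_new)
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of ancestry proportions Q (individual x K,
#' rows summing to 1) and ancestral allele frequencies F (K x SNP) under
#' the binomial admixture model, by expectation-maximization:
#' responsibilities per allele copy are proportional to `q_ik f_kj` (and
#' `q_ik (1 - f_kj)` for the reference allele); the M-step renormalizes the
#' expected copy counts. Q starts from a seeded flat Dirichlet and F from
#' perturbed panel frequencies. The log-likelihood is non-decreasing at
#' every iteration; iteration stops when the relative change drops below
#' `tol` or at `max_iter`. Cells marked missing are skipped, which is also
#' how cross-validation holds cells out.
#'
#' @param panel a [genotype_panel()]; for a standard fit it should be
#'   imputed, but NA cells are tolerated and simply ignored.
#' @param k number of ancestral clusters (>= 1).
#' @param seed integer seed for the initialization.
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 2000).
#' @return A list of class `admixture_fit` with `k`, `q_matrix`,
#'   `f_matrix`, `loglik`, `loglik_trace`, `n_iter`, `seed`, `converged`.
#' @export
admixture_fit <- function(panel, k, seed = 1, tol = 1e-6, max_iter = 2000) {
  g <- panel$dosages
  storage.mode(g) <- "double"
  n <- nrow(g); m <- ncol(g)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of individuals (", n, ")")
  w <- (!is.na(g)) + 0
  g[is.na(g)] <- 0
  set.seed(seed)
  q <- rdirichlet(n, rep(1, k))
  p_hat <- colSums(g) / pmax(2 * colSums(w), 1)
  f <- matrix(rep(p_hat, each = k), k, m) +
    matrix(stats::runif(k * m, -0.05, 0.05), k, m)
  f <- pmin(pmax(f, 1e-3), 1 - 1e-3)
  if (k == 1) q <- matrix(1, n, 1)

  ll_of <- function(q, f) {
    h <- pmin(pmax(q %*% f, 1e-10), 1 - 1e-10)
    sum(w * (g * log(h) + (2 - g) * log(1 - h)))
  }
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    st <- admixture_em_step(g, w, q, f)
    q <- st$q; f <- st$f
    ll <- ll_of(q, f)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  structure(list(k = k, q_matrix = q, f_matrix = f,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = iter, seed = seed, converged = converged),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$k, ", loglik =", format(x$loglik),
      ",", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

#' Cross-validated selection of the number of ancestral clusters
#'
#' For each fold, a disjoint random `mask_fraction` of observed cells is
#' hidden; the model is fitted on the remaining cells (EM skips hidden
#' cells) and the hidden dosages are predicted as `2 h_ij`. The CV error of
#' a K is the mean squared error on hidden cells averaged over folds; the
#' reported best K minimizes it. A mask that would leave some SNP with no
#' observation is redrawn (up to 20 attempts).
#'
#' @param panel an imputed [genotype_panel()].
#' @param k_values integer vector of K values to score.
#' @param mask_fraction fraction of cells hidden per fold (default 0.1).
#' @param n_folds number of folds with disjoint masks (default 5);
#'   `n_folds * mask_fraction` must be <= 1.
#' @param seed integer seed (controls masks and EM starts).
#' @param tol,max_iter EM settings for the fold fits (defaults 1e-5, 500 —
#'   looser than [admixture_fit()] since only the ranking of K is used).
#' @return A list with `cv_table` (data frame K, cv_error), `best_k`, and
#'   `fold_errors` (K x fold matrix).
#' @export
admixture_cv <- function(panel, k_values, mask_fraction = 0.1, n_folds = 5,
                         seed = 1, tol = 1e-5, max_iter = 500) {
  if (anyNA(panel$dosages)) {
    stop("panel contains missing calls; run impute_missing() first")
  }
  if (mask_fraction <= 0 || mask_fraction * n_folds > 1) {
    stop("need 0 < mask_fraction and mask_fraction * n_folds <= 1")
  }
  g <- panel$dosages
  storage.mode(g) <- "double"
  n_cells <- length(g)
  per_fold <- round(mask_fraction * n_cells)
  set.seed(seed)
  masks <- NULL
  for (attempt in 1:20) {
    perm <- sample.int(n_cells)
    cand <- lapply(seq_len(n_folds), function(fold) {
      perm[((fold - 1) * per_fold + 1):(fold * per_fold)]
    })
    ok <- all(vapply(cand, function(hide) {
      wm <- matrix(TRUE, nrow(g), ncol(g)); wm[hide] <- FALSE
      all(colSums(wm) > 0)
    }, logical(1)))
    if (ok) { masks <- cand; break }
  }
  if (is.null(masks)) stop("could not draw masks leaving every SNP observed")
  fold_errors <- matrix(NA_real_, length(k_values), n_folds,
                        dimnames = list(paste0("K", k_values), NULL))
  for (ki in seq_along(k_values)) {
    k <- k_values[ki]
    for (fold in seq_len(n_folds)) {
      hide <- masks[[fold]]
      dos <- panel$dosages
      dos[hide] <- NA_integer_
      masked <- genotype_panel(panel$samples, panel$snps, dos)
      fit <- admixture_fit(masked, k, seed = seed + 1000L * fold + k,
                           tol = tol, max_iter = max_iter)
      h <- fit$q_matrix %*% fit$f_matrix
      pred <- 2 * h[hide]
      fold_errors[ki, fold] <- mean((g[hide] - pred)^2)
    }
  }
  cv_error <- rowMeans(fold_errors)
  cv_table <- data.frame(k = k_values, cv_error = unname(cv_error))
  list(cv_table = cv_table, best_k = k_values[which.min(cv_error)],
       fold_errors = fold_errors)
}

#' Match fitted admixture components to reference components
#'
#' Greedy assignment of fitted components to reference components by
#' maximal correlation of the Q columns — the usual label-switching fix
#' applied at evaluation time only, never inside the fit.
#'
#' @param q_fit,q_ref individual x K matrices with equal dimensions.
#' @return `q_fit` with columns permuted to best match `q_ref`.
#' @export
match_components <- function(q_fit, q_ref) {
  K <- ncol(q_ref)
  if (ncol(q_fit) != K) stop("component counts differ")
  cc <- suppressWarnings(stats::cor(q_fit, q_ref))
  cc[!is.finite(cc)] <- -Inf
  perm <- integer(K)
  used <- rep(FALSE, K)
  for (step in seq_len(K)) {
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    perm[best[2]] <- best[1]
    cc[best[1], ] <- -Inf
    cc[, best[2]] <- -Inf
  }
  q_fit[, perm, drop = FALSE]
}
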