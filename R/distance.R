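#' Reynolds coancestry estimate between two populations
#'
#' Least-squares estimator of the coancestry coefficient theta from allele
#' frequencies and diploid sample counts. Per biallelic locus with
#' frequencies p1, p2 (of the same allele) and heterozygosities
#' `alpha_i = 2 p_i (1 - p_i)`:
#' \deqn{num_l = (p_1-p_2)^2 - \frac{(n_1+n_2)(n_1\alpha_1+n_2\alpha_2)}
#'   {4 n_1 n_2 (n_1+n_2-1)}}
#' \deqn{den_l = (p_1-p_2)^2 + \frac{(4 n_1 n_2-n_1-n_2)(n_1\alpha_1+n_2\alpha_2)}
#'   {4 n_1 n_2 (n_1+n_2-1)}}
#' and `theta = sum(num) / sum(den)` over loci (ratio of sums, not mean of
#' ratios), clamped to \[0, 1\]. Loci where either frequency is undefined
#' are skipped. With `correct = FALSE` the finite-sample correction terms
#' are dropped (frequency-only simplification).
#'
#' @param freq1,freq2 per-SNP allele frequencies of the two populations
#'   (`NA` = undefined).
#' @param n1,n2 diploid sample counts (>= 2).
#' @param correct apply the sample-size correction terms (default TRUE).
#' @return A list with `theta`, `num_sum`, `den_sum`, `n_loci`.
#' @export
reynolds_pair <- function(freq1, freq2, n1, n2, correct = TRUE) {
  if (length(freq1) != length(freq2)) stop("frequency vectors differ in length")
  if (n1 < 2 || n2 < 2) stop("need at least 2 diploid samples per population")
  ok <- !is.na(freq1) & !is.na(freq2)
  if (!any(ok)) stop("no shared loci with defined frequencies")
  p1 <- freq1[ok]; p2 <- freq2[ok]
  a <- (p1 - p2)^2
  al1 <- 2 * p1 * (1 - p1)
  al2 <- 2 * p2 * (1 - p2)
  if (correct) {
    denom <- 4 * n1 * n2 * (n1 + n2 - 1)
    shared <- (n1 * al1 + n2 * al2)
    num <- a - (n1 + n2) * shared / denom
    den <- a + (4 * n1 * n2 - n1 - n2) * shared / denom
  } else {
    num <- a
    den <- a + (al1 + al2) / 2
  }
  num_sum <- sum(num); den_sum <- sum(den)
  theta <- if (den_sum > 0) num_sum / den_sum else 0
  theta <- min(max(theta, 0), 1)
  list(theta = theta, num_sum = num_sum, den_sum = den_sum, n_loci = sum(ok))
}

#' Pairwise Reynolds distance matrix between populations
#'
#' Applies [reynolds_pair()] to every population pair of an
#' [allele_frequencies()] table. The distance is theta itself by default;
#' `transform = "log"` gives `-ln(1 - theta)` (both are monotone, so NJ
#' topologies agree for small theta).
#'
#' @param freqs output of [allele_frequencies()].
#' @param n_samples named vector of diploid sample counts per population
#'   (names matching the frequency table rows).
#' @param transform `"theta"` (default) or `"log"`.
#' @param correct apply sample-size corrections (default TRUE).
#' @return Symmetric matrix with zero diagonal, dimnames = population
#'   labels.
#' @export
reynolds_matrix <- function(freqs, n_samples, transform = c("theta", "log"),
                            correct = TRUE) {
  transform <- match.arg(transform)
  labs <- rownames(freqs$freq)
  if (length(labs) < 2) stop("need at least two populations")
  if (!all(labs %in% names(n_samples))) {
    stop("sample counts missing for: ",
         paste(setdiff(labs, names(n_samples)), collapse = ", "))
  }
  P <- length(labs)
  d <- matrix(0, P, P, dimnames = list(labs, labs))
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      th <- reynolds_pair(freqs$freq[i, ], freqs$freq[j, ],
                          n_samples[[labs[i]]], n_samples[[labs[j]]],
                          correct = correct)$theta
      d[i, j] <- d[j, i] <- if (transform == "log") -log(1 - min(th, 1 - 1e-12)) else th
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical (unweighted) Saitou-Nei neighbor joining: iteratively join the
#' pair minimizing `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` where `R_i` is the
#' row sum over active clusters; limb lengths follow the standard formulas
#' and negative lengths are clamped to zero. Ties in Q are broken by the
#' lexicographically smallest label pair (a cluster is keyed by its
#' smallest leaf label), making the output deterministic. Two taxa yield a
#' single edge; three or more yield the usual unrooted topology with one
#' trifurcating root node.
#'
#' @param d symmetric distance matrix with zero diagonal, finite entries
#'   and dimnames (population labels).
#' @return An [ape::read.tree()]-compatible `phylo` object.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  if (is.null(labs)) labs <- colnames(d)
  if (is.null(labs)) stop("distance matrix must have dimnames")
  n <- nrow(d)
  if (n < 2) stop("need at least two taxa")
  if (!all(is.finite(d))) stop("distance matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  dimnames(d) <- list(labs, labs)

  if (n == 2) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }

  # active clusters: node id (tips 1..n, internals n+1...), sort key =
  # smallest leaf label in the cluster
  node_id <- seq_len(n)
  key <- labs
  D <- d
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  next_node <- n + 1L
  r <- n
  while (r > 3) {
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    # order candidate pairs by sorted label pair, lexicographically
    pk <- apply(cand, 1, function(ij) {
      kk <- sort(c(key[ij[1]], key[ij[2]]))
      paste(kk[1], kk[2], sep = "\r")
    })
    best <- cand[order(pk)[1], ]
    i <- min(best); j <- max(best)
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    edges <- rbind(edges, c(next_node, node_id[i]), c(next_node, node_id[j]))
    lens <- c(lens, li, lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node_id <- c(node_id[keep], next_node)
    key <- c(key[keep], min(key[c(i, j)]))
    next_node <- next_node + 1L
    r <- r - 1
  }
  # final trifurcation: limbs from the three pairwise equations
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(edges, c(next_node, node_id[1]), c(next_node, node_id[2]),
                 c(next_node, node_id[3]))
  lens <- c(lens, max(la, 0), max(lb, 0), max(lc, 0))
  root <- next_node

  # renumber internals so the root is n+1 (ape convention)
  n_internal <- root - n
  new_id <- integer(root)
  new_id[seq_len(n)] <- seq_len(n)
  ord <- c(root, setdiff((n + 1L):root, root))
  new_id[ord] <- n + seq_len(n_internal)
  edge <- cbind(new_id[edges[, 1]], new_id[edges[, 2]])
  tr <- list(edge = edge, edge.length = lens, tip.label = labs,
             Nnode = n_internal)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

needs_quoting <- function(x) grepl("[][(){}:;,' \t\n]", x)

quote_label <- function(x) {
  ifelse(needs_quoting(x),
         paste0("'", gsub("'", "''", x), "'"),
         x)
}

#' Serialize a phylo tree to a Newick string
#'
#' Branch lengths are written with 15 significant digits; labels containing
#' Newick metacharacters (whitespace, parentheses, colon, semicolon, comma,
#' quotes, brackets) are single-quoted with internal quotes doubled.
#'
#' @param tree a `phylo` object.
#' @return Newick string ending in ";".
#' @export
newick_string <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node, incoming) {
    if (node <= n) {
      lab <- quote_label(tree$tip.label[node])
    } else {
      kid_edges <- children[[as.character(node)]]
      parts <- vapply(kid_edges, function(e) {
        rec(tree$edge[e, 2], tree$edge.length[e])
      }, character(1))
      lab <- paste0("(", paste(parts, collapse = ","), ")")
    }
    if (is.na(incoming)) lab else paste0(lab, ":", format(incoming, digits = 15))
  }
  root <- n + 1L
  paste0(rec(root, NA_real_), ";")
}

#' Write a tree to a Newick file
#' @param tree a `phylo` object.
#' @param path output path.
#' @return Invisibly, `NULL`.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(NULL)
}

#' Write a distance matrix as labeled TSV and/or PHYLIP square format
#' @param d symmetric labeled matrix.
#' @param tsv_path,phylip_path output paths (either may be `NULL`).
#' @return Invisibly, `NULL`.
#' @export
write_distance_matrix <- function(d, tsv_path = NULL, phylip_path = NULL) {
  if (!is.null(tsv_path)) {
    tab <- data.frame(population = rownames(d),
                      format(d, digits = 10, trim = TRUE),
                      check.names = FALSE)
    utils::write.table(tab, tsv_path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  if (!is.null(phylip_path)) {
    lines <- c(format(nrow(d)),
               paste(formatC(rownames(d), width = -10),
                     apply(format(d, digits = 10, trim = TRUE), 1, paste,
                           collapse = " ")))
    writeLines(lines, phylip_path)
  }
  invisible(NULL)
}
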