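#' Biweight midcorrelation matrix
#'
#' Robust correlation between all gene pairs: values are centred on the
#' median, scaled by the median absolute deviation, downweighted by Tukey
#' bisquare weights (tuning constant 9, so observations beyond 9 MADs get
#' zero weight), and the weighted vectors are correlated. Outlier samples
#' therefore barely perturb the estimate, unlike Pearson correlation. Genes
#' whose MAD is zero cannot be scaled robustly; they fall back to Pearson
#' standardization for their pairs (a warning reports how many).
#'
#' @param data An [expression_dataset()] (log scale expected).
#' @param samples Optional sample ids (or index) restricting the computation
#'   to one condition's samples; default all samples.
#' @return Symmetric genes x genes correlation matrix in [-1, 1] with unit
#'   diagonal.
#' @export
bicor_matrix <- function(data, samples = NULL) {
  x <- data$values
  if (!is.null(samples)) x <- x[, samples, drop = FALSE]
  if (ncol(x) < 4) stop("bicor needs at least 4 samples")
  if (anyNA(x)) stop("missing expression values are not supported")
  z <- bicor_standardize(x)
  cc <- tcrossprod(z)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- 1
  cc
}

# Rows standardized so that tcrossprod() yields bicor (or Pearson for
# MAD-zero rows): weighted, centred, unit-norm vectors.
bicor_standardize <- function(x) {
  med <- apply(x, 1, stats::median)
  mad_ <- apply(x, 1, stats::mad, constant = 1)
  bad <- mad_ == 0
  if (any(bad))
    warning(sum(bad), " gene(s) with zero MAD fall back to Pearson ",
            "standardization")
  z <- x - med
  u <- z / (9 * mad_)
  u[bad, ] <- 0  # weight 1 everywhere; handled as Pearson below
  w <- (1 - u^2)^2 * (abs(u) < 1)
  z <- z * w
  if (any(bad)) {
    xb <- x[bad, , drop = FALSE]
    z[bad, ] <- xb - rowMeans(xb)
  }
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0))
    stop("gene '", rownames(x)[which(nrm == 0)[1]],
         "' has zero dispersion; remove constant genes first")
  z / nrm
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned weighted-network adjacency a_ij = |cor_ij|^beta with unit
#' diagonal. Raising to beta suppresses weak correlations continuously
#' instead of hard-thresholding them.
#'
#' @param cor_mat Symmetric correlation matrix.
#' @param beta Positive soft-threshold exponent.
#' @param condition_label Label stored on the network (for reporting).
#' @return A `weighted_network`: list with `gene_ids`, `adjacency`, `beta`,
#'   `tom` (NULL until [tom_similarity()] runs) and `condition_label`.
#' @export
adjacency_from_cor <- function(cor_mat, beta, condition_label = "") {
  if (beta <= 0) stop("`beta` must be positive")
  adj <- abs(cor_mat)^beta
  diag(adj) <- 1
  structure(list(gene_ids = rownames(cor_mat), adjacency = adj,
                 beta = beta, tom = NULL, condition_label = condition_label),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted_network", if (nzchar(x$condition_label))
    paste0("(", x$condition_label, ")") else "", ":",
    length(x$gene_ids), "genes, beta =", x$beta,
    if (!is.null(x$tom)) ", TOM computed" else "", "\n")
  invisible(x)
}

#' Whole-network connectivity
#'
#' @param net A `weighted_network`.
#' @return Named vector k_i = sum of a gene's adjacencies to all other genes.
#' @export
connectivity <- function(net) {
  stats::setNames(rowSums(net$adjacency) - 1, net$gene_ids)
}

#' Scale-free fit index of a connectivity distribution
#'
#' Bins connectivity into 10 equal-width bins (empty bins dropped) and
#' regresses log10(bin frequency) on log10(mean bin connectivity). Returns
#' the signed R^2: positive only when the slope is negative, i.e. when high
#' connectivity is rarer than low connectivity, as in a scale-free degree
#' distribution.
#'
#' @param k Numeric vector of connectivities.
#' @param n_bins Number of bins (default 10).
#' @return List with `r_squared` (signed), `slope`, and the `fit_table` of
#'   bin means and frequencies.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (all(k == 0)) stop("degenerate all-zero connectivity")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  ok <- !is.na(dk) & dk > 0
  dk <- dk[ok]; freq <- freq[ok]
  if (length(dk) < 2)
    return(list(r_squared = 0, slope = NA_real_,
                fit_table = data.frame(mean_k = dk, freq = freq)))
  fit <- stats::lm(log10(freq) ~ log10(dk))
  r2 <- unname(summary(fit)$r.squared)
  slope <- unname(stats::coef(fit)[2])
  list(r_squared = -sign(slope) * r2, slope = slope,
       fit_table = data.frame(mean_k = as.numeric(dk),
                              freq = as.numeric(freq)))
}

#' Choose the soft-threshold power for approximate scale-free topology
#'
#' For each candidate beta the unsigned adjacency |cor|^beta is formed, the
#' connectivity distribution is fit to a power law ([scale_free_fit()]), and
#' the smallest beta whose signed R^2 reaches `r2_target` is chosen. If no
#' candidate reaches the target, the beta with the maximal fit is returned
#' with a warning.
#'
#' @param cor_mat Symmetric correlation matrix.
#' @param candidate_betas Ascending positive candidates (default 1:20).
#' @param r2_target Required signed R^2 (default 0.80).
#' @return List with `beta` (chosen power) and `fit_table` (data.frame:
#'   beta, r_squared, slope, mean_k, median_k, max_k).
#' @export
pick_soft_threshold <- function(cor_mat, candidate_betas = 1:20,
                                r2_target = 0.80) {
  if (any(candidate_betas <= 0)) stop("candidate betas must be positive")
  if (is.unsorted(candidate_betas)) stop("candidate betas must be ascending")
  ac <- abs(cor_mat)
  diag(ac) <- 0
  rows <- lapply(candidate_betas, function(b) {
    k <- rowSums(ac^b)
    sf <- scale_free_fit(k)
    data.frame(beta = b, r_squared = sf$r_squared, slope = sf$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  qualifying <- which(tab$r_squared >= r2_target)
  if (length(qualifying) > 0) {
    beta <- tab$beta[qualifying[1]]
  } else {
    warning("no candidate beta reached R^2 >= ", r2_target,
            "; using the best fit (beta = ",
            tab$beta[which.max(tab$r_squared)], ")")
    beta <- tab$beta[which.max(tab$r_squared)]
  }
  list(beta = beta, fit_table = tab)
}

#' Restrict a network to its most connected genes
#'
#' Ranks genes by whole-network connectivity and keeps the top fraction,
#' re-slicing (not recomputing) the adjacency. Ties at the cutoff are broken
#' by gene id, lexicographically, so the result is deterministic.
#'
#' @param net A `weighted_network`.
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @param min_genes Minimum allowed size of the retained universe.
#' @return The filtered `weighted_network` (TOM, if any, is discarded).
#' @export
filter_top_connectivity <- function(net, fraction = 0.5, min_genes = 30) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  k <- connectivity(net)
  n_keep <- ceiling(fraction * length(k))
  if (n_keep < min_genes)
    stop("connectivity filter would retain ", n_keep,
         " genes, fewer than min_genes = ", min_genes)
  ord <- order(-k, net$gene_ids)
  keep <- sort(ord[seq_len(n_keep)])
  structure(list(gene_ids = net$gene_ids[keep],
                 adjacency = net$adjacency[keep, keep, drop = FALSE],
                 beta = net$beta, tom = NULL,
                 condition_label = net$condition_label),
            class = "weighted_network")
}

#' Topological overlap similarity
#'
#' The unsigned TOM combines direct adjacency with shared-neighbour
#' adjacency: TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), where
#' l_ij = sum_u a_iu a_uj over u distinct from i and j and k is whole-network
#' connectivity. Two genes are topologically similar when they are strongly
#' connected to each other and to the same neighbours. The diagonal is 1.
#'
#' @param net A `weighted_network`.
#' @return The network with `$tom` filled in (symmetric, entries in [0, 1]).
#' @export
tom_similarity <- function(net) {
  a <- net$adjacency
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a            # includes no i/j terms since diag(a) = 0
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  if (any(denom < 1e-12)) stop("degenerate TOM denominator (< 1e-12)")
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  dimnames(tom) <- list(net$gene_ids, net$gene_ids)
  net$tom <- tom
  net
}

#' Write a similarity matrix as an edge list
#'
#' @param mat Symmetric matrix with gene ids as dimnames.
#' @param path Output TSV path (columns gene_a, gene_b, weight).
#' @param threshold Only pairs with weight above this are written.
#' @return Invisibly, the number of edges written.
#' @export
write_edge_list <- function(mat, path, threshold = 0.1) {
  idx <- which(upper.tri(mat) & mat > threshold, arr.ind = TRUE)
  df <- data.frame(gene_a = rownames(mat)[idx[, 1]],
                   gene_b = colnames(mat)[idx[, 2]],
                   weight = mat[idx])
  df <- df[order(-df$weight), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(df))
}
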