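#' Module partition constructor
#'
#' @param labels Named character vector gene id -> module label;
#'   `"unassigned"` is the reserved label for unclustered (gray) genes.
#' @param min_module_size,cut_height Parameters the partition was built with.
#' @return A `module_partition` with size-ranked `module_labels`.
#' @export
module_partition <- function(labels, min_module_size = 30,
                             cut_height = 0.995) {
  stopifnot(!is.null(names(labels)))
  mods <- setdiff(unique(labels), "unassigned")
  sizes <- table(factor(labels, levels = mods))
  mods <- mods[order(-as.integer(sizes), mods)]
  structure(list(label_of_gene = labels, module_labels = mods,
                 min_module_size = min_module_size, cut_height = cut_height),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  n_un <- sum(x$label_of_gene == "unassigned")
  cat("module_partition:", length(x$module_labels), "modules over",
      length(x$label_of_gene), "genes (", n_un, "unassigned )\n")
  if (length(x$module_labels) > 0) {
    sz <- module_sizes(x)
    cat("sizes:", paste(sprintf("%s=%d", names(sz), sz), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Sizes of the modules in a partition
#' @param part A `module_partition`.
#' @return Named integer vector (excludes "unassigned").
#' @export
module_sizes <- function(part) {
  vapply(part$module_labels,
         function(m) sum(part$label_of_gene == m), integer(1))
}

#' Genes belonging to one module
#' @param part A `module_partition`.
#' @param module A module label (or "unassigned").
#' @return Character vector of gene ids.
#' @export
module_genes <- function(part, module) {
  names(part$label_of_gene)[part$label_of_gene == module]
}

#' Detect modules by average-linkage clustering of the TOM dissimilarity
#'
#' Genes are clustered on 1 - TOM with average linkage and the dendrogram is
#' decomposed into branches by a dynamic tree-cut variant. A branch is
#' detached from its parent when either (a) the join to its parent lies
#' above `cut_height` (the static cut), or (b) the branch is distinctly
#' separated from its surroundings: the detachment ratio
#' (parent join height - branch top height) / (1 - branch top height)
#' exceeds `detach_ratio`. A tight branch that joins the rest of the tree
#' far above its own internal merge heights is thereby recognized as a
#' module even when the join itself sits below the static cut; a flat cut
#' alone cannot do this because between-module joins accumulate gradually
#' just under the dendrogram ceiling. Detached branches smaller than
#' `min_size` are relabelled "unassigned" (the gray pseudo-module); the rest
#' are named "M1", "M2", ... by decreasing size. Single genes are never
#' detached on their own: a gene attaching late to a module stays with it.
#'
#' @param net A `weighted_network` with `$tom` computed (see
#'   [tom_similarity()]), or a similarity matrix with gene dimnames.
#' @param min_size Minimum module size (default 30).
#' @param cut_height Static dendrogram cut height on the 1 - TOM scale
#'   (default 0.995).
#' @param detach_ratio Branch detachment threshold in (0, 1); default 0.5,
#'   i.e. a branch is a module when its parent join spans more than half of
#'   the branch's remaining dissimilarity range.
#' @return A `module_partition`.
#' @export
detect_modules <- function(net, min_size = 30, cut_height = 0.995,
                           detach_ratio = 0.5) {
  sim <- if (inherits(net, "weighted_network")) {
    if (is.null(net$tom)) stop("run tom_similarity() first")
    net$tom
  } else net
  if (min_size < 2) stop("`min_size` must be >= 2")
  genes <- rownames(sim)
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- tree_branches(hc, cut_height, detach_ratio)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_size])
  labels <- rep("unassigned", length(genes))
  names(labels) <- genes
  if (length(big) == 0) {
    warning("no cluster reached min_size = ", min_size,
            "; all genes unassigned")
    return(module_partition(labels, min_size, cut_height))
  }
  # name by decreasing size, ties by first-seen cluster id
  ord <- big[order(-as.integer(sizes[as.character(big)]), big)]
  for (i in seq_along(ord))
    labels[cl == ord[i]] <- paste0("M", i)
  module_partition(labels, min_size, cut_height)
}

# Decompose an hclust tree into branches: cut the edge above an internal
# node when the parent join is above cut_height or the detachment ratio
# exceeds the threshold; leaves always follow their parent node. Returns an
# integer cluster id per leaf, in leaf order.
tree_branches <- function(hc, cut_height, detach_ratio) {
  m <- hc$merge
  h <- hc$height
  n_nodes <- nrow(m)
  parent <- rep(NA_integer_, n_nodes)
  for (i in seq_len(n_nodes))
    for (ch in m[i, ]) if (ch > 0) parent[ch] <- i
  cut <- logical(n_nodes)
  for (i in seq_len(n_nodes)) {
    p <- parent[i]
    if (is.na(p)) next  # root
    gap_ratio <- if (h[i] >= 1) 0 else (h[p] - h[i]) / (1 - h[i])
    cut[i] <- h[p] > cut_height || gap_ratio > detach_ratio
  }
  comp <- integer(n_nodes)
  next_id <- 0L
  for (i in rev(seq_len(n_nodes))) {  # top-down: parents have larger index
    if (is.na(parent[i]) || cut[i]) {
      next_id <- next_id + 1L
      comp[i] <- next_id
    } else comp[i] <- comp[parent[i]]
  }
  leaf_comp <- integer(n_nodes + 1)
  for (i in seq_len(n_nodes))
    for (ch in m[i, ]) if (ch < 0) leaf_comp[-ch] <- comp[i]
  leaf_comp
}

# First principal component of the standardized module submatrix over the
# given samples: unit-norm, sign-aligned with the module mean profile.
eigengene_of <- function(x_std) {
  sv <- svd(x_std, nu = 0, nv = 1)
  me <- sv$v[, 1]
  mean_profile <- colMeans(x_std)
  if (sum(me * mean_profile) < 0) me <- -me
  list(me = me, variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  s[s == 0] <- 1
  (x - mu) / s
}

#' Module eigengenes for one condition
#'
#' The eigengene of a module is the first principal component of its
#' standardized gene x sample submatrix, restricted to the samples of one
#' condition: a single per-sample profile summarizing the module. Vectors
#' are unit-norm with sign fixed so the eigengene correlates nonnegatively
#' with the module's mean expression profile.
#'
#' @param data An [expression_dataset()] (log scale).
#' @param part A `module_partition`.
#' @param condition A condition label of `data`.
#' @return List: `eigengenes` (samples x modules matrix),
#'   `variance_explained` (named vector), `samples`.
#' @export
module_eigengenes <- function(data, part, condition) {
  samp <- condition_samples(data, condition)
  mods <- part$module_labels
  me <- matrix(NA_real_, length(samp), length(mods),
               dimnames = list(samp, mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    g <- intersect(module_genes(part, m), rownames(data$values))
    if (length(g) < 2) stop("module '", m, "' has fewer than 2 genes")
    xs <- standardize_rows(data$values[g, samp, drop = FALSE])
    eg <- eigengene_of(xs)
    me[, m] <- eg$me
    ve[m] <- eg$variance_explained
  }
  list(eigengenes = me, variance_explained = ve, samples = samp)
}

#' Module membership and connectivity statistics for one condition
#'
#' Computes, over one condition's samples: module eigengenes and the
#' variance they explain; kME(g, m) = Pearson correlation of gene g's
#' expression with module m's eigengene (module membership); and kIM(g) =
#' sum of g's adjacencies to the other genes of its own module (intramodular
#' connectivity) in the supplied network.
#'
#' @param data An [expression_dataset()] (log scale).
#' @param net A `weighted_network` whose adjacency supplies kIM.
#' @param part A `module_partition` over the network's genes.
#' @param condition A condition label of `data`.
#' @return A `module_statistics` list: `eigengenes`, `variance_explained`,
#'   `kme` (genes x modules), `kim` (named vector), `condition`.
#' @export
compute_module_statistics <- function(data, net, part, condition) {
  eg <- module_eigengenes(data, part, condition)
  genes <- net$gene_ids
  x <- t(data$values[genes, eg$samples, drop = FALSE])
  kme <- stats::cor(x, eg$eigengenes)
  rownames(kme) <- genes
  lab <- part$label_of_gene[genes]
  kim <- stats::setNames(numeric(length(genes)), genes)
  a <- net$adjacency
  for (m in unique(lab)) {
    in_m <- which(lab == m)
    if (length(in_m) < 2) next
    kim[in_m] <- rowSums(a[in_m, in_m, drop = FALSE]) - 1
  }
  structure(list(eigengenes = eg$eigengenes,
                 variance_explained = eg$variance_explained,
                 kme = kme, kim = kim, condition = condition),
            class = "module_statistics")
}

#' Merge highly similar modules by eigengene correlation
#'
#' Iteratively merges the closest module pair whose eigengene correlation
#' (in the reference condition) exceeds `merge_cor`, recomputing eigengenes
#' after every merge, until no pair exceeds the threshold. Keeps the module
#' structure from fragmenting one underlying co-expression group into
#' near-duplicate modules.
#'
#' @param data An [expression_dataset()] (log scale).
#' @param part A `module_partition`.
#' @param condition Reference condition whose samples define the eigengenes.
#' @param merge_cor Correlation threshold above which modules merge
#'   (default 0.8).
#' @return The refined `module_partition`, relabelled by size.
#' @export
refine_modules <- function(data, part, condition, merge_cor = 0.8) {
  labels <- part$label_of_gene
  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2) break
    tmp <- module_partition(labels, part$min_module_size, part$cut_height)
    eg <- module_eigengenes(data, tmp, condition)
    cc <- stats::cor(eg$eigengenes)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] <= merge_cor) break
    a <- colnames(cc)[best[2]]
    b <- rownames(cc)[best[1]]
    keep <- sort(c(a, b))[1]
    labels[labels %in% c(a, b)] <- keep
  }
  # relabel by size
  out <- module_partition(labels, part$min_module_size, part$cut_height)
  relab <- stats::setNames(paste0("M", seq_along(out$module_labels)),
                           out$module_labels)
  new_labels <- ifelse(labels == "unassigned", "unassigned",
                       relab[labels])
  names(new_labels) <- names(labels)
  module_partition(new_labels, part$min_module_size, part$cut_height)
}

#' Write a partition as a two-column TSV (gene_id, module)
#' @param part A `module_partition`.
#' @param path Output path.
#' @export
write_partition <- function(part, path) {
  utils::write.table(
    data.frame(gene_id = names(part$label_of_gene),
               module = unname(part$label_of_gene)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
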