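#' Gene significance for a clinical trait
#'
#' GS_i = |Pearson cor(x_i, trait)| over the samples of one condition with a
#' non-missing trait value (pairwise-complete).
#'
#' @param data An [expression_dataset()] with the trait in `$traits`.
#' @param trait Trait name.
#' @param condition Condition label whose samples are used.
#' @return List: `gs` (named per-gene vector in [0, 1]) and `n_used`.
#' @export
gene_significance <- function(data, trait, condition) {
  if (!trait %in% colnames(data$traits))
    stop("trait '", trait, "' not present in dataset")
  samp <- condition_samples(data, condition)
  tv <- data$traits[samp, trait]
  use <- !is.na(tv)
  if (sum(use) < 4)
    stop("trait '", trait, "' has fewer than 4 non-missing values in ",
         "condition '", condition, "'")
  r <- stats::cor(t(data$values[, samp[use], drop = FALSE]), tv[use])[, 1]
  list(gs = abs(r), n_used = sum(use))
}

#' Module eigengene-trait correlations
#'
#' Pearson correlation between each module eigengene and each numeric trait
#' over samples with a non-missing trait value; two-sided p from the t
#' transform t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#' P-values are reported unadjusted (a BH column is appended for
#' convenience, within each trait).
#'
#' @param stats A `module_statistics` (eigengenes for one condition).
#' @param data The [expression_dataset()] carrying the traits.
#' @param traits Trait names (default: all in `data`).
#' @return data.frame: module, trait, r, p, p_bh, n_used. Entries with fewer
#'   than 4 usable samples get NA with a note attribute.
#' @export
module_trait_correlation <- function(stats, data, traits = NULL) {
  if (is.null(traits)) traits <- colnames(data$traits)
  me <- stats$eigengenes
  samp <- rownames(me)
  rows <- list()
  for (tr in traits) {
    tv <- data$traits[samp, tr]
    use <- !is.na(tv)
    for (m in colnames(me)) {
      n_used <- sum(use)
      if (n_used < 4) {
        rows[[length(rows) + 1]] <- data.frame(
          module = m, trait = tr, r = NA_real_, p = NA_real_,
          n_used = n_used, stringsAsFactors = FALSE)
        next
      }
      r <- stats::cor(me[use, m], tv[use])
      r2 <- min(r^2, 1 - 1e-15)
      tstat <- r * sqrt((n_used - 2) / (1 - r2))
      p <- 2 * stats::pt(-abs(tstat), n_used - 2)
      rows[[length(rows) + 1]] <- data.frame(
        module = m, trait = tr, r = r, p = max(p, .Machine$double.xmin),
        n_used = n_used, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(module = character(0), trait = character(0),
                      r = numeric(0), p = numeric(0), n_used = integer(0),
                      p_bh = numeric(0), stringsAsFactors = FALSE))
  out$p_bh <- stats::ave(out$p, out$trait,
                         FUN = function(p) stats::p.adjust(p, "BH"))
  out
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Over-representation of gene sets in modules
#'
#' For each module x set pair over a fixed gene universe, the binomial tail
#' p = P(X >= k), X ~ Binomial(module size, set size / universe size), where
#' k is the observed overlap — the Reactome-style binomial ORA p-value. The
#' hypergeometric tail (Fisher-style) is available via `method`. FDR is BH
#' within each module across sets.
#'
#' @param part A `module_partition`.
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param universe Gene universe (default: the partition's genes). Sets are
#'   intersected with the universe; sets with empty intersection are skipped
#'   with a note.
#' @param method `"binomial"` (default) or `"hypergeometric"`.
#' @return data.frame: module, set, k_overlap, module_size, set_size,
#'   universe_size, p, fdr, overlap_genes (comma-separated).
#' @export
over_representation <- function(part, gene_sets, universe = NULL,
                                method = c("binomial", "hypergeometric")) {
  method <- match.arg(method)
  if (is.null(universe)) universe <- names(part$label_of_gene)
  sets <- lapply(gene_sets, intersect, y = universe)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    message("skipping ", sum(empty), " gene set(s) with empty universe ",
            "intersection")
    sets <- sets[!empty]
  }
  rows <- list()
  for (m in part$module_labels) {
    mg <- intersect(module_genes(part, m), universe)
    for (sn in names(sets)) {
      s <- sets[[sn]]
      ov <- intersect(mg, s)
      k <- length(ov)
      p <- if (method == "binomial") {
        stats::pbinom(k - 1, length(mg), length(s) / length(universe),
                      lower.tail = FALSE)
      } else {
        stats::phyper(k - 1, length(s), length(universe) - length(s),
                      length(mg), lower.tail = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        module = m, set = sn, k_overlap = k, module_size = length(mg),
        set_size = length(s), universe_size = length(universe), p = p,
        overlap_genes = paste(sort(ov), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$fdr <- stats::ave(out$p, out$module,
                          FUN = function(p) stats::p.adjust(p, "BH"))
    out <- out[, c("module", "set", "k_overlap", "module_size", "set_size",
                   "universe_size", "p", "fdr", "overlap_genes")]
  }
  out
}
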