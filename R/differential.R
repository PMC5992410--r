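#' Moderated-t differential expression between the two conditions
#'
#' Fits a per-gene two-group linear model and shrinks the residual variances
#' toward a common prior by empirical Bayes (limma's moderated t), gaining
#' stability at moderate sample sizes. The t statistic is signed as
#' condition 2 minus condition 1, so exchanging the labels negates it.
#'
#' @param data An [expression_dataset()] on the log scale with exactly two
#'   condition labels, each with at least 2 samples.
#' @param de_alpha Adjusted-p threshold for the DE flag (default 0.05).
#' @return data.frame: gene, de_t, de_p, de_p_adj (Benjamini-Hochberg),
#'   de_flag.
#' @export
differential_expression <- function(data, de_alpha = 0.05) {
  labs <- condition_labels(data)
  if (length(labs) != 2) stop("exactly two conditions are required")
  grp <- factor(data$condition, levels = labs)
  if (any(table(grp) < 2)) stop("each condition needs at least 2 samples")
  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(data$values, design))
  t_ <- fit$t[, 2]
  p <- fit$p.value[, 2]
  p_adj <- stats::p.adjust(p, "BH")
  data.frame(gene = rownames(data$values), de_t = unname(t_),
             de_p = unname(p), de_p_adj = unname(p_adj),
             de_flag = unname(p_adj < de_alpha),
             stringsAsFactors = FALSE)
}

#' Per-gene variance F test between the two conditions
#'
#' F = s1^2 / s2^2 with a two-sided p from the F distribution on
#' (n1 - 1, n2 - 1) degrees of freedom (the doubled smaller tail, capped at
#' 1) — the classical two-variance F test applied gene by gene.
#'
#' @param data An [expression_dataset()] on the log scale, two conditions
#'   with at least 2 samples each.
#' @param dv_alpha Adjusted-p threshold for the DV flag (default 0.05).
#' @return data.frame: gene, dv_f, dv_p, dv_p_adj (BH), dv_flag.
#' @export
differential_variability <- function(data, dv_alpha = 0.05) {
  labs <- condition_labels(data)
  if (length(labs) != 2) stop("exactly two conditions are required")
  s1 <- condition_samples(data, labs[1])
  s2 <- condition_samples(data, labs[2])
  if (length(s1) < 2 || length(s2) < 2)
    stop("each condition needs at least 2 samples")
  v1 <- row_vars(data$values[, s1, drop = FALSE])
  v2 <- row_vars(data$values[, s2, drop = FALSE])
  f <- v1 / v2
  df1 <- length(s1) - 1
  df2 <- length(s2) - 1
  p <- 2 * pmin(stats::pf(f, df1, df2), stats::pf(f, df1, df2,
                                                  lower.tail = FALSE))
  p <- pmin(p, 1)
  both_zero <- v1 == 0 & v2 == 0
  one_zero <- xor(v1 == 0, v2 == 0)
  if (any(both_zero)) {
    warning(sum(both_zero), " gene(s) with zero variance in both conditions;",
            " p set to 1")
    f[both_zero] <- 1; p[both_zero] <- 1
  }
  if (any(one_zero)) {
    warning(sum(one_zero), " gene(s) with zero variance in exactly one",
            " condition; p set to its lower bound")
    p[one_zero] <- .Machine$double.xmin
  }
  p_adj <- stats::p.adjust(p, "BH")
  data.frame(gene = rownames(data$values), dv_f = unname(f),
             dv_p = unname(p), dv_p_adj = unname(p_adj),
             dv_flag = unname(p_adj < dv_alpha),
             stringsAsFactors = FALSE)
}

#' Count significantly changed co-expression edges per gene
#'
#' For every unordered gene pair, the condition-specific Pearson
#' correlations r1 and r2 are compared by Fisher's r-to-z:
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with a two-sided
#' normal p. An edge is "changed" when p < `edge_alpha`. The per-gene count
#' n_i of changed incident edges and the global changed-edge rate
#' r = changed pairs / all pairs feed the binomial wiring test
#' ([dw_test()]). Correlations of magnitude 1 are clamped to 1 - 1e-12
#' before atanh, with a warning.
#'
#' @param data An [expression_dataset()] (log scale); both conditions need
#'   more than 3 samples.
#' @param genes Gene universe to test (default: all genes in `data`); the
#'   network analysis passes the filtered network universe here.
#' @param edge_alpha Per-edge significance threshold (default 0.01).
#' @param method Correlation estimator for the edge test: `"pearson"`
#'   (default, matching the classical r-to-z machinery) or `"bicor"`.
#' @return List: `counts` (named per-gene changed-edge counts), `rate`
#'   (global changed-edge rate r), `n_genes`, `changed` (logical genes x
#'   genes matrix), `z` (the z matrix).
#' @export
changed_edges <- function(data, genes = NULL, edge_alpha = 0.01,
                          method = c("pearson", "bicor")) {
  method <- match.arg(method)
  labs <- condition_labels(data)
  if (length(labs) != 2) stop("exactly two conditions are required")
  if (is.null(genes)) genes <- rownames(data$values)
  s1 <- condition_samples(data, labs[1])
  s2 <- condition_samples(data, labs[2])
  n1 <- length(s1); n2 <- length(s2)
  if (n1 <= 3 || n2 <= 3)
    stop("Fisher r-to-z needs more than 3 samples per condition")
  sub <- subset_dataset(data, genes = genes)
  cor_of <- function(samp) {
    if (method == "pearson") stats::cor(t(sub$values[, samp, drop = FALSE]))
    else bicor_matrix(sub, samples = samp)
  }
  r1 <- cor_of(s1)
  r2 <- cor_of(s2)
  lim <- 1 - 1e-12
  if (any(abs(r1[upper.tri(r1)]) >= lim) ||
      any(abs(r2[upper.tri(r2)]) >= lim))
    warning("correlations with |r| = 1 clamped before atanh")
  r1 <- pmin(pmax(r1, -lim), lim)
  r2 <- pmin(pmax(r2, -lim), lim)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (atanh(r1) - atanh(r2)) / se
  p <- 2 * stats::pnorm(-abs(z))
  changed <- p < edge_alpha
  diag(changed) <- FALSE
  counts <- stats::setNames(rowSums(changed), genes)
  n <- length(genes)
  rate <- sum(changed) / (n * (n - 1))  # = changed pairs / total pairs
  list(counts = counts, rate = rate, n_genes = n, changed = changed, z = z)
}

#' Binomial test for genes enriched in changed edges (differential wiring)
#'
#' Under the null that changed edges fall uniformly across the network, the
#' number of changed edges incident to a gene is Binomial(T, r) with
#' T = N - 1 trials (a gene has N - 1 potential edges) and r the global
#' changed-edge rate. The DW p-value is the inclusive upper tail
#' P(X >= n_i), computed with the stable [stats::pbinom()] survival
#' function; a gene is flagged DW when p < `dw_alpha`.
#'
#' @param counts Named per-gene changed-edge counts (from
#'   [changed_edges()]).
#' @param rate Global changed-edge rate r in [0, 1].
#' @param n_genes Network size N.
#' @param dw_alpha DW significance threshold (default 0.01).
#' @return data.frame: gene, changed_edges, dw_p, dw_flag.
#' @export
dw_test <- function(counts, rate, n_genes, dw_alpha = 0.01) {
  if (rate < 0 || rate > 1) stop("`rate` must lie in [0, 1]")
  trials <- n_genes - 1
  if (any(counts > trials))
    stop("a changed-edge count exceeds N - 1; upstream invariant breached")
  p <- stats::pbinom(counts - 1, trials, rate, lower.tail = FALSE)
  data.frame(gene = names(counts), changed_edges = unname(counts),
             dw_p = unname(p), dw_flag = unname(p < dw_alpha),
             stringsAsFactors = FALSE)
}

#' Combined per-gene differential network analysis
#'
#' Runs [differential_expression()], [differential_variability()],
#' [changed_edges()] and [dw_test()] on one gene universe and merges the
#' results.
#'
#' @inheritParams changed_edges
#' @param de_alpha,dv_alpha,dw_alpha Flag thresholds.
#' @return A `differential_result`: list with `table` (per-gene data.frame),
#'   `rate`, `n_genes`.
#' @export
differential_network <- function(data, genes = NULL, edge_alpha = 0.01,
                                 dw_alpha = 0.01, de_alpha = 0.05,
                                 dv_alpha = 0.05,
                                 method = c("pearson", "bicor")) {
  if (is.null(genes)) genes <- rownames(data$values)
  sub <- subset_dataset(data, genes = genes)
  de <- differential_expression(sub, de_alpha)
  dv <- differential_variability(sub, dv_alpha)
  ce <- changed_edges(data, genes, edge_alpha, method)
  dw <- dw_test(ce$counts, ce$rate, ce$n_genes, dw_alpha)
  tab <- merge(merge(de, dv, by = "gene"), dw, by = "gene")
  tab <- tab[match(genes, tab$gene), ]
  rownames(tab) <- NULL
  structure(list(table = tab, rate = ce$rate, n_genes = ce$n_genes),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cat("differential_result over", x$n_genes, "genes:",
      sum(x$table$de_flag), "DE,", sum(x$table$dv_flag), "DV,",
      sum(x$table$dw_flag), "DW; changed-edge rate r =",
      signif(x$rate, 4), "\n")
  invisible(x)
}

#' Module enrichment of affected genes
#'
#' For each module and each affected-gene class (DE, DV, DW), tests whether
#' the module contains more affected genes than expected by chance with a
#' one-sided Fisher's exact test on the 2x2 table (in module vs not) x
#' (affected vs not) over the network universe, Bonferroni-corrected by the
#' number of non-"unassigned" modules.
#'
#' @param part A `module_partition` over the network universe.
#' @param flags Named list of character vectors: for each class name, the
#'   affected gene ids (e.g. `list(DE = ..., DV = ..., DW = ...)`).
#' @param enrich_alpha Bonferroni-corrected threshold for the `enriched`
#'   call (default 0.05).
#' @return data.frame: module, class, in_module_affected, in_module_total,
#'   affected_total, universe_total, odds_ratio, fisher_p, bonferroni_p,
#'   enriched.
#' @export
module_enrichment <- function(part, flags, enrich_alpha = 0.05) {
  universe <- names(part$label_of_gene)
  mods <- part$module_labels
  n_mods <- length(mods)
  empty <- data.frame(module = character(0), class = character(0),
                      in_module_affected = integer(0),
                      in_module_total = integer(0),
                      affected_total = integer(0),
                      universe_total = integer(0), odds_ratio = numeric(0),
                      fisher_p = numeric(0), bonferroni_p = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE)
  if (n_mods == 0 || length(flags) == 0) return(empty)
  rows <- list()
  for (cl in names(flags)) {
    affected <- intersect(flags[[cl]], universe)
    for (m in mods) {
      mg <- module_genes(part, m)
      k <- length(intersect(mg, affected))
      tab <- matrix(c(k,
                      length(mg) - k,
                      length(affected) - k,
                      length(universe) - length(mg) - length(affected) + k),
                    2, 2)
      if (length(affected) == 0) {
        p <- 1; or <- 0
      } else {
        ft <- stats::fisher.test(tab, alternative = "greater")
        p <- ft$p.value
        or <- unname(ft$estimate)
      }
      rows[[length(rows) + 1]] <- data.frame(
        module = m, class = cl, in_module_affected = k,
        in_module_total = length(mg), affected_total = length(affected),
        universe_total = length(universe), odds_ratio = or,
        fisher_p = p, bonferroni_p = min(1, p * n_mods),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$enriched <- out$bonferroni_p < enrich_alpha
  out
}

#' Call differentially wired hub genes
#'
#' A DW hub is a gene flagged DW whose module membership (kME, in the
#' reference condition) exceeds `kme_threshold` — the network-central genes
#' whose wiring changes between conditions. The membership used is the kME
#' to the gene's own consensus module; a gene left unassigned by the
#' consensus clustering (which happens to strongly rewired genes, since the
#' minimum-TOM consensus suppresses membership that holds in only one
#' condition) is judged by the module it is most strongly correlated with in
#' the reference condition. Results are sorted by kME, descending.
#'
#' @param result A `differential_result` (or its `$table`).
#' @param stats A `module_statistics` for the reference condition.
#' @param part The `module_partition` the statistics refer to.
#' @param kme_threshold Strict lower bound on kME (default 0.8).
#' @return data.frame: gene, module, kme, dw_p.
#' @export
call_dw_hubs <- function(result, stats, part, kme_threshold = 0.8) {
  tab <- if (inherits(result, "differential_result")) result$table else result
  dw_genes <- tab$gene[tab$dw_flag]
  out <- data.frame(gene = character(0), module = character(0),
                    kme = numeric(0), dw_p = numeric(0),
                    stringsAsFactors = FALSE)
  if (ncol(stats$kme) == 0) return(out)
  for (g in dw_genes) {
    if (!g %in% rownames(stats$kme)) next
    m <- part$label_of_gene[[g]]
    if (is.null(m) || is.na(m) || m == "unassigned")
      m <- colnames(stats$kme)[which.max(abs(stats$kme[g, ]))]
    if (!m %in% colnames(stats$kme)) next
    kme <- stats$kme[g, m]
    if (kme > kme_threshold)
      out <- rbind(out, data.frame(gene = g, module = m, kme = kme,
                                   dw_p = tab$dw_p[tab$gene == g],
                                   stringsAsFactors = FALSE))
  }
  out[order(-out$kme), , drop = FALSE]
}
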