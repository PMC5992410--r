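#' Consensus network across two conditions
#'
#' The consensus similarity is the entrywise minimum of the two condition
#' TOM matrices (restricted to the shared gene universe), so a high
#' consensus value requires strong topological overlap in BOTH conditions.
#' Because the two networks may use different soft-threshold powers, their
#' TOM scales can differ; with `scale = TRUE` the second TOM is first
#' ratio-scaled so its 95th percentile matches the first's, then the minimum
#' is taken.
#'
#' @param net1,net2 `weighted_network`s with `$tom` computed.
#' @param scale Apply 95th-percentile ratio scaling to `net2`'s TOM before
#'   the minimum (default `FALSE`).
#' @return A `consensus_network`: list with `gene_ids`, `consensus_tom`,
#'   `source_betas`, `scaling_applied`.
#' @export
build_consensus <- function(net1, net2, scale = FALSE) {
  if (is.null(net1$tom) || is.null(net2$tom))
    stop("both networks need TOM computed (tom_similarity)")
  common <- intersect(net1$gene_ids, net2$gene_ids)
  if (length(common) == 0) stop("empty gene intersection between networks")
  t1 <- net1$tom[common, common, drop = FALSE]
  t2 <- net2$tom[common, common, drop = FALSE]
  if (scale) {
    q1 <- stats::quantile(t1[upper.tri(t1)], 0.95)
    q2 <- stats::quantile(t2[upper.tri(t2)], 0.95)
    if (q2 > 0) t2 <- pmin(t2 * (q1 / q2), 1)
  }
  cons <- pmin(t1, t2)
  diag(cons) <- 1
  structure(list(gene_ids = common, consensus_tom = cons,
                 source_betas = c(net1$beta, net2$beta),
                 scaling_applied = scale),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("consensus_network:", length(x$gene_ids), "genes, source betas",
      paste(x$source_betas, collapse = "/"),
      if (x$scaling_applied) "(quantile-scaled)" else "", "\n")
  invisible(x)
}

#' Detect consensus modules
#'
#' Applies the same average-linkage / tree-cut procedure as
#' [detect_modules()] to 1 - consensus TOM. Because the consensus TOM is the
#' minimum over conditions, structure present in only one condition is
#' suppressed and its genes fall to "unassigned".
#'
#' @param cons A `consensus_network`.
#' @param min_size,cut_height As in [detect_modules()].
#' @return A `module_partition`.
#' @export
detect_consensus_modules <- function(cons, min_size = 30,
                                     cut_height = 0.995) {
  detect_modules(cons$consensus_tom, min_size = min_size,
                 cut_height = cut_height)
}
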