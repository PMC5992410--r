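#' Pipeline configuration
#'
#' Collects every tunable threshold of the end-to-end analysis with the
#' package defaults: soft-threshold candidates 1..20 at scale-free R^2 0.80,
#' top-50 percent connectivity filter, minimum module size 30, dendrogram
#' cut height 0.995, eigengene merge threshold 0.8, 200 preservation
#' permutations, per-edge and DW alphas 0.01, DE/DV alphas 0.05 (BH), and a
#' DW-hub kME threshold of 0.8.
#'
#' @param expression,annotation,exclusion_list,gmt Optional input paths; the
#'   first two are unused when a dataset object is passed to
#'   [run_pipeline()] directly.
#' @param reference_condition Condition treated as the reference (its
#'   samples define module eigengene statistics for hub calling); default:
#'   first label in the data.
#' @param beta_candidates,r2_target See [pick_soft_threshold()].
#' @param connectivity_fraction See [filter_top_connectivity()].
#' @param min_module_size,cut_height See [detect_modules()].
#' @param merge_cor See [refine_modules()].
#' @param n_perm Preservation permutations (>= 50).
#' @param edge_alpha,dw_alpha,de_alpha,dv_alpha,hub_kme Differential-network
#'   thresholds.
#' @param variance_floor,iac_threshold,drop_flagged Preprocessing options.
#' @param seed Master seed; stochastic stages draw from substreams derived
#'   from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, annotation = NULL,
                            exclusion_list = NULL, gmt = NULL,
                            reference_condition = NULL,
                            beta_candidates = 1:20, r2_target = 0.80,
                            connectivity_fraction = 0.5,
                            min_module_size = 30, cut_height = 0.995,
                            merge_cor = 0.8, n_perm = 200,
                            edge_alpha = 0.01, dw_alpha = 0.01,
                            de_alpha = 0.05, dv_alpha = 0.05,
                            hub_kme = 0.8, variance_floor = 0,
                            iac_threshold = 0.65, drop_flagged = FALSE,
                            seed = 1L) {
  cfg <- as.list(environment())
  alphas <- c(edge_alpha, dw_alpha, de_alpha, dv_alpha)
  if (any(alphas <= 0 | alphas >= 1))
    stop("all alpha thresholds must lie in (0, 1)")
  if (connectivity_fraction <= 0 || connectivity_fraction > 1)
    stop("`connectivity_fraction` must lie in (0, 1]")
  if (n_perm < 50) stop("`n_perm` must be >= 50")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full differential co-expression analysis
#'
#' Executes, in order: preprocessing (log2(x+1), gene filters, IAC screen);
#' per-condition biweight-midcorrelation networks with independent
#' soft-threshold selection; unification of the two universes by keeping the
#' genes in the top `connectivity_fraction` of MEAN condition connectivity
#' (so both networks share one gene universe); per-condition TOM;
#' reference-condition module detection with quality and cross-condition
#' preservation statistics; consensus TOM (entrywise minimum) and consensus
#' modules with eigengene-based merging; per-condition module statistics;
#' DE/DV/DW tests with module enrichment and DW-hub calls; module-trait
#' correlations and gene significance; optional gene-set
#' over-representation. All tabular artifacts are written to `out_dir`
#' together with a JSON run manifest (config snapshot, seed, universe size,
#' per-stage wall-clock, file checksums, warnings).
#'
#' @param data An [expression_dataset()] of nonnegative normalized counts,
#'   or `NULL` to read from the paths in `config`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for TSV artifacts and `manifest.json`.
#' @return Invisibly, a list with every stage's result object plus
#'   `manifest`.
#' @export
run_pipeline <- function(data = NULL, config = pipeline_config(),
                         out_dir = "diffwire_out") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- c()
  warns <- character(0)
  stamp <- function(stage, start) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - start, units = "secs"),
                               3)
  }
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  run_stage <- function(stage, expr) {
    start <- Sys.time()
    res <- tryCatch(wcollect(expr), error = function(e) {
      writeLines(paste("FAILED at stage:", stage),
                 file.path(out_dir, "FAILED"))
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    })
    stamp(stage, start)
    res
  }

  if (is.null(data)) {
    if (is.null(config$expression) || is.null(config$annotation))
      stop("either pass `data` or set expression/annotation paths in config")
    data <- read_dataset(config$expression, config$annotation)
  }
  excl <- if (!is.null(config$exclusion_list))
    read_exclusion_list(config$exclusion_list) else character(0)

  prep <- run_stage("preprocessing", preprocess(
    data, excl, config$variance_floor, config$iac_threshold,
    config$drop_flagged))
  d <- prep$data

  labs <- condition_labels(d)
  if (length(labs) != 2) stop("the pipeline requires exactly two conditions")
  ref <- config$reference_condition
  if (is.null(ref)) ref <- labs[1]
  if (!ref %in% labs) stop("reference_condition '", ref, "' not in data")
  other <- setdiff(labs, ref)
  if (min(table(d$condition)) < 4)
    stop("each condition needs at least 4 samples")

  nets <- run_stage("network_construction", {
    lapply(stats::setNames(c(ref, other), c(ref, other)), function(cl) {
      cm <- bicor_matrix(d, condition_samples(d, cl))
      st <- pick_soft_threshold(cm, config$beta_candidates, config$r2_target)
      list(net = adjacency_from_cor(cm, st$beta, cl), fit = st$fit_table)
    })
  })

  # one shared universe: top fraction of MEAN condition connectivity
  universe <- run_stage("universe_unification", {
    k_mean <- (connectivity(nets[[ref]]$net) +
                 connectivity(nets[[other]]$net)) / 2
    n_keep <- ceiling(config$connectivity_fraction * length(k_mean))
    gid <- nets[[ref]]$net$gene_ids
    sort(gid[order(-k_mean, gid)[seq_len(n_keep)]])
  })
  slice_net <- function(nn) {
    nn$adjacency <- nn$adjacency[universe, universe]
    nn$gene_ids <- universe
    nn$tom <- NULL
    nn
  }
  net1 <- run_stage("tom_reference",
                    tom_similarity(slice_net(nets[[ref]]$net)))
  net2 <- run_stage("tom_other", tom_similarity(slice_net(nets[[other]]$net)))

  part_ref <- run_stage("reference_modules", detect_modules(
    net1, config$min_module_size, config$cut_height))
  quality <- run_stage("module_quality", module_preservation(
    net1, net1, part_ref, config$n_perm, config$seed + 101L))
  preservation <- run_stage("module_preservation", module_preservation(
    net1, net2, part_ref, config$n_perm, config$seed + 102L))

  cons <- run_stage("consensus_network", build_consensus(net1, net2))
  part <- run_stage("consensus_modules", {
    p0 <- detect_consensus_modules(cons, config$min_module_size,
                                   config$cut_height)
    if (length(p0$module_labels) > 1)
      refine_modules(d, p0, ref, config$merge_cor) else p0
  })

  stats_ref <- run_stage("module_statistics_reference",
                         compute_module_statistics(d, net1, part, ref))
  stats_other <- run_stage("module_statistics_other",
                           compute_module_statistics(d, net2, part, other))

  diff <- run_stage("differential_network", differential_network(
    d, universe, config$edge_alpha, config$dw_alpha, config$de_alpha,
    config$dv_alpha))
  flags <- list(DE = diff$table$gene[diff$table$de_flag],
                DV = diff$table$gene[diff$table$dv_flag],
                DW = diff$table$gene[diff$table$dw_flag])
  enrich <- run_stage("module_enrichment", module_enrichment(part, flags))
  hubs <- run_stage("dw_hubs", call_dw_hubs(diff, stats_ref, part,
                                            config$hub_kme))

  trait_cor <- NULL
  if (ncol(d$traits) > 0)
    trait_cor <- run_stage("trait_association", rbind(
      cbind(condition = ref, module_trait_correlation(stats_ref, d)),
      cbind(condition = other, module_trait_correlation(stats_other, d))))

  ora <- NULL
  if (!is.null(config$gmt))
    ora <- run_stage("over_representation",
                     over_representation(part, read_gmt(config$gmt)))

  # tabular artifacts
  out <- function(f) file.path(out_dir, f)
  gene_tab <- diff$table
  gene_tab$module <- unname(part$label_of_gene[gene_tab$gene])
  utils::write.table(gene_tab, out("differential_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(enrich, out("module_enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(hubs, out("dw_hubs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_partition(part, out("consensus_modules.tsv"))
  write_partition(part_ref, out("reference_modules.tsv"))
  utils::write.table(rbind(quality, preservation), out("preservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kme_tab <- data.frame(gene = rownames(stats_ref$kme),
                        module = unname(part$label_of_gene[
                          rownames(stats_ref$kme)]),
                        kme_own = kme_own_module(stats_ref, part),
                        kim = unname(stats_ref$kim))
  utils::write.table(kme_tab, out("module_membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(trait_cor))
    utils::write.table(trait_cor, out("module_trait_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ora))
    utils::write.table(ora, out("over_representation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("diffwire")),
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    n_samples = ncol(d$values),
    universe_size = length(universe),
    betas = stats::setNames(c(nets[[ref]]$net$beta, nets[[other]]$net$beta),
                            c(ref, other)),
    n_consensus_modules = length(part$module_labels),
    n_unassigned = sum(part$label_of_gene == "unassigned"),
    n_de = sum(diff$table$de_flag), n_dv = sum(diff$table$dv_flag),
    n_dw = sum(diff$table$dw_flag),
    stage_seconds = as.list(timings),
    checksums = as.list(tools::md5sum(files)),
    warnings = warns,
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  invisible(list(data = d, preprocessing = prep, networks = nets,
                 universe = universe, net_ref = net1, net_other = net2,
                 reference_partition = part_ref, quality = quality,
                 preservation = preservation, consensus = cons,
                 partition = part, stats_ref = stats_ref,
                 stats_other = stats_other, differential = diff,
                 enrichment = enrich, hubs = hubs, trait_cor = trait_cor,
                 ora = ora, manifest = manifest))
}

# kME of each gene to its own module (NA for unassigned genes)
kme_own_module <- function(stats, part) {
  genes <- rownames(stats$kme)
  lab <- part$label_of_gene[genes]
  out <- rep(NA_real_, length(genes))
  ok <- lab %in% colnames(stats$kme)
  out[ok] <- stats$kme[cbind(which(ok), match(lab[ok], colnames(stats$kme)))]
  stats::setNames(out, genes)
}
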