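#' Configuration for the two-condition synthetic expression generator
#'
#' Defines the latent-factor model from which [generate_dataset()] draws a
#' gene x sample matrix with planted co-expression modules, rewired (DW),
#' mean-shifted (DE) and variance-scaled (DV) genes, and numeric traits
#' driven by module eigengenes. Defaults describe the package's reference
#' simulation: 1,000 genes in 5 modules of 150 (250 pure-noise background
#' genes), 60 samples per condition, 10 DW genes (half drawn from hubs),
#' 30 DE genes at a log2 shift of 1, and 30 DV genes at a 4-fold variance
#' increase.
#'
#' @param n_genes Total number of genes.
#' @param module_sizes Integer vector of planted module sizes; the sum must
#'   not exceed `n_genes`, and leftover genes become unstructured background.
#' @param n_samples_per_condition Length-2 integer vector: samples in
#'   condition 1 and condition 2.
#' @param hub_loading_range Interval within (0, 1]: eigengene loadings drawn
#'   for the top 20 percent of each module (its hubs).
#' @param background_loading_range Interval within [0, 1): the non-hub
#'   loadings decay linearly from just below the hub range toward the upper
#'   bound of this interval, leaving a gap around the kME = 0.8 hub
#'   threshold so hub status is unambiguous.
#' @param n_dw_genes Number of differentially wired genes: in condition 2
#'   only, their loading is moved to a different module's eigengene.
#' @param dw_hub_fraction Fraction of DW genes drawn from module hubs (the
#'   rest come from non-hub module genes). Default 1: the reference
#'   simulation plants its DW signal on hubs, the case of scientific
#'   interest for hub calling.
#' @param dw_mode How a DW gene loses its condition-1 wiring in condition 2:
#'   `"zero"` (default) sets its loading to zero, so the planted truth
#'   labels stay complete — no other gene's wiring changes beyond its edges
#'   to the DW genes; `"reassign"` moves the loading to a different module's
#'   eigengene, which additionally plants real secondary wiring changes on
#'   the receiving module's genes (unlabelled in the truth).
#' @param n_de_genes,de_shift Number of differentially expressed genes and
#'   the log2-scale mean shift added in condition 2.
#' @param n_dv_genes,dv_scale Number of differentially variable genes and the
#'   factor (> 1) by which their residual variance is multiplied in
#'   condition 2. DE labels are planted on non-hub module genes (a mean
#'   shift leaves the correlation structure untouched, and module genes
#'   survive the pipeline's connectivity filter); DV labels go to background
#'   genes, whose total variance is pure residual variance, so the planted
#'   variance ratio equals `dv_scale` exactly.
#' @param trait_driver_modules Named integer vector mapping trait name to the
#'   1-based index of the module whose eigengene drives it.
#' @param trait_noise_sd Gaussian noise sd added to each trait.
#' @param trait_missing_rate Probability that a trait value is missing.
#' @param gene_baseline_sd Standard deviation of the per-gene log2 baseline
#'   abundance (drawn once per gene, shared by both conditions). Real
#'   expression data spans orders of magnitude across genes; this baseline
#'   is what makes sample-to-sample correlations over genes (the IAC screen)
#'   high, as they are on real arrays. It cancels from every per-gene
#'   centred statistic.
#' @param count_offset Offset used when mapping latent log2 expression x to
#'   nonnegative "normalized counts" via 2^(x + baseline + offset) - 1; the
#'   default 8 keeps even the lowest-baseline genes clear of the zero floor.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000,
                             module_sizes = rep(150L, 5L),
                             n_samples_per_condition = c(60L, 60L),
                             hub_loading_range = c(0.85, 0.95),
                             background_loading_range = c(0, 0.40),
                             n_dw_genes = 10L,
                             dw_hub_fraction = 1.0,
                             dw_mode = c("zero", "reassign"),
                             n_de_genes = 30L,
                             de_shift = 1.0,
                             n_dv_genes = 30L,
                             dv_scale = 4,
                             trait_driver_modules = c(pack_years = 1L,
                                                      drinks_per_day = 2L),
                             trait_noise_sd = 0.5,
                             trait_missing_rate = 0.2,
                             gene_baseline_sd = 2.5,
                             count_offset = 8,
                             seed = 1L) {
  dw_mode <- match.arg(dw_mode)
  cfg <- list(n_genes = as.integer(n_genes),
              module_sizes = as.integer(module_sizes),
              n_samples_per_condition = as.integer(n_samples_per_condition),
              hub_loading_range = as.numeric(hub_loading_range),
              background_loading_range = as.numeric(background_loading_range),
              n_dw_genes = as.integer(n_dw_genes),
              dw_hub_fraction = as.numeric(dw_hub_fraction),
              dw_mode = dw_mode,
              n_de_genes = as.integer(n_de_genes),
              de_shift = as.numeric(de_shift),
              n_dv_genes = as.integer(n_dv_genes),
              dv_scale = as.numeric(dv_scale),
              trait_driver_modules = trait_driver_modules,
              trait_noise_sd = as.numeric(trait_noise_sd),
              trait_missing_rate = as.numeric(trait_missing_rate),
              gene_baseline_sd = as.numeric(gene_baseline_sd),
              count_offset = as.numeric(count_offset),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid `", field, "`: ", msg,
                                    call. = FALSE)
  if (cfg$n_genes < 1) fail("n_genes", "must be positive")
  if (any(cfg$module_sizes < 1)) fail("module_sizes", "all sizes must be >= 1")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    fail("module_sizes", sprintf("sum (%d) exceeds n_genes (%d)",
                                 sum(cfg$module_sizes), cfg$n_genes))
  if (length(cfg$n_samples_per_condition) != 2 ||
      any(cfg$n_samples_per_condition < 1))
    fail("n_samples_per_condition", "must be two positive integers")
  hl <- cfg$hub_loading_range
  if (length(hl) != 2 || hl[1] <= 0 || hl[2] > 1 || hl[1] > hl[2])
    fail("hub_loading_range", "must be an interval within (0, 1]")
  bl <- cfg$background_loading_range
  if (length(bl) != 2 || bl[1] < 0 || bl[2] >= 1 || bl[1] > bl[2])
    fail("background_loading_range", "must be an interval within [0, 1)")
  if (cfg$n_dw_genes < 0 || cfg$n_dw_genes > sum(cfg$module_sizes))
    fail("n_dw_genes", "must be between 0 and sum(module_sizes)")
  if (cfg$dw_hub_fraction < 0 || cfg$dw_hub_fraction > 1)
    fail("dw_hub_fraction", "must lie in [0, 1]")
  n_background <- cfg$n_genes - sum(cfg$module_sizes)
  if (cfg$n_dv_genes > n_background)
    fail("n_dv_genes",
         sprintf("n_dv_genes (%d) exceeds background gene count (%d)",
                 cfg$n_dv_genes, n_background))
  if (cfg$n_de_genes + cfg$n_dw_genes > sum(cfg$module_sizes))
    fail("n_de_genes",
         "n_de_genes + n_dw_genes exceeds the module gene pool")
  if (cfg$n_dv_genes > 0 && cfg$dv_scale <= 1)
    fail("dv_scale", "must be > 1")
  tdm <- cfg$trait_driver_modules
  if (length(tdm) > 0) {
    if (is.null(names(tdm)) || any(!nzchar(names(tdm))))
      fail("trait_driver_modules", "must be named by trait")
    if (any(tdm < 1 | tdm > length(cfg$module_sizes)))
      fail("trait_driver_modules", "module index out of range")
  }
  if (cfg$trait_missing_rate < 0 || cfg$trait_missing_rate >= 1)
    fail("trait_missing_rate", "must lie in [0, 1)")
  if (cfg$trait_noise_sd <= 0) fail("trait_noise_sd", "must be positive")
  if (cfg$gene_baseline_sd < 0) fail("gene_baseline_sd", "must be >= 0")
  invisible(cfg)
}

# Per-module loading profile: hubs (top 20%) in hub_loading_range, the rest
# decaying linearly from 0.1 below the hub range toward the background upper
# bound. The gap keeps planted hubs separated at the kME = 0.8 threshold.
module_loadings <- function(size, hub_range, bg_range) {
  n_hub <- max(1L, ceiling(0.2 * size))
  hub <- sort(stats::runif(n_hub, hub_range[1], hub_range[2]),
              decreasing = TRUE)
  n_rest <- size - n_hub
  if (n_rest == 0) return(hub)
  top_rest <- max(bg_range[2], hub_range[1] - 0.1)
  rest <- seq(top_rest, bg_range[2], length.out = n_rest)
  c(hub, rest)
}

#' Generate a two-condition expression dataset with planted signal
#'
#' Latent-factor simulation: each module m in condition c has an eigengene
#' E_{m,c} ~ N(0, I) drawn independently per condition; gene g in module m
#' with loading u_g has latent expression x = u_g E_{m,c} + e, with residual
#' sd sqrt(1 - u_g^2) so that cor(x, E) = u_g. Background genes are pure
#' N(0,1) noise. DW genes keep their condition-1 behaviour but load on a
#' different module's eigengene in condition 2; DE genes gain a mean shift
#' and DV genes a residual-variance scaling in condition 2. Traits equal the
#' driver module's eigengene plus noise, with missing values at the
#' configured rate. Latent values map to nonnegative normalized counts via
#' 2^(x + offset) - 1, so the pipeline's log2(x + 1) transform approximately
#' recovers x.
#'
#' @param config A [synthetic_config()].
#' @return A list with `data` (an [expression_dataset()] of counts, condition
#'   labels `"progressor"`/`"nonprogressor"`) and `truth` (a
#'   `synthetic_truth` list: `module_of_gene` named integer vector with 0 for
#'   background, `dw_genes`, `de_genes`, `dv_genes`, `hub_genes`,
#'   `trait_driver_modules`, `loadings`, and `dw_target_module`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  n_mod <- length(config$module_sizes)
  n1 <- config$n_samples_per_condition[1]
  n2 <- config$n_samples_per_condition[2]
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  samples <- c(sprintf("P%03d", seq_len(n1)), sprintf("N%03d", seq_len(n2)))
  condition <- stats::setNames(rep(c("progressor", "nonprogressor"),
                                   c(n1, n2)), samples)

  module_of_gene <- integer(config$n_genes)
  idx <- 1L
  for (m in seq_len(n_mod)) {
    module_of_gene[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }
  names(module_of_gene) <- genes

  loadings <- numeric(config$n_genes)
  hub_flag <- logical(config$n_genes)
  for (m in seq_len(n_mod)) {
    in_m <- which(module_of_gene == m)
    lm <- module_loadings(length(in_m), config$hub_loading_range,
                          config$background_loading_range)
    loadings[in_m] <- lm
    hub_flag[in_m[seq_len(max(1L, ceiling(0.2 * length(in_m))))]] <- TRUE
  }
  names(loadings) <- genes

  # planted labels; each gene carries at most one
  module_gene_idx <- which(module_of_gene > 0)
  hub_idx <- which(hub_flag)
  nonhub_idx <- setdiff(module_gene_idx, hub_idx)
  n_dw_hub <- min(round(config$n_dw_genes * config$dw_hub_fraction),
                  length(hub_idx))
  n_dw_rest <- config$n_dw_genes - n_dw_hub
  dw_idx <- c(if (n_dw_hub > 0) sample(hub_idx, n_dw_hub),
              if (n_dw_rest > 0) sample(nonhub_idx, n_dw_rest))
  background_idx <- which(module_of_gene == 0)
  de_pool <- setdiff(nonhub_idx, dw_idx)
  if (config$n_de_genes > length(de_pool))
    stop("invalid `n_de_genes`: exceeds the unlabelled non-hub module gene",
         " pool (", length(de_pool), ")", call. = FALSE)
  de_idx <- if (config$n_de_genes > 0)
    sample(de_pool, config$n_de_genes) else integer(0)
  dv_idx <- if (config$n_dv_genes > 0)
    sample(background_idx, config$n_dv_genes) else integer(0)

  # condition-2 rewiring target for each DW gene: 0 = loading zeroed
  dw_target <- integer(length(dw_idx))
  if (identical(config$dw_mode, "reassign")) {
    for (j in seq_along(dw_idx)) {
      own <- module_of_gene[dw_idx[j]]
      others <- setdiff(seq_len(n_mod), own)
      dw_target[j] <- if (length(others) == 0) 0L else
        others[1L + (j - 1L) %% length(others)]
    }
  }

  eig1 <- matrix(stats::rnorm(n_mod * n1), n_mod, n1)
  eig2 <- matrix(stats::rnorm(n_mod * n2), n_mod, n2)

  x <- matrix(0, config$n_genes, n1 + n2, dimnames = list(genes, samples))
  for (g in seq_len(config$n_genes)) {
    m <- module_of_gene[g]
    u <- loadings[g]
    sd_res <- sqrt(max(0, 1 - u^2))
    x1 <- if (m > 0) u * eig1[m, ] else numeric(n1)
    m2 <- m
    pos <- match(g, dw_idx)
    if (!is.na(pos)) m2 <- dw_target[pos]
    x2 <- if (m2 > 0) u * eig2[m2, ] else numeric(n2)
    sd2 <- sd_res
    if (g %in% dv_idx) sd2 <- sd_res * sqrt(config$dv_scale)
    x1 <- x1 + stats::rnorm(n1, 0, sd_res)
    x2 <- x2 + stats::rnorm(n2, 0, sd2)
    if (g %in% de_idx) x2 <- x2 + config$de_shift
    x[g, ] <- c(x1, x2)
  }

  traits <- data.frame(row.names = samples)
  for (tn in names(config$trait_driver_modules)) {
    m <- config$trait_driver_modules[[tn]]
    v <- c(eig1[m, ], eig2[m, ]) +
      stats::rnorm(n1 + n2, 0, config$trait_noise_sd)
    if (config$trait_missing_rate > 0) {
      miss <- stats::runif(n1 + n2) < config$trait_missing_rate
      v[miss] <- NA_real_
    }
    traits[[tn]] <- v
  }

  # truncate baselines at +/- 2 sd so that, at the default offset, the
  # count floor at zero is essentially never reached and log2(count + 1)
  # recovers x + baseline + offset exactly
  bl_cap <- 2 * config$gene_baseline_sd
  baseline <- pmin(pmax(stats::rnorm(config$n_genes, 0,
                                     config$gene_baseline_sd), -bl_cap),
                   bl_cap)
  counts <- pmax(2^(x + baseline + config$count_offset) - 1, 0)

  truth <- structure(list(
    module_of_gene = module_of_gene,
    dw_genes = genes[dw_idx],
    de_genes = genes[de_idx],
    dv_genes = genes[dv_idx],
    hub_genes = genes[hub_idx],
    trait_driver_modules = config$trait_driver_modules,
    loadings = loadings,
    dw_target_module = stats::setNames(dw_target, genes[dw_idx])
  ), class = "synthetic_truth")

  list(data = expression_dataset(counts, condition, traits), truth = truth)
}

#' Write a generated dataset and its ground truth to a directory
#'
#' Produces `expression.tsv`, `annotation.tsv` and `truth.json`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
simulate_dataset_files <- function(config = synthetic_config(), dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_dataset(config)
  ep <- file.path(dir, "expression.tsv")
  ap <- file.path(dir, "annotation.tsv")
  tp <- file.path(dir, "truth.json")
  write_dataset(sim$data, ep, ap)
  jsonlite::write_json(lapply(unclass(sim$truth), function(v)
    if (is.null(names(v)) || length(v) == 0) v else as.list(v)),
    tp, auto_unbox = TRUE, digits = NA)
  invisible(c(ep, ap, tp))
}
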