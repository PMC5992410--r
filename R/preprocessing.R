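#' Variance-stabilizing log transform
#'
#' Replaces every expression value v by log2(v + 1). This is the standard
#' transform for normalized RNA-seq counts ahead of correlation-based
#' network analysis: it tames the mean-variance relationship while mapping
#' 0 to 0.
#'
#' @param data An [expression_dataset()] of nonnegative values.
#' @return The transformed [expression_dataset()]; ids, condition labels and
#'   traits are unchanged.
#' @export
log_transform <- function(data) {
  neg <- which(data$values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(data$values)[neg[1, 1]],
                 colnames(data$values)[neg[1, 2]]))
  data$values <- log2(data$values + 1)
  data
}

#' Filter genes by exclusion list and variance
#'
#' Removes (a) genes named on a user-supplied exclusion list (e.g. the
#' olfactory receptor genes commonly dropped from tumor expression data) and
#' (b) genes whose variance across all samples is at or below
#' `variance_floor` (default 0: strictly zero-variance genes, which carry no
#' correlation signal).
#'
#' @param data An [expression_dataset()], normally post-[log_transform()].
#' @param exclusion_list Character vector of gene ids to drop (may be empty).
#' @param variance_floor Nonnegative variance threshold; genes with
#'   `var <= variance_floor` are dropped.
#' @return A list: `data` (the filtered [expression_dataset()]) and `report`
#'   (data.frame with columns `gene_id`, `reason`).
#' @export
filter_genes <- function(data, exclusion_list = character(0),
                         variance_floor = 0) {
  if (variance_floor < 0) stop("`variance_floor` must be >= 0")
  v <- row_vars(data$values)
  excluded <- rownames(data$values) %in% exclusion_list
  low_var <- v <= variance_floor & !excluded
  report <- data.frame(
    gene_id = c(rownames(data$values)[excluded],
                rownames(data$values)[low_var]),
    reason = rep(c("exclusion list", "zero/low variance"),
                 c(sum(excluded), sum(low_var))),
    stringsAsFactors = FALSE
  )
  keep <- !(excluded | low_var)
  if (!any(keep)) stop("gene filtering removed every gene")
  list(data = subset_dataset(data, genes = which(keep)), report = report)
}

#' Inter-array correlation (IAC) sample screen
#'
#' The IAC of a sample is its mean Pearson correlation (over genes) with
#' every other sample; unusually low values indicate outlying arrays.
#'
#' @param data An [expression_dataset()] with at least 3 samples.
#' @return Named numeric vector of per-sample IAC values.
#' @export
inter_array_correlation <- function(data) {
  if (ncol(data$values) < 3) stop("IAC needs at least 3 samples")
  sds <- apply(data$values, 2, stats::sd)
  if (any(sds == 0))
    stop("sample '", colnames(data$values)[which(sds == 0)[1]],
         "' has zero variance across genes; its correlations are undefined")
  cc <- stats::cor(data$values)
  n <- ncol(cc)
  stats::setNames((rowSums(cc) - 1) / (n - 1), colnames(data$values))
}

#' Flag samples with low inter-array correlation
#'
#' @param iac Named IAC vector from [inter_array_correlation()].
#' @param threshold Samples with IAC below this are flagged (default 0.65,
#'   the conventional screen for expression arrays).
#' @return Character vector of flagged sample ids (possibly empty). Flagged
#'   samples are reported, not dropped; removal is the caller's decision.
#' @export
flag_low_iac <- function(iac, threshold = 0.65) {
  names(iac)[iac < threshold]
}

#' Full preprocessing stage
#'
#' log2(x + 1) transform, exclusion-list and variance filtering, and the IAC
#' outlier screen, in that order.
#'
#' @inheritParams filter_genes
#' @param iac_threshold Passed to [flag_low_iac()].
#' @param drop_flagged If `TRUE`, samples failing the IAC screen are removed.
#' @return A list: `data` (processed dataset), `removed_genes` (report
#'   data.frame), `iac` (named vector), `flagged_samples` (character).
#' @export
preprocess <- function(data, exclusion_list = character(0),
                       variance_floor = 0, iac_threshold = 0.65,
                       drop_flagged = FALSE) {
  data <- log_transform(data)
  filt <- filter_genes(data, exclusion_list, variance_floor)
  iac <- inter_array_correlation(filt$data)
  flagged <- flag_low_iac(iac, iac_threshold)
  out <- filt$data
  if (drop_flagged && length(flagged) > 0)
    out <- subset_dataset(out, samples = setdiff(colnames(out$values), flagged))
  list(data = out, removed_genes = filt$report, iac = iac,
       flagged_samples = flagged)
}

# rowwise variance without forming a dense centered copy per call site
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  (rowSums(x^2) - n * mu^2) / (n - 1)
}
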