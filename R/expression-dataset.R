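#' Expression dataset container
#'
#' Bundles a gene x sample matrix of expression values with per-sample
#' condition labels and optional numeric traits. This is the universal input
#' object of the pipeline: the generator produces one, preprocessing
#' transforms one, and every downstream stage consumes one.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique; they become the gene and
#'   sample identifiers.
#' @param condition Character (or factor) vector of per-sample condition
#'   labels, one per column of `values`, named by sample id or in column
#'   order. Exactly the labels define the study's two (or more) groups.
#' @param traits Optional data.frame of numeric traits, one row per sample
#'   (rownames = sample ids). `NA` encodes a missing measurement.
#'
#' @return An object of class `expression_dataset` with elements `values`,
#'   `condition` (named character vector) and `traits` (data.frame, possibly
#'   zero-column).
#' @export
expression_dataset <- function(values, condition, traits = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  condition <- as.character(condition)
  if (length(condition) != ncol(values))
    stop("`condition` must have one label per sample")
  if (is.null(names(condition))) names(condition) <- colnames(values)
  condition <- condition[colnames(values)]
  if (anyNA(condition))
    stop("every sample needs exactly one condition label")
  if (is.null(traits)) {
    traits <- data.frame(row.names = colnames(values))
  } else {
    traits <- as.data.frame(traits)
    if (nrow(traits) != ncol(values))
      stop("`traits` must have one row per sample")
    rownames(traits) <- colnames(values)
  }
  structure(
    list(values = values, condition = condition, traits = traits),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  tab <- table(x$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (ncol(x$traits) > 0)
    cat("traits:", paste(colnames(x$traits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

gene_ids <- function(data) rownames(data$values)
sample_ids <- function(data) colnames(data$values)

#' Condition labels present in a dataset
#'
#' @param data An [expression_dataset()].
#' @return Character vector of distinct condition labels, in order of first
#'   appearance.
#' @export
condition_labels <- function(data) unique(unname(data$condition))

#' Sample ids belonging to one condition
#'
#' @param data An [expression_dataset()].
#' @param label A condition label present in `data`.
#' @return Character vector of sample ids.
#' @export
condition_samples <- function(data, label) {
  if (!label %in% data$condition)
    stop("condition label '", label, "' not present in dataset")
  names(data$condition)[data$condition == label]
}

#' Subset a dataset by genes and/or samples
#'
#' @param data An [expression_dataset()].
#' @param genes Gene ids (or logical/integer index) to keep; `NULL` keeps all.
#' @param samples Sample ids (or index) to keep; `NULL` keeps all.
#' @return The subsetted [expression_dataset()].
#' @export
subset_dataset <- function(data, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- rownames(data$values)
  if (is.null(samples)) samples <- colnames(data$values)
  vals <- data$values[genes, samples, drop = FALSE]
  expression_dataset(vals, data$condition[colnames(vals)],
                     data$traits[colnames(vals), , drop = FALSE])
}

#' Write a dataset to disk as plain-text tables
#'
#' Expression goes to a TSV with gene ids in the first column (`gene_id`) and
#' one column per sample; the annotation TSV has columns `sample_id`,
#' `condition`, then one column per trait with missing values encoded as
#' empty fields.
#'
#' @param data An [expression_dataset()].
#' @param expression_path,annotation_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(data, expression_path, annotation_path) {
  expr <- data.frame(gene_id = rownames(data$values), data$values,
                     check.names = FALSE)
  utils::write.table(expr, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(sample_id = colnames(data$values),
                    condition = unname(data$condition),
                    data$traits, check.names = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(expression_path, annotation_path))
}

#' Read an expression matrix plus sample annotation into a dataset
#'
#' Accepts the TSV/CSV layout written by [write_dataset()]: expression with
#' gene ids in the first column and sample ids in the header; annotation with
#' `sample_id` and `condition` columns and any further numeric trait columns.
#' Gzip-compressed files are handled transparently by R's readers.
#'
#' @param expression_path Path to the expression table (TSV, or CSV if the
#'   file extension is `.csv`/`.csv.gz`).
#' @param annotation_path Path to the sample annotation TSV.
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(expression_path, annotation_path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", expression_path)) "," else "\t"
  expr <- utils::read.table(expression_path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(expr[, -1, drop = FALSE])
  rownames(vals) <- as.character(expr[[1]])
  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!all(c("sample_id", "condition") %in% colnames(ann)))
    stop("annotation must contain 'sample_id' and 'condition' columns")
  rownames(ann) <- ann$sample_id
  ann <- ann[colnames(vals), , drop = FALSE]
  traits <- ann[, setdiff(colnames(ann), c("sample_id", "condition")),
                drop = FALSE]
  expression_dataset(vals, stats::setNames(ann$condition, ann$sample_id),
                     traits)
}

#' Read a gene exclusion list (one gene id per line)
#'
#' @param path File path; blank lines and `#` comments are ignored.
#' @return Character vector of gene ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
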