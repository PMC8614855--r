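#' Expression matrix with sample metadata
#'
#' Wraps a features x samples numeric matrix (raw counts or TPM) together
#' with the sample-to-stage metadata of the time-course design. Counts must
#' be non-negative integers; TPM any non-negative reals. Stages are kept as
#' an ordered factor so downstream stage comparisons have a defined order
#' (developmental time: e.g. D0 < D15 < D85 < Y2).
#'
#' @param values Numeric matrix, rownames = feature ids, colnames = sample
#'   ids.
#' @param kind `"counts"` or `"TPM"`.
#' @param metadata `data.frame` with columns `sample_id`, `stage`,
#'   `replicate`; every sample column must appear.
#' @param stage_order Optional character vector fixing the stage order;
#'   defaults to order of first appearance in `metadata`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, kind = c("counts", "TPM"), metadata,
                              stage_order = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature rownames and sample colnames")
  }
  if (any(values < 0)) stop("validation error: negative expression value")
  if (kind == "counts" && any(values != round(values))) {
    stop("validation error: counts must be integral")
  }
  stopifnot(all(c("sample_id", "stage", "replicate") %in% names(metadata)))
  missing <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing) > 0L) {
    stop("validation error: samples missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  if (is.null(stage_order)) stage_order <- unique(as.character(metadata$stage))
  metadata$stage <- factor(as.character(metadata$stage),
                           levels = stage_order, ordered = TRUE)
  if (anyNA(metadata$stage)) {
    stop("validation error: stage outside declared stage_order")
  }
  structure(list(values = values, kind = kind, metadata = metadata),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix (%s): %d features x %d samples, stages: %s\n",
              x$kind, nrow(x$values), ncol(x$values),
              paste(levels(x$metadata$stage), collapse = " < ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file has a feature-id first column and one column per sample;
#' the metadata file has columns `sample_id`, `stage`, `replicate`.
#'
#' @inheritParams expression_matrix
#' @param path Path to the matrix TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path, kind = c("counts", "TPM"),
                                   metadata_path, stage_order = NULL) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  expression_matrix(m, kind = kind, metadata = meta,
                    stage_order = stage_order)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' @param x An `expr_matrix`.
#' @param path Output path for the matrix.
#' @param metadata_path Optional output path for the metadata table.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- data.frame(feature_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- x$metadata
    meta$stage <- as.character(meta$stage)
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Per-stage replicate means
#'
#' Arithmetic mean of expression over the replicates of each stage, stage
#' order preserved.
#'
#' @param x An `expr_matrix`.
#' @return Numeric matrix, features x stages.
#' @export
stage_means <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  stages <- levels(x$metadata$stage)
  counts <- table(factor(x$metadata$stage, levels = stages))
  if (any(counts == 0L)) {
    stop("stage with no samples: ",
         paste(stages[counts == 0L], collapse = ", "))
  }
  out <- vapply(stages, function(s) {
    rowMeans(x$values[, x$metadata$stage == s, drop = FALSE])
  }, numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values), ncol = length(stages),
                dimnames = list(rownames(x$values), stages))
  out
}
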