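#' Construct an expression matrix
#'
#' A light container for a genes-by-samples numeric grid. Row names are gene
#' identifiers and column names are sample identifiers; both are treated as
#' opaque, case-sensitive strings. The `scale` flag records whether values
#' are on a linear FPKM/TPM/CPM-like scale (non-negative) or already
#' log2(x + 1) transformed (finite).
#'
#' @param values Numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids).
#' @param scale `"linear"` or `"log2p1"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `scale`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("G", 1:3), c("S1", "S2")))
#' x <- expression_matrix(m, "linear")
#' dim(x)
#' @export
expression_matrix <- function(values, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  if (scale == "linear") {
    if (anyNA(values) || any(!is.finite(values)))
      stop("linear-scale values must be finite and non-missing", call. = FALSE)
    if (any(values < 0))
      stop("linear-scale values must be >= 0", call. = FALSE)
  } else if (any(!is.finite(values))) {
    stop("log-scale values must be finite", call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# Internal: subset an ExpressionMatrix keeping the class and scale.
subset_expression <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, x$scale)
}

#' Validate a sample-metadata table
#'
#' Metadata is a plain `data.frame` with one row per sample. Required
#' columns: `sample_id` (unique) and `donor_id`. Any further columns hold
#' stratum labels (character/factor, e.g. dementia status, sex, brain
#' structure), donor age in years, or continuous marker values
#' (non-negative reals, `NA` when missing).
#'
#' @param metadata A data.frame.
#' @param expression Optional `ExpressionMatrix`; when given, every
#'   `sample_id` must be present among its sample ids.
#' @return `metadata`, invisibly, after validation.
#' @export
validate_metadata <- function(metadata, expression = NULL) {
  if (!is.data.frame(metadata))
    stop("metadata must be a data.frame", call. = FALSE)
  for (col in c("sample_id", "donor_id"))
    if (!col %in% names(metadata))
      stop("metadata lacks required column `", col, "`", call. = FALSE)
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  if (length(dup))
    stop("duplicate sample_id(s) in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!is.null(expression)) {
    missing <- setdiff(metadata$sample_id, sample_ids(expression))
    if (length(missing))
      stop("metadata sample(s) absent from expression matrix: ",
           paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  num_cols <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
  for (col in num_cols) {
    v <- metadata[[col]]
    if (any(!is.na(v) & !is.finite(v)))
      stop("metadata column `", col, "` contains non-finite values",
           call. = FALSE)
  }
  invisible(metadata)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene ids). Within-set
#'   duplicates are removed.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled empty when absent).
#' @return A `GeneSetCollection`: list with elements `sets` and
#'   `descriptions`, both named by set.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a named list of gene-id vectors", call. = FALSE)
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    stop("duplicate set name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop("empty gene set(s): ", paste(empty, collapse = ", "), call. = FALSE)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- as.character(descriptions)
  if (length(descriptions) != length(sets))
    stop("`descriptions` must match `sets` in length", call. = FALSE)
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, median size %d\n",
              length(x$sets), as.integer(stats::median(lengths(x$sets)))))
  invisible(x)
}
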