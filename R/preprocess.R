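#' Filter report
#'
#' Small record of what a gene filter did: how many genes came in, how many
#' survived, and a text description of the rule applied.
#'
#' @param n_input,n_kept Gene counts before and after.
#' @param rule Human-readable description of the threshold applied.
#' @return A `FilterReport` list.
#' @export
filter_report <- function(n_input, n_kept, rule) {
  n_input <- as.integer(n_input)
  n_kept <- as.integer(n_kept)
  if (n_kept < 0L || n_kept > n_input)
    stop("invalid filter report: 0 <= n_kept <= n_input violated",
         call. = FALSE)
  structure(list(n_input = n_input, n_kept = n_kept, rule = rule),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: kept %d / %d genes (%s)\n",
              x$n_kept, x$n_input, x$rule))
  invisible(x)
}

#' Log-transform a linear-scale expression matrix
#'
#' Applies `log2(x + pseudocount)` cell-wise, the standard preprocessing for
#' FPKM-like units before correlation analysis. Refuses to transform a
#' matrix already on the log scale (double-transform guard).
#'
#' @param x Linear-scale `ExpressionMatrix`.
#' @param pseudocount Positive offset added before the log (default 1, so
#'   zeros map to zero).
#' @return A `log2p1`-scale `ExpressionMatrix`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "linear")
    stop("matrix is already log scale; refusing to transform twice",
         call. = FALSE)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  expression_matrix(log2(x$values + pseudocount), "log2p1")
}

#' Keep genes whose mean expression exceeds a threshold
#'
#' Row means are computed on the linear scale and genes are kept only when
#' strictly above the threshold (a gene averaging exactly the threshold is
#' removed).
#'
#' @param x Linear-scale `ExpressionMatrix`.
#' @param threshold Mean-expression cutoff (e.g. 10 RPKM).
#' @return List with elements `matrix` (filtered) and `report`
#'   ([filter_report()]).
#' @export
mean_expression_filter <- function(x, threshold) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "linear")
    stop("mean_expression_filter expects a linear-scale matrix",
         call. = FALSE)
  keep <- rowMeans(x$values) > threshold
  out <- subset_expression(x, genes = which(keep))
  list(matrix = out,
       report = filter_report(nrow(x$values), sum(keep),
                              sprintf("row mean > %g", threshold)))
}

#' Average expression within donors
#'
#' Collapses multiple samples per donor to one column per donor (arithmetic
#' mean of that donor's sample columns, on whatever scale the matrix is on).
#' Donor columns come out in sorted order for determinism.
#'
#' @param x An `ExpressionMatrix`.
#' @param metadata Metadata data.frame mapping every sample to a `donor_id`.
#' @return An `ExpressionMatrix` with one column per donor.
#' @export
per_donor_average <- function(x, metadata) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  validate_metadata(metadata)
  sids <- sample_ids(x)
  idx <- match(sids, metadata$sample_id)
  if (anyNA(idx))
    stop("sample(s) without donor mapping: ",
         paste(head(sids[is.na(idx)], 5L), collapse = ", "), call. = FALSE)
  donors <- metadata$donor_id[idx]
  if (anyNA(donors))
    stop("sample(s) with missing donor_id: ",
         paste(head(sids[is.na(donors)], 5L), collapse = ", "), call. = FALSE)
  donor_levels <- sort(unique(donors), method = "radix")
  out <- vapply(donor_levels, function(d) {
    rowMeans(x$values[, donors == d, drop = FALSE])
  }, numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values)) # vapply drops dim for 1 gene
  dimnames(out) <- list(gene_ids(x), donor_levels)
  expression_matrix(out, x$scale)
}

#' Bin donor/sample ages into fixed-width intervals
#'
#' Bins are half-open `[k*width, (k+1)*width)` labelled
#' `"<lo>-<hi>"` (e.g. `"0-9"`, `"10-19"` for width 10). An optional
#' open-ended terminal bin (`open_from`) reproduces groupings like
#' "30+" for every age at or above the cut.
#'
#' @param metadata Metadata data.frame with an `age` column (years).
#' @param width_years Bin width (default 10).
#' @param open_from Optional age at which a single open-ended final bin
#'   (labelled `"<open_from>+"`) starts.
#' @return Named character vector: bin label per sample id. Samples with
#'   missing age are omitted with a warning.
#' @export
age_bin <- function(metadata, width_years = 10L, open_from = NULL) {
  if (!"age" %in% names(metadata))
    stop("metadata lacks an `age` column", call. = FALSE)
  width_years <- as.integer(width_years)
  stopifnot(width_years >= 1L)
  age <- metadata$age
  miss <- is.na(age)
  if (any(miss)) {
    warning(sprintf("age_bin: %d sample(s) with missing age omitted",
                    sum(miss)), call. = FALSE)
  }
  age_ok <- age[!miss]
  ids <- metadata$sample_id[!miss]
  k <- floor(age_ok / width_years)
  labels <- sprintf("%d-%d", k * width_years, (k + 1L) * width_years - 1L)
  if (!is.null(open_from)) {
    open <- age_ok >= open_from
    labels[open] <- sprintf("%d+", as.integer(open_from))
  }
  names(labels) <- ids
  labels
}

#' Counts-per-million expression filter
#'
#' Keeps genes expressed above `cpm_threshold` counts-per-million in at
#' least `min(group_sizes) - 1` samples (the smallest-group-minus-one
#' convention for grouped RNA-seq designs; floored at one sample so that
#' genes expressed nowhere never survive).
#'
#' @param counts Linear-scale `ExpressionMatrix` of non-negative raw counts.
#' @param group_sizes Integer vector of per-group sample counts.
#' @param cpm_threshold CPM cutoff, strict (default 1).
#' @return List with `matrix` (filtered) and `report`.
#' @export
cpm_filter <- function(counts, group_sizes, cpm_threshold = 1) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$scale != "linear")
    stop("cpm_filter expects linear-scale raw counts", call. = FALSE)
  group_sizes <- as.integer(group_sizes)
  if (!length(group_sizes) || any(group_sizes < 1L))
    stop("`group_sizes` must contain >= 1 positive group size", call. = FALSE)
  lib <- colSums(counts$values)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(head(sample_ids(counts)[lib == 0], 5L), collapse = ", "),
         call. = FALSE)
  cpm <- sweep(counts$values, 2L, lib, "/") * 1e6
  min_samples <- max(min(group_sizes) - 1L, 1L)
  keep <- rowSums(cpm > cpm_threshold) >= min_samples
  list(matrix = subset_expression(counts, genes = which(keep)),
       report = filter_report(nrow(counts$values), sum(keep),
                              sprintf("CPM > %g in >= %d samples",
                                      cpm_threshold, min_samples)))
}

#' Fold-change / p-value gene filter
#'
#' Splits a per-gene effect table into up- and down-regulated calls using
#' strict thresholds: up when `fc > fc_threshold` and `p < p_threshold`,
#' down when `fc < 1/fc_threshold` and `p < p_threshold`. Boundary values
#' are excluded.
#'
#' @param effects Data.frame with columns `gene_id`, `fc` (fold change,
#'   > 0) and `p` (in `[0, 1]`).
#' @param fc_threshold Fold-change cutoff (default 1.5).
#' @param p_threshold p-value cutoff (default 0.05).
#' @return List with `up`, `down` (gene-id vectors) and `report`.
#' @export
fc_p_filter <- function(effects, fc_threshold = 1.5, p_threshold = 0.05) {
  for (col in c("gene_id", "fc", "p"))
    if (!col %in% names(effects))
      stop("`effects` lacks column `", col, "`", call. = FALSE)
  if (any(effects$fc <= 0))
    stop("fold changes must be > 0", call. = FALSE)
  if (any(effects$p < 0 | effects$p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  up <- effects$fc > fc_threshold & effects$p < p_threshold
  down <- effects$fc < 1 / fc_threshold & effects$p < p_threshold
  list(up = effects$gene_id[up],
       down = effects$gene_id[down],
       report = filter_report(nrow(effects), sum(up) + sum(down),
                              sprintf("FC > %g (or < 1/%g) and p < %g",
                                      fc_threshold, fc_threshold,
                                      p_threshold)))
}
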