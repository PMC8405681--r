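# Guide-gene ranking: correlate one anchor transcript against the rest of
# the transcriptome within a sample stratum, order by r, and z-score the
# correlation vector to obtain the pre-ranked enrichment statistic.

new_ranked_profile <- function(guide_id, stratum, entries, n_samples,
                               excluded) {
  structure(list(guide_id = guide_id, stratum = stratum, entries = entries,
                 n_samples = n_samples, excluded = excluded),
            class = "RankedProfile")
}

#' @export
print.RankedProfile <- function(x, ...) {
  cat(sprintf(
    "RankedProfile: guide %s, stratum `%s`, %d genes over %d samples (%d excluded)\n",
    x$guide_id, x$stratum, nrow(x$entries), x$n_samples, nrow(x$excluded)))
  invisible(x)
}

#' @export
as.data.frame.RankedProfile <- function(x, ...) x$entries

# Internal: resolve a sample filter against metadata.
# `filter` is NULL (all samples), a named character vector/list of
# label = value equality constraints, or a predicate function on the
# metadata data.frame returning a logical vector.
resolve_samples <- function(x, metadata, filter) {
  sids <- sample_ids(x)
  if (is.null(filter)) return(sids)
  if (is.function(filter)) {
    if (is.null(metadata))
      stop("a sample filter requires metadata", call. = FALSE)
    keep <- filter(metadata)
    if (!is.logical(keep) || length(keep) != nrow(metadata))
      stop("filter function must return one logical per metadata row",
           call. = FALSE)
    return(intersect(sids, metadata$sample_id[keep %in% TRUE]))
  }
  filter <- unlist(filter)
  if (is.null(names(filter)) || any(!nzchar(names(filter))))
    stop("sample filter must be named label = value pairs or a function",
         call. = FALSE)
  if (is.null(metadata))
    stop("a sample filter requires metadata", call. = FALSE)
  keep <- rep(TRUE, nrow(metadata))
  for (label in names(filter)) {
    if (!label %in% names(metadata))
      stop("unknown stratum label `", label, "` in sample filter",
           call. = FALSE)
    keep <- keep & !is.na(metadata[[label]]) &
      metadata[[label]] == filter[[label]]
  }
  intersect(sids, metadata$sample_id[keep])
}

format_filter_label <- function(filter) {
  if (is.null(filter)) return("all")
  if (is.function(filter)) return("custom")
  f <- unlist(filter)
  paste(sprintf("%s=%s", names(f), f), collapse = ",")
}

#' Correlate a guide gene against the whole transcriptome
#'
#' Computes the Pearson correlation between the guide transcript and every
#' other gene over a (possibly stratified) set of samples, then orders
#' genes by descending r with ties broken by gene id. The guide itself is
#' excluded from the ranking, as are genes with zero variance (undefined r)
#' or missing values, each recorded with a reason. The centred/scaled
#' statistic `z` is left `NA` until [center_scale()] is applied.
#'
#' @param x Log-scale `ExpressionMatrix` (apply [log_transform()] first).
#' @param guide_id Gene id of the guide transcript.
#' @param metadata Optional metadata data.frame (required when filtering).
#' @param sample_filter `NULL` for all samples, named `label = value`
#'   pairs matched against metadata columns, or a predicate function.
#' @param stratum Optional label stored on the profile (defaults to a
#'   rendering of the filter).
#' @return A `RankedProfile`.
#' @export
guide_correlation_profile <- function(x, guide_id, metadata = NULL,
                                      sample_filter = NULL, stratum = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "log2p1")
    stop("expected a log-scale matrix; apply log_transform() first",
         call. = FALSE)
  if (!guide_id %in% gene_ids(x))
    stop("guide gene `", guide_id, "` absent from expression matrix",
         call. = FALSE)
  samples <- resolve_samples(x, metadata, sample_filter)
  if (length(samples) < 3L)
    stop(sprintf("need >= 3 samples after filtering, got %d",
                 length(samples)), call. = FALSE)
  if (is.null(stratum)) stratum <- format_filter_label(sample_filter)

  v <- x$values[, samples, drop = FALSE]
  g <- v[guide_id, ]
  if (stats::sd(g) == 0)
    stop("guide gene has zero variance in the selected samples",
         call. = FALSE)
  others <- setdiff(rownames(v), guide_id)
  ov <- v[others, , drop = FALSE]
  r <- suppressWarnings(as.vector(stats::cor(g, t(ov))))
  names(r) <- others

  row_var <- rowSums((ov - rowMeans(ov))^2)
  reason <- rep(NA_character_, length(others))
  reason[is.na(r) & row_var == 0] <- "zero-variance"
  reason[is.na(r) & row_var != 0] <- "missing"
  excluded <- data.frame(gene_id = c(guide_id, others[!is.na(reason)]),
                         reason = c("guide", reason[!is.na(reason)]),
                         stringsAsFactors = FALSE)

  keep <- is.na(reason)
  gid <- others[keep]
  rv <- r[keep]
  ord <- order(-rv, gid, method = "radix")
  entries <- data.frame(gene_id = gid[ord], r = unname(rv[ord]),
                        z = NA_real_, rank = seq_along(ord),
                        stringsAsFactors = FALSE)
  new_ranked_profile(guide_id, stratum, entries, length(samples), excluded)
}

#' Centre and scale a correlation profile
#'
#' Fills the `z` column of a `RankedProfile`: `z = (r - mean(r)) / sd(r)`
#' with the sample (n - 1) standard deviation. The resulting signed
#' statistic feeds pre-ranked enrichment, so pathways depleted with the
#' guide receive negative scores.
#'
#' @param profile A `RankedProfile` with >= 2 entries.
#' @return The profile with `z` filled; order unchanged.
#' @export
center_scale <- function(profile) {
  stopifnot(inherits(profile, "RankedProfile"))
  r <- profile$entries$r
  if (length(r) < 2L)
    stop("need >= 2 entries to centre and scale", call. = FALSE)
  s <- stats::sd(r)
  if (s == 0)
    stop("degenerate profile: all correlations identical (sd = 0)",
         call. = FALSE)
  profile$entries$z <- (r - mean(r)) / s
  profile
}

#' Select genes from the top of a ranked profile
#'
#' Three selection rules: a fixed count of top genes (`top_count`), a
#' fraction of the list (`top_fraction`, floor of fraction times list
#' length), or all genes with correlation strictly above a cutoff
#' (`r_cutoff`). Because profile entries are deterministically ordered
#' (r descending, gene id ascending on ties), boundary ties resolve
#' reproducibly.
#'
#' @param profile A `RankedProfile`.
#' @param rule `"top_count"`, `"top_fraction"`, or `"r_cutoff"`.
#' @param parameter Count (>= 1), fraction in (0, 1], or cutoff in (-1, 1).
#' @return A `GeneSelection`: list with `rule`, `parameter`, `genes`
#'   (ordered gene ids).
#' @export
select_genes <- function(profile,
                         rule = c("top_count", "top_fraction", "r_cutoff"),
                         parameter) {
  stopifnot(inherits(profile, "RankedProfile"))
  rule <- match.arg(rule)
  e <- profile$entries
  genes <- switch(rule,
    top_count = {
      if (parameter < 1) stop("top_count needs a count >= 1", call. = FALSE)
      e$gene_id[seq_len(min(as.integer(parameter), nrow(e)))]
    },
    top_fraction = {
      if (parameter <= 0 || parameter > 1)
        stop("top_fraction needs a fraction in (0, 1]", call. = FALSE)
      e$gene_id[seq_len(floor(parameter * nrow(e)))]
    },
    r_cutoff = {
      if (parameter <= -1 || parameter >= 1)
        stop("r_cutoff needs a cutoff in (-1, 1)", call. = FALSE)
      e$gene_id[e$r > parameter]
    })
  structure(list(rule = rule, parameter = parameter, genes = genes),
            class = "GeneSelection")
}

#' @export
print.GeneSelection <- function(x, ...) {
  cat(sprintf("GeneSelection: %d genes (%s, parameter %g)\n",
              length(x$genes), x$rule, x$parameter))
  invisible(x)
}

#' Binned correlation heat-map matrix
#'
#' Reduces a genes-by-samples matrix to a grid of bin-by-bin averages of
#' per-gene z-scores, with genes ordered by their correlation to the guide
#' (descending) and samples ordered by guide expression (descending).
#' Incomplete trailing bins are dropped. This is the numeric backbone of a
#' guide-centred correlation heat map where each pixel averages, e.g., ten
#' genes by ten samples.
#'
#' @param x `ExpressionMatrix` (typically pre-filtered by
#'   [mean_expression_filter()] and log transformed).
#' @param profile `RankedProfile` providing the gene order and guide id.
#' @param bin Bin edge length in genes and samples (default 10).
#' @return Numeric matrix of dimension
#'   `floor(n_genes/bin) x floor(n_samples/bin)`.
#' @export
binned_heatmap_matrix <- function(x, profile, bin = 10L) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            inherits(profile, "RankedProfile"))
  bin <- as.integer(bin)
  stopifnot(bin >= 1L)
  if (!profile$guide_id %in% gene_ids(x))
    stop("guide gene absent from matrix; cannot order samples",
         call. = FALSE)
  genes <- profile$entries$gene_id[profile$entries$gene_id %in% gene_ids(x)]
  g <- x$values[profile$guide_id, ]
  sample_ord <- order(-g, names(g), method = "radix")
  v <- x$values[genes, sample_ord, drop = FALSE]
  if (nrow(v) < bin || ncol(v) < bin)
    stop(sprintf("need at least one full %dx%d bin, got %d genes x %d samples",
                 bin, bin, nrow(v), ncol(v)), call. = FALSE)
  mu <- rowMeans(v)
  sdev <- apply(v, 1L, stats::sd)
  degenerate <- rownames(v)[sdev == 0]
  if (length(degenerate))
    stop("zero variance (cannot z-score) for gene(s): ",
         paste(head(degenerate, 5L), collapse = ", "), call. = FALSE)
  z <- (v - mu) / sdev
  n_gb <- nrow(z) %/% bin
  n_sb <- ncol(z) %/% bin
  out <- matrix(NA_real_, n_gb, n_sb)
  for (i in seq_len(n_gb)) {
    rows <- ((i - 1L) * bin + 1L):(i * bin)
    for (j in seq_len(n_sb)) {
      cols <- ((j - 1L) * bin + 1L):(j * bin)
      out[i, j] <- mean(z[rows, cols])
    }
  }
  out
}

#' Cross-structure correlation of one gene's expression
#'
#' For a cohort where each donor contributes samples from several brain
#' structures (or other anatomical units), computes the Pearson correlation
#' of a gene's expression between every pair of structures on donor-matched
#' values (per-donor means within each structure). Pairs with fewer than 3
#' shared donors are reported `NA` with a warning.
#'
#' @param x An `ExpressionMatrix`.
#' @param metadata Metadata with `donor_id` and a structure column.
#' @param gene_id Gene to analyse.
#' @param structure_label Name of the metadata column holding the
#'   structure of each sample.
#' @return Symmetric correlation matrix (unit diagonal) over structures.
#' @export
cross_structure_correlation <- function(x, metadata, gene_id,
                                        structure_label) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  validate_metadata(metadata)
  if (!structure_label %in% names(metadata))
    stop("metadata lacks structure column `", structure_label, "`",
         call. = FALSE)
  if (!gene_id %in% gene_ids(x))
    stop("gene `", gene_id, "` absent from expression matrix", call. = FALSE)
  md <- metadata[metadata$sample_id %in% sample_ids(x) &
                   !is.na(metadata[[structure_label]]), , drop = FALSE]
  structures <- sort(unique(md[[structure_label]]), method = "radix")
  expr <- x$values[gene_id, md$sample_id]
  # donor x structure means
  donor_means <- lapply(structures, function(s) {
    sel <- md[[structure_label]] == s
    tapply(expr[sel], md$donor_id[sel], mean)
  })
  names(donor_means) <- structures
  n <- length(structures)
  out <- matrix(NA_real_, n, n, dimnames = list(structures, structures))
  diag(out) <- 1
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- donor_means[[i]]
      b <- donor_means[[j]]
      shared <- intersect(names(a), names(b))
      if (length(shared) < 3L) {
        warning(sprintf(
          "cross_structure_correlation: pair %s/%s omitted (%d shared donors)",
          structures[i], structures[j], length(shared)), call. = FALSE)
        next
      }
      out[i, j] <- out[j, i] <- stats::cor(a[shared], b[shared])
    }
  }
  out
}
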