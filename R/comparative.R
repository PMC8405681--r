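# Cross-stratum comparisons: Venn overlaps of top gene lists, overlap-
# coefficient similarity, correlation-distribution tests, median-split
# marker association, and bivariate guide-marker correlation.

as_gene_list <- function(x) {
  if (inherits(x, "GeneSelection")) x$genes else as.character(x)
}

#' Venn overlap of two or three gene lists
#'
#' Exact region counts by set arithmetic, plus pairwise overlap
#' coefficients (`|A n B| / min(|A|, |B|)`) and Jaccard indices. Region
#' counts are keyed by canonical positional labels (`A_only`, `AB`,
#' `ABC`, ...). Empty lists yield coefficients of 0 with a flag.
#'
#' @param lists Named list of 2 or 3 gene-id vectors (or `GeneSelection`
#'   objects). Duplicates within a list are removed with a warning.
#' @return An `OverlapReport`: list with `list_names`, `sizes`,
#'   `region_counts`, `pairwise` (data.frame), and for two lists also
#'   top-level `overlap_coefficient` and `jaccard`, plus `flags`.
#' @export
venn_overlap <- function(lists) {
  if (!is.list(lists) || !(length(lists) %in% c(2L, 3L)))
    stop("venn_overlap needs a list of 2 or 3 gene lists", call. = FALSE)
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    names(lists) <- LETTERS[seq_along(lists)]
  lists <- lapply(lists, as_gene_list)
  for (nm in names(lists)) {
    if (anyDuplicated(lists[[nm]])) {
      warning("duplicates removed from list `", nm, "`", call. = FALSE)
      lists[[nm]] <- unique(lists[[nm]])
    }
  }
  flags <- character(0)
  if (any(lengths(lists) == 0L))
    flags <- c(flags, "empty-list")

  n <- length(lists)
  letters_here <- LETTERS[seq_len(n)]
  universe <- unique(unlist(lists, use.names = FALSE))
  membership <- vapply(lists, function(g) universe %in% g,
                       logical(length(universe)))
  if (length(universe) == 0L)
    membership <- matrix(logical(0), 0L, n)
  region_of <- apply(membership, 1L, function(m)
    paste(letters_here[m], collapse = ""))
  all_regions <- unlist(lapply(seq_len(n), function(k)
    apply(combn(letters_here, k), 2L, paste, collapse = "")))
  region_counts <- vapply(all_regions, function(r)
    sum(region_of == r), integer(1))
  names(region_counts) <- ifelse(nchar(all_regions) == 1L,
                                 paste0(all_regions, "_only"), all_regions)

  pairs <- combn(names(lists), 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- lists[[pairs[1L, j]]]
    b <- lists[[pairs[2L, j]]]
    shared <- length(intersect(a, b))
    uni <- length(union(a, b))
    mn <- min(length(a), length(b))
    data.frame(list_a = pairs[1L, j], list_b = pairs[2L, j],
               n_a = length(a), n_b = length(b), intersection = shared,
               overlap_coefficient = if (mn > 0) shared / mn else 0,
               jaccard = if (uni > 0) shared / uni else 0,
               stringsAsFactors = FALSE)
  }))
  out <- list(list_names = names(lists), sizes = lengths(lists),
              region_counts = region_counts, pairwise = pairwise,
              flags = flags)
  if (n == 2L) {
    out$overlap_coefficient <- pairwise$overlap_coefficient[1L]
    out$jaccard <- pairwise$jaccard[1L]
  }
  structure(out, class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf("OverlapReport: %s\n", paste(x$list_names, collapse = " / ")))
  print(x$region_counts)
  invisible(x)
}

#' Pairwise overlap-coefficient similarity matrix
#'
#' Symmetric matrix of overlap coefficients
#' (`|A n B| / min(|A|, |B|)`) across named gene lists, unit diagonal.
#' This coefficient substitutes for proprietary between-group pathway
#' similarity scores; by the conventional annotation, values above 0.1
#' indicate substantial overlap between groups.
#'
#' @param lists Named list (>= 2) of gene-id vectors or `GeneSelection`s.
#' @return Numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop("similarity_matrix needs >= 2 lists", call. = FALSE)
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    names(lists) <- LETTERS[seq_along(lists)]
  lists <- lapply(lists, function(x) unique(as_gene_list(x)))
  n <- length(lists)
  out <- diag(1, n)
  dimnames(out) <- list(names(lists), names(lists))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mn <- min(length(lists[[i]]), length(lists[[j]]))
    shared <- length(intersect(lists[[i]], lists[[j]]))
    out[i, j] <- out[j, i] <- if (mn > 0) shared / mn else 0
  }
  out
}

#' Compare two correlation-coefficient distributions
#'
#' Two-sided two-sample test on the correlation values of two top-gene
#' selections (e.g. the top 1% in two strata), reporting the difference of
#' medians as the effect size. Degenerate all-equal inputs yield p = 1
#' with a flag.
#'
#' @param r_a,r_b Numeric vectors of correlation coefficients (>= 10 each).
#' @param test `"mann_whitney"` (default) or `"welch_t"`.
#' @return List with `statistic`, `p_value`, `median_difference`
#'   (median(a) - median(b)), `test`, `flag`.
#' @export
compare_r_distributions <- function(r_a, r_b,
                                    test = c("mann_whitney", "welch_t")) {
  test <- match.arg(test)
  r_a <- as.numeric(r_a)
  r_b <- as.numeric(r_b)
  if (length(r_a) < 10L || length(r_b) < 10L)
    stop("need >= 10 values per side", call. = FALSE)
  med_diff <- stats::median(r_a) - stats::median(r_b)
  if (length(unique(c(r_a, r_b))) == 1L) {
    return(list(statistic = NA_real_, p_value = 1,
                median_difference = med_diff, test = test,
                flag = "degenerate-all-equal"))
  }
  ht <- if (test == "mann_whitney") {
    suppressWarnings(stats::wilcox.test(r_a, r_b, alternative = "two.sided",
                                        exact = FALSE))
  } else {
    stats::t.test(r_a, r_b, alternative = "two.sided", var.equal = FALSE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       median_difference = med_diff, test = test, flag = NA_character_)
}

#' Split samples at the median of guide expression
#'
#' Dichotomizes a stratum's samples into `Lo` (guide expression below the
#' median, with values equal to the median assigned to Lo — a deterministic,
#' conservative rule) and `Hi` (above the median). With an even number of
#' distinct values the halves are equal.
#'
#' @param guide_expr Named numeric vector: guide expression per sample id.
#' @param metadata Optional metadata (needed when `stratum` is given).
#' @param stratum Optional named `label = value` filter restricting samples.
#' @param guide_id Optional guide gene id recorded on the report.
#' @return A `MedianSplitReport`: list with `guide_id`, `stratum`,
#'   `median`, `lo_samples`, `hi_samples`; `tests` is filled by
#'   [marker_tests()].
#' @export
median_split <- function(guide_expr, metadata = NULL, stratum = NULL,
                         guide_id = NA_character_) {
  if (is.null(names(guide_expr)))
    stop("`guide_expr` must be named by sample id", call. = FALSE)
  label <- "all"
  if (!is.null(stratum)) {
    if (is.null(metadata))
      stop("a stratum filter requires metadata", call. = FALSE)
    f <- unlist(stratum)
    keep <- rep(TRUE, nrow(metadata))
    for (lab in names(f)) {
      if (!lab %in% names(metadata))
        stop("unknown stratum label `", lab, "`", call. = FALSE)
      keep <- keep & !is.na(metadata[[lab]]) & metadata[[lab]] == f[[lab]]
    }
    guide_expr <- guide_expr[names(guide_expr) %in%
                               metadata$sample_id[keep]]
    label <- paste(sprintf("%s=%s", names(f), f), collapse = ",")
  }
  if (length(guide_expr) < 4L)
    stop("need >= 4 samples in the stratum", call. = FALSE)
  if (length(unique(guide_expr)) == 1L)
    stop("all guide expression values identical; median split undefined",
         call. = FALSE)
  med <- stats::median(guide_expr)
  lo <- names(guide_expr)[guide_expr <= med]
  hi <- names(guide_expr)[guide_expr > med]
  structure(list(guide_id = guide_id, stratum = label, median = med,
                 lo_samples = lo, hi_samples = hi, tests = NULL),
            class = "MedianSplitReport")
}

#' @export
print.MedianSplitReport <- function(x, ...) {
  cat(sprintf("MedianSplitReport: stratum `%s`, Lo n=%d / Hi n=%d (median %.4g)\n",
              x$stratum, length(x$lo_samples), length(x$hi_samples),
              x$median))
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}

#' @export
as.data.frame.MedianSplitReport <- function(x, ...) {
  if (is.null(x$tests))
    data.frame(stratum = x$stratum, n_lo = length(x$lo_samples),
               n_hi = length(x$hi_samples), median = x$median,
               stringsAsFactors = FALSE)
  else x$tests
}

#' Test continuous markers between Lo and Hi groups
#'
#' For each marker column, compares values between the Lo and Hi sample
#' groups of a median split with a two-sided two-sample test (Welch t by
#' default, Mann-Whitney as the nonparametric option). Missing marker
#' values are dropped pairwise; markers with fewer than 3 observed values
#' in either group are flagged and not tested; markers absent from the
#' metadata are skipped with a warning.
#'
#' @param report A `MedianSplitReport` (groups formed).
#' @param metadata Metadata data.frame holding the marker columns.
#' @param markers Character vector of marker column names; default all
#'   numeric metadata columns except `age`.
#' @param test `"welch_t"` (default) or `"mann_whitney"`.
#' @return The report with `tests` filled: a data.frame with one row per
#'   marker (`marker`, `n_lo`, `n_hi`, `mean_lo`, `mean_hi`, `statistic`,
#'   `p_value`, `flag`).
#' @export
marker_tests <- function(report, metadata, markers = NULL,
                         test = c("welch_t", "mann_whitney")) {
  stopifnot(inherits(report, "MedianSplitReport"))
  test <- match.arg(test)
  if (is.null(markers)) {
    num <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
    markers <- setdiff(num, c("age"))
  }
  present <- markers %in% names(metadata)
  if (any(!present)) {
    warning("marker(s) absent from metadata, skipped: ",
            paste(markers[!present], collapse = ", "), call. = FALSE)
    markers <- markers[present]
  }
  rows <- lapply(markers, function(m) {
    v <- metadata[[m]]
    names(v) <- metadata$sample_id
    lo <- v[report$lo_samples]
    hi <- v[report$hi_samples]
    lo <- lo[!is.na(lo)]
    hi <- hi[!is.na(hi)]
    base <- data.frame(marker = m, n_lo = length(lo), n_hi = length(hi),
                       mean_lo = if (length(lo)) mean(lo) else NA_real_,
                       mean_hi = if (length(hi)) mean(hi) else NA_real_,
                       statistic = NA_real_, p_value = NA_real_,
                       flag = NA_character_, stringsAsFactors = FALSE)
    if (length(lo) < 3L || length(hi) < 3L) {
      base$flag <- "insufficient-values"
      return(base)
    }
    if (length(unique(c(lo, hi))) == 1L) {
      base$flag <- "degenerate-all-equal"
      base$p_value <- 1
      return(base)
    }
    ht <- if (test == "welch_t") {
      stats::t.test(lo, hi, alternative = "two.sided", var.equal = FALSE)
    } else {
      suppressWarnings(stats::wilcox.test(lo, hi,
                                          alternative = "two.sided",
                                          exact = FALSE))
    }
    base$statistic <- unname(ht$statistic)
    base$p_value <- ht$p.value
    base
  })
  report$tests <- do.call(rbind, rows)
  report
}

#' Correlate guide expression with a continuous marker
#'
#' Pearson (default) or Spearman correlation on complete pairs, with a
#' two-sided p-value.
#'
#' @param guide_expr,marker Numeric vectors of equal length (pairs with
#'   missing values dropped).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p_value`, `n` (complete pairs used).
#' @export
guide_marker_correlation <- function(guide_expr, marker,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(guide_expr) != length(marker))
    stop("`guide_expr` and `marker` must have equal length", call. = FALSE)
  ok <- !is.na(guide_expr) & !is.na(marker)
  if (sum(ok) < 3L)
    stop("need >= 3 complete pairs", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(guide_expr[ok], marker[ok], method = method,
                    alternative = "two.sided", exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
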