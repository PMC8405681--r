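#' Read a gene-by-sample expression table
#'
#' Expects a tab-separated UTF-8 file: the first column holds gene ids, the
#' header row holds sample ids. All cells must parse as numbers; duplicate
#' gene or sample ids are an error.
#'
#' @param path File path.
#' @param scale Scale of the stored values, `"linear"` or `"log2p1"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("malformed expression file `", path,
         "`: need a gene-id column plus >= 1 sample column", call. = FALSE)
  gene_col <- tab[[1L]]
  dup <- unique(gene_col[duplicated(gene_col)])
  if (length(dup))
    stop("duplicate gene id(s) in `", path, "`: ",
         paste(dup, collapse = ", "), call. = FALSE)
  samples <- names(tab)[-1L]
  values <- matrix(NA_real_, nrow = nrow(tab), ncol = length(samples),
                   dimnames = list(gene_col, samples))
  for (j in seq_along(samples)) {
    raw <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(is.na(raw) | raw %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("non-numeric cell in `%s`: row `%s`, column `%s` (value `%s`)",
                   path, gene_col[bad[1L]], samples[j], raw[bad[1L]]),
           call. = FALSE)
    values[, j] <- num
  }
  expression_matrix(values, scale)
}

#' Write an expression matrix as TSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output file path.
#' @param digits Significant digits for serialized values (default 17,
#'   which round-trips doubles exactly).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, digits = 17L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = gene_ids(x),
                   apply(x$values, 2L, function(v) sprintf("%.*g", digits, v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", sample_ids(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Tab-separated with a header; must contain `sample_id` and `donor_id`
#' columns. Empty cells become `NA` and are propagated as missing (never
#' zero). Columns that parse fully as numbers are kept numeric.
#'
#' @param path File path.
#' @return A validated metadata `data.frame` (see [validate_metadata()]).
#' @export
read_metadata <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
  validate_metadata(tab)
  tab
}

#' Write a sample-metadata table as TSV
#' @param metadata Metadata data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated (the MSigDB dialect). Within-set duplicate genes are
#' removed and their count reported via `message()`; a line with fewer than
#' three fields is a parse error naming the line.
#'
#' @param path File path.
#' @return A [gene_set_collection()], with attribute
#'   `n_duplicates_removed`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  nm <- character(length(lines))
  desc <- character(length(lines))
  sets <- vector("list", length(lines))
  n_dup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[!(seq_along(f) > 2L & !nzchar(f))] # trailing empty fields
    if (length(f) < 3L)
      stop(sprintf("GMT parse error in `%s` at line %d: expected >= 3 tab-separated fields, got %d",
                   path, i, length(f)), call. = FALSE)
    genes <- f[-(1:2)]
    u <- unique(genes)
    n_dup <- n_dup + length(genes) - length(u)
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- u
  }
  names(sets) <- nm
  out <- gene_set_collection(sets, desc)
  if (n_dup > 0L)
    message(sprintf("read_gmt: removed %d within-set duplicate gene entr%s",
                    n_dup, if (n_dup == 1L) "y" else "ies"))
  attr(out, "n_duplicates_removed") <- n_dup
  out
}

#' Write a gene-set collection to GMT
#' @param collection A `GeneSetCollection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Internal: render a data.frame with numeric columns at fixed precision.
format_result_frame <- function(df, digits) {
  for (col in names(df)) {
    if (is.double(df[[col]]))
      df[[col]] <- sprintf("%.*g", digits, df[[col]])
  }
  df
}

#' Write a tabular result as TSV
#'
#' Serializes enrichment tables, ranked profiles, or any data.frame-like
#' result with a header row, floats at fixed significant-digit precision and
#' a deterministic row order: tables carrying `p_adjusted` and `set_name`
#' columns are ordered by adjusted p, ties broken by name; other tables keep
#' their input order.
#'
#' @param table A data.frame, `RankedProfile`, or `MedianSplitReport`
#'   (its tests table).
#' @param path Output file path.
#' @param digits Significant digits for floats (default 7).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, digits = 7L) {
  df <- as.data.frame(table)
  if (all(c("p_adjusted", "set_name") %in% names(df)) && nrow(df))
    df <- df[order(df$p_adjusted, df$set_name, method = "radix"), ,
             drop = FALSE]
  df <- format_result_frame(df, digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a TSV result written by [write_results()]
#' @param path File path.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", quote = "",
             check.names = FALSE, stringsAsFactors = FALSE,
             na.strings = c("NA"))
}
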