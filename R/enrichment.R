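# Pre-ranked gene-set enrichment, implemented from scratch: weighted
# running-sum enrichment score (ES), gene-permutation null, signed-side
# NES normalization, nominal p with the +1 correction, BH adjustment.

#' Enrichment configuration
#'
#' @param weight_exponent Weight `w` applied to the ranking statistic in
#'   the hit increments (`|s|^w`); 0 gives the unweighted Kolmogorov-
#'   Smirnov-like statistic, 1 (default) the standard weighted form.
#' @param n_permutations Number `K` of random same-size gene sets drawn for
#'   the null (default 10000, minimum 100).
#' @param min_set_size,max_set_size Set-size window applied after
#'   restriction to measured genes (defaults 15 and 500).
#' @param seed Integer seed driving all permutation draws.
#' @return An `EnrichmentConfig` list.
#' @export
enrichment_config <- function(weight_exponent = 1, n_permutations = 10000L,
                              min_set_size = 15L, max_set_size = 500L,
                              seed = 1L) {
  n_permutations <- as.integer(n_permutations)
  min_set_size <- as.integer(min_set_size)
  max_set_size <- as.integer(max_set_size)
  if (weight_exponent < 0) stop("weight_exponent must be >= 0", call. = FALSE)
  if (n_permutations < 100L)
    stop("n_permutations must be >= 100", call. = FALSE)
  if (min_set_size > max_set_size)
    stop("min_set_size must be <= max_set_size", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = n_permutations,
                 min_set_size = min_set_size, max_set_size = max_set_size,
                 seed = seed),
            class = "EnrichmentConfig")
}

#' Restrict a collection and profile to each other
#'
#' Two-sided restriction: each gene set is intersected with the ranked
#' genes and dropped when its measured size falls outside
#' `[min_set_size, max_set_size]`; the ranked list is then restricted to
#' genes appearing in at least one retained set, and re-ranked.
#'
#' @param collection A `GeneSetCollection`.
#' @param profile A `RankedProfile`.
#' @param min_set_size,max_set_size Measured-size window (defaults 15, 500).
#' @return List with `collection` (restricted), `profile` (restricted,
#'   re-ranked) and `log` (data.frame of per-set sizes and retention).
#' @export
restrict_to_measured <- function(collection, profile, min_set_size = 15L,
                                 max_set_size = 500L) {
  stopifnot(inherits(collection, "GeneSetCollection"),
            inherits(profile, "RankedProfile"))
  ranked <- profile$entries$gene_id
  inter <- lapply(collection$sets, function(g) g[g %in% ranked])
  size_after <- lengths(inter)
  kept <- size_after >= min_set_size & size_after <= max_set_size
  log <- data.frame(set_name = names(collection$sets),
                    size_before = lengths(collection$sets),
                    size_measured = unname(size_after),
                    kept = unname(kept),
                    stringsAsFactors = FALSE)
  if (!any(kept))
    stop("no gene set overlaps the ranked list within the size window",
         call. = FALSE)
  kept_sets <- inter[kept]
  universe <- unique(unlist(kept_sets, use.names = FALSE))
  keep_entry <- profile$entries$gene_id %in% universe
  entries <- profile$entries[keep_entry, , drop = FALSE]
  entries$rank <- seq_len(nrow(entries))
  rownames(entries) <- NULL
  restricted_profile <- new_ranked_profile(profile$guide_id, profile$stratum,
                                           entries, profile$n_samples,
                                           profile$excluded)
  list(collection = gene_set_collection(
         kept_sets, collection$descriptions[names(kept_sets)]),
       profile = restricted_profile,
       log = log)
}

# Internal: ES evaluated only at hit positions. `aw` is the full vector of
# |s|^w over the ranked list, `pos` the sorted positions of set members.
# The running sum is piecewise linear between hits, so its extrema occur
# just after a hit (`top`) or just before one (`bot`). When the positive
# and negative extreme magnitudes tie (to within floating tolerance) the
# ES is 0 — the convention of reference GSEA implementations, which keeps
# the score antisymmetric under list reversal.
es_at_hits <- function(aw, pos, N) {
  k <- length(pos)
  w <- aw[pos]
  denom <- sum(w)
  if (denom == 0) { # all weights zero at hits: fall back to equal weights
    w <- rep.int(1, k)
    denom <- k
  }
  cw <- cumsum(w) / denom
  miss <- (pos - seq_len(k)) / (N - k)
  top <- cw - miss
  bot <- c(0, cw[-k]) - miss
  i_max <- which.max(top)
  i_min <- which.min(bot)
  mx <- top[i_max]
  mn <- bot[i_min]
  if (abs(mx + mn) <= 1e-12 * max(1, abs(mx)))
    list(ES = 0, hit_index = i_max, positive = NA)
  else if (mx >= -mn)
    list(ES = mx, hit_index = i_max, positive = TRUE)
  else
    list(ES = mn, hit_index = i_min, positive = FALSE)
}

# Internal: extract the ranking statistic from a profile.
profile_statistic <- function(profile, statistic = c("z", "rank")) {
  statistic <- match.arg(statistic)
  n <- nrow(profile$entries)
  if (statistic == "z") {
    s <- profile$entries$z
    if (anyNA(s))
      stop("profile has no centred/scaled statistic; run center_scale() first",
           call. = FALSE)
    s
  } else {
    rev(seq_len(n)) - (n + 1) / 2 # centred descending ranks
  }
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom accumulating `|s|^w` (relative
#' to the set total) on set members and `1/(N - k)` on non-members; the ES
#' is the value of the hit-minus-miss running sum at its maximum absolute
#' deviation, signed. The leading edge contains the set members at or
#' before the extremum (at or after it, for a negative ES).
#'
#' @param profile A centred/scaled `RankedProfile` (see [center_scale()]).
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Weight `w` on the statistic (default 1).
#' @param statistic `"z"` (default) or `"rank"` (centred ranks).
#' @return List with `ES`, `running_sum` (length-N deviation vector),
#'   `leading_edge`, and `size` (set genes present in the list).
#' @export
enrichment_score <- function(profile, gene_set, weight_exponent = 1,
                             statistic = c("z", "rank")) {
  stopifnot(inherits(profile, "RankedProfile"))
  s <- profile_statistic(profile, statistic)
  ranked <- profile$entries$gene_id
  N <- length(ranked)
  pos <- sort.int(which(ranked %in% gene_set))
  k <- length(pos)
  if (k == 0L)
    stop("no gene of the set appears in the ranked list", call. = FALSE)
  if (k == N)
    stop("set equals the whole ranked list; miss increment undefined",
         call. = FALSE)
  aw <- abs(s)^weight_exponent
  es <- es_at_hits(aw, pos, N)

  hit <- logical(N)
  hit[pos] <- TRUE
  w <- aw
  w[!hit] <- 0
  denom <- sum(w)
  p_hit <- if (denom > 0) cumsum(w) / denom else cumsum(hit) / k
  p_miss <- cumsum(!hit) / (N - k)
  running <- p_hit - p_miss

  extremum_pos <- pos[es$hit_index]
  leading <- if (is.na(es$positive)) character(0) # tied extrema: ES = 0
             else if (es$positive) ranked[pos[pos <= extremum_pos]]
             else ranked[pos[pos >= extremum_pos]]
  list(ES = es$ES, running_sum = running, leading_edge = leading, size = k)
}

# Internal: K permutation enrichment scores for a set of size k drawn
# uniformly without replacement from an N-long ranked list with weight
# vector aw.
perm_es_pool <- function(aw, k, N, K) {
  vapply(seq_len(K), function(i) {
    es_at_hits(aw, sort.int(sample.int(N, k)), N)$ES
  }, numeric(1))
}

# Internal: NES and nominal p from an observed ES and a permutation pool.
# Signed-side normalization: only permutation scores with the sign of the
# observed ES enter the denominator and the p-value count (an ES of zero
# counts to the positive side); the +1 correction keeps p in (0, 1].
nes_p_from_pool <- function(es, pool) {
  same <- if (es >= 0) pool[pool >= 0] else pool[pool < 0]
  n_same <- length(same)
  if (n_same == 0L) {
    return(list(NES = NA_real_, p_nominal = 1 / (length(pool) + 1),
                n_same_sign = 0L, flag = "no-same-sign-permutations"))
  }
  list(NES = es / mean(abs(same)),
       p_nominal = (1 + sum(abs(same) >= abs(es))) / (1 + n_same),
       n_same_sign = n_same, flag = NA_character_)
}

#' Gene-permutation null for one gene set
#'
#' Draws `K` random gene sets of the same measured size uniformly without
#' replacement from the ranked list, computes their enrichment scores, and
#' normalizes: `NES = ES / mean(|permutation ES of the same sign|)`;
#' `p = (1 + #{same-sign |perm ES| >= |ES|}) / (1 + #same-sign)`.
#' Deterministic given `config$seed`.
#'
#' @param profile A centred/scaled `RankedProfile`.
#' @param gene_set Character vector of gene ids.
#' @param config An [enrichment_config()].
#' @param statistic `"z"` or `"rank"`.
#' @param keep_perm Return the permutation ES vector as `perm_es`.
#' @return List with `ES`, `NES`, `p_nominal`, `n_same_sign`, `flag`
#'   (and `perm_es` when requested).
#' @export
permutation_null <- function(profile, gene_set, config = enrichment_config(),
                             statistic = c("z", "rank"), keep_perm = FALSE) {
  obs <- enrichment_score(profile, gene_set, config$weight_exponent,
                          statistic)
  s <- profile_statistic(profile, statistic)
  aw <- abs(s)^config$weight_exponent
  N <- length(s)
  set.seed(config$seed)
  pool <- perm_es_pool(aw, obs$size, N, config$n_permutations)
  out <- nes_p_from_pool(obs$ES, pool)
  out$ES <- obs$ES
  if (keep_perm) out$perm_es <- pool
  out[c("ES", "NES", "p_nominal", "n_same_sign", "flag",
        if (keep_perm) "perm_es")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across a family of nominal p-values, preserving
#' input order. Thin validated wrapper over `stats::p.adjust(..., "BH")`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Run pre-ranked enrichment over a gene-set collection
#'
#' Restricts the collection and profile to each other (see
#' [restrict_to_measured()]), scores every retained set, builds the
#' permutation null — one shared pool per distinct set size, with the RNG
#' substream derived from `(seed, size)` so results do not depend on the
#' order sets appear in the GMT — and applies BH adjustment across all
#' retained sets.
#'
#' @param profile A centred/scaled `RankedProfile`.
#' @param collection A `GeneSetCollection`.
#' @param config An [enrichment_config()].
#' @param statistic `"z"` (default) or `"rank"`.
#' @return An `EnrichmentTable` data.frame with columns `set_name`,
#'   `size_measured`, `ES`, `NES`, `p_nominal`, `p_adjusted`,
#'   `leading_edge` (comma-joined), ordered by adjusted p then set name.
#'   The restriction log is attached as attribute `restriction_log`.
#' @export
run_enrichment <- function(profile, collection, config = enrichment_config(),
                           statistic = c("z", "rank")) {
  statistic <- match.arg(statistic)
  res <- restrict_to_measured(collection, profile,
                              config$min_set_size, config$max_set_size)
  rp <- res$profile
  sets <- res$collection$sets
  s <- profile_statistic(rp, statistic)
  aw <- abs(s)^config$weight_exponent
  N <- length(s)

  sizes <- lengths(sets)
  pools <- new.env(parent = emptyenv())
  pool_for <- function(k) {
    key <- as.character(k)
    if (is.null(pools[[key]])) {
      set.seed((config$seed + 104729 * k) %% 2147483647L)
      pools[[key]] <- perm_es_pool(aw, k, N, config$n_permutations)
    }
    pools[[key]]
  }

  rows <- lapply(names(sets), function(nm) {
    es <- enrichment_score(rp, sets[[nm]], config$weight_exponent, statistic)
    np <- nes_p_from_pool(es$ES, pool_for(es$size))
    data.frame(set_name = nm, size_measured = es$size, ES = es$ES,
               NES = np$NES, p_nominal = np$p_nominal,
               leading_edge = paste(es$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- bh_adjust(tab$p_nominal)
  tab <- tab[order(tab$p_adjusted, tab$set_name, method = "radix"), ,
             drop = FALSE]
  tab <- tab[, c("set_name", "size_measured", "ES", "NES", "p_nominal",
                 "p_adjusted", "leading_edge")]
  rownames(tab) <- NULL
  attr(tab, "restriction_log") <- res$log
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}

#' Significant pathways of an enrichment table
#' @param table An `EnrichmentTable`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The rows with `p_adjusted <= alpha`.
#' @export
significant_sets <- function(table, alpha = 0.05) {
  table[table$p_adjusted <= alpha, , drop = FALSE]
}

#' Top pathways by |NES|
#' @param table An `EnrichmentTable`.
#' @param n Number of pathways per direction (default 20).
#' @param direction `"positive"`, `"negative"`, or `"both"`.
#' @return Rows ordered by decreasing |NES| within the chosen direction.
#' @export
top_pathways <- function(table, n = 20L,
                         direction = c("both", "positive", "negative")) {
  direction <- match.arg(direction)
  tab <- switch(direction,
                positive = table[!is.na(table$NES) & table$NES > 0, ,
                                 drop = FALSE],
                negative = table[!is.na(table$NES) & table$NES < 0, ,
                                 drop = FALSE],
                both = table[!is.na(table$NES), , drop = FALSE])
  tab <- tab[order(-abs(tab$NES), tab$set_name, method = "radix"), ,
             drop = FALSE]
  head(tab, n)
}
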