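# Independent oracles and fixture builders shared across the test files.
# Oracles are deliberately naive (two-pass formulas, literal definitions,
# O(n^2) loops) so they cannot share code paths with the implementation.

# Naive two-pass Pearson correlation.
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Literal running-sum enrichment score: walk every position of the ranked
# list accumulating weighted hits and uniform misses, then take the value
# at the maximum absolute deviation (positive side wins exact magnitude
# ties, the package's documented convention).
oracle_es <- function(s, hit, w = 1) {
  N <- length(s)
  k <- sum(hit)
  aw <- abs(s)^w
  denom <- sum(aw[hit])
  p_hit <- p_miss <- numeric(N)
  ch <- 0; cm <- 0
  for (i in seq_len(N)) {
    if (hit[i]) ch <- ch + aw[i] else cm <- cm + 1
    p_hit[i] <- if (denom > 0) ch / denom else 0
    p_miss[i] <- cm / (N - k)
  }
  dev <- p_hit - p_miss
  mx <- max(dev); mn <- min(c(0, dev))
  if (abs(mx + mn) <= 1e-12 * max(1, abs(mx))) 0 # tied extrema
  else if (mx >= -mn) mx
  else mn
}

# Literal Benjamini-Hochberg step-up: adj_i = min over j with
# p_j >= p_i of p_j * m / rank_j, clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    min(1, min(p[p >= p[i]] * m / rk[p >= p[i]]))
  }, numeric(1))
}

# Build a RankedProfile directly from a statistic vector (descending).
make_profile <- function(z, gene_ids = sprintf("G%03d", seq_along(z)),
                         r = z, guide_id = "GUIDE", stratum = "test",
                         n_samples = 10L) {
  structure(list(
    guide_id = guide_id, stratum = stratum,
    entries = data.frame(gene_id = gene_ids, r = r, z = z,
                         rank = seq_along(z), stringsAsFactors = FALSE),
    n_samples = n_samples,
    excluded = data.frame(gene_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)),
    class = "RankedProfile")
}

# Random linear-scale expression fixture.
random_expression <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  v <- matrix(round(2^rnorm(n_genes * n_samples, 4, 2), 4),
              nrow = n_genes,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(v, "linear")
}

# Small two-stratum synthetic configuration used by several tests.
small_synth_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_donors_per_stratum = 25, samples_per_donor = 4,
         n_background_genes = 800, n_decoy_sets = 10,
         decoy_set_size = 30, seed = seed),
    list(...))
  do.call(synth_config, args)
}
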