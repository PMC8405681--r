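# Synthetic cohort generator: rank-1 latent-factor co-expression modules
# tied to a guide gene, two-level strata with differing module strength,
# continuous markers coupled to the guide, and decoy gene sets — all with
# recorded ground truth.

#' Theoretical guide-gene correlation of a planted module
#'
#' Under the rank-1 model (guide latent `g = f + e_g`, module gene latent
#' `x = beta * f + e`, with `f` standard normal), the population Pearson
#' correlation between guide and module gene latents is
#' `rho = beta / sqrt((1 + tau_g^2) * (beta^2 + tau^2))`.
#'
#' @param beta Module loading.
#' @param noise_sd Module gene noise sd `tau` (> 0).
#' @param guide_noise_sd Guide noise sd `tau_g` (>= 0).
#' @return `rho`, in (-1, 1).
#' @export
rho_theoretical <- function(beta, noise_sd = 1, guide_noise_sd = 0.5) {
  beta / sqrt((1 + guide_noise_sd^2) * (beta^2 + noise_sd^2))
}

#' Loading that yields a target guide-gene correlation
#'
#' Inverts [rho_theoretical()]: returns the `beta` for which a module gene
#' has population correlation `rho` with the guide. Requires
#' `|rho| < 1 / sqrt(1 + guide_noise_sd^2)`.
#'
#' @param rho Target correlation.
#' @param noise_sd,guide_noise_sd As in [rho_theoretical()].
#' @return The loading `beta`.
#' @export
beta_for_rho <- function(rho, noise_sd = 1, guide_noise_sd = 0.5) {
  a <- (1 + guide_noise_sd^2) * rho^2
  if (any(a >= 1))
    stop("|rho| must be < 1/sqrt(1 + guide_noise_sd^2)", call. = FALSE)
  sign(rho) * sqrt(a * noise_sd^2 / (1 - a))
}

#' Specify a planted co-expression module
#'
#' @param name Module name (used in gene ids and set names).
#' @param n_genes Number of member genes.
#' @param beta Named numeric vector of loadings, one per stratum level.
#' @param noise_sd Gene-level noise sd `tau` (> 0).
#' @return A `module_spec` list.
#' @export
module_spec <- function(name, n_genes = 40L, beta = c(D = 2, ND = 1),
                        noise_sd = 1) {
  if (is.null(names(beta)) || any(!nzchar(names(beta))))
    stop("`beta` must be named by stratum level", call. = FALSE)
  if (any(!is.finite(beta)))
    stop("`beta` must be finite", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  list(name = name, n_genes = as.integer(n_genes), beta = beta,
       noise_sd = noise_sd)
}

default_modules <- function(stratum_levels = c("D", "ND"),
                            guide_noise_sd = 0.5) {
  rho_strong <- c(0.6, 0.7, 0.8) # stronger-coupled stratum (first level)
  rho_weak <- c(0.4, 0.5, 0.6)   # weaker-coupled stratum (second level)
  lapply(seq_along(rho_strong), function(i) {
    beta <- c(beta_for_rho(rho_strong[i], 1, guide_noise_sd),
              beta_for_rho(rho_weak[i], 1, guide_noise_sd))
    names(beta) <- stratum_levels[1:2]
    module_spec(sprintf("M%d", i), 40L, beta, 1)
  })
}

default_markers <- function() {
  list(list(name = "AT8", slope = 1, noise_sd = 1),
       list(name = "pTau", slope = 0.8, noise_sd = 1),
       list(name = "TNFa", slope = 0, noise_sd = 1))
}

#' Synthetic-cohort configuration
#'
#' Defaults emulate the structure of an old-old postmortem brain cohort:
#' two dementia-status strata with 50 donors each and 4 samples per donor
#' (about 400 samples), 5000 background genes as a desk-scale stand-in for
#' a whole transcriptome, three planted guide-linked modules whose coupling
#' is stronger in the first stratum, guide noise sd 0.5, donor ages 77-102,
#' and markers coupled to the guide latent.
#'
#' @param stratum_name Metadata column name for the stratum (default
#'   `"dementia"`).
#' @param stratum_levels Stratum levels (default `c("D", "ND")`).
#' @param n_donors_per_stratum Donors per stratum (default 50).
#' @param samples_per_donor Samples per donor (default 4).
#' @param n_background_genes Independent background genes (default 5000).
#' @param modules List of [module_spec()]s; default three modules with
#'   guide correlations 0.6/0.7/0.8 in the first stratum and 0.4/0.5/0.6
#'   in the second.
#' @param guide_id Guide gene id (default `"ENHO"`).
#' @param guide_noise_sd Guide noise sd `tau_g` (default 0.5).
#' @param markers List of `list(name, slope, noise_sd)` marker specs.
#' @param marker_offset Additive offset keeping markers non-negative
#'   (default 10).
#' @param expr_offset,expr_scale Map latent values to linear units via
#'   `2^(offset + scale * latent)` (defaults 5 and 1, so `log2(x + 1)`
#'   approximately recovers the latent scale).
#' @param n_decoy_sets,decoy_set_size Decoy gene sets drawn from the
#'   background pool (defaults 50 and 50).
#' @param age_range Donor age range in years (default 77-102).
#' @param seed Master seed; expression, markers and decoys use fixed
#'   substreams derived from it.
#' @return A `SynthConfig` list.
#' @export
synth_config <- function(stratum_name = "dementia",
                         stratum_levels = c("D", "ND"),
                         n_donors_per_stratum = 50L,
                         samples_per_donor = 4L,
                         n_background_genes = 5000L,
                         modules = NULL,
                         guide_id = "ENHO",
                         guide_noise_sd = 0.5,
                         markers = default_markers(),
                         marker_offset = 10,
                         expr_offset = 5, expr_scale = 1,
                         n_decoy_sets = 50L, decoy_set_size = 50L,
                         age_range = c(77L, 102L),
                         seed = 1L) {
  if (is.null(modules))
    modules <- default_modules(stratum_levels, guide_noise_sd)
  if (guide_noise_sd < 0) stop("guide_noise_sd must be >= 0", call. = FALSE)
  if (n_donors_per_stratum < 1L || samples_per_donor < 1L)
    stop("need >= 1 donor per stratum and >= 1 sample per donor",
         call. = FALSE)
  for (m in modules) {
    missing_levels <- setdiff(stratum_levels, names(m$beta))
    if (length(missing_levels))
      stop("module `", m$name, "` lacks beta for stratum level(s): ",
           paste(missing_levels, collapse = ", "), call. = FALSE)
  }
  for (mk in markers)
    if (mk$noise_sd <= 0)
      stop("marker `", mk$name, "` needs noise_sd > 0", call. = FALSE)
  if (expr_scale <= 0) stop("expr_scale must be > 0", call. = FALSE)
  structure(list(stratum_name = stratum_name,
                 stratum_levels = stratum_levels,
                 n_donors_per_stratum = as.integer(n_donors_per_stratum),
                 samples_per_donor = as.integer(samples_per_donor),
                 n_background_genes = as.integer(n_background_genes),
                 modules = modules, guide_id = guide_id,
                 guide_noise_sd = guide_noise_sd, markers = markers,
                 marker_offset = marker_offset,
                 expr_offset = expr_offset, expr_scale = expr_scale,
                 n_decoy_sets = as.integer(n_decoy_sets),
                 decoy_set_size = as.integer(decoy_set_size),
                 age_range = as.integer(age_range),
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Generate a synthetic cohort with ground truth
#'
#' Per sample `j`, a standard-normal latent factor `f_j` drives the guide
#' (`g_j = f_j + e`, sd `tau_g`) and each planted-module gene
#' (`x_ij = beta_stratum * f_j + e`, sd `tau`); background genes are
#' independent noise. Latents map to strictly positive linear expression
#' through `2^(offset + scale * latent)`. Markers are
#' `offset + slope * g_j + noise`, floored at zero. Deterministic given the
#' seed; markers use a separate RNG substream so adding markers never
#' perturbs expression draws.
#'
#' @param config A [synth_config()].
#' @return List with `expression` (linear-scale `ExpressionMatrix`),
#'   `metadata` (data.frame), and `truth` (a `SyntheticTruth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  levels <- config$stratum_levels
  n_d <- config$n_donors_per_stratum
  spd <- config$samples_per_donor
  donors <- sprintf("DNR%04d", seq_len(n_d * length(levels)))
  donor_stratum <- rep(levels, each = n_d)
  sample_donor <- rep(donors, each = spd)
  sample_stratum <- rep(donor_stratum, each = spd)
  samples <- sprintf("SMP%05d", seq_along(sample_donor))
  S <- length(samples)

  # expression substream
  set.seed(config$seed)
  donor_age <- sample(seq(config$age_range[1L], config$age_range[2L]),
                      length(donors), replace = TRUE)
  donor_sex <- sample(c("M", "F"), length(donors), replace = TRUE)
  f <- stats::rnorm(S)
  g <- f + stats::rnorm(S, sd = config$guide_noise_sd)

  module_rows <- lapply(config$modules, function(m) {
    beta_s <- m$beta[sample_stratum]
    latent <- matrix(stats::rnorm(m$n_genes * S, sd = m$noise_sd),
                     nrow = m$n_genes) +
      matrix(beta_s * f, nrow = m$n_genes, ncol = S, byrow = TRUE)
    rownames(latent) <- sprintf("%s_G%03d", m$name, seq_len(m$n_genes))
    latent
  })
  background <- matrix(stats::rnorm(config$n_background_genes * S),
                       nrow = config$n_background_genes)
  rownames(background) <- sprintf("BG_G%05d",
                                  seq_len(config$n_background_genes))
  latent <- rbind(matrix(g, nrow = 1,
                         dimnames = list(config$guide_id, NULL)),
                  do.call(rbind, module_rows), background)
  colnames(latent) <- samples
  values <- 2^(config$expr_offset + config$expr_scale * latent)
  expression <- expression_matrix(values, "linear")

  # marker substream
  set.seed(config$seed + 1L)
  metadata <- data.frame(sample_id = samples, donor_id = sample_donor,
                         stringsAsFactors = FALSE)
  metadata[[config$stratum_name]] <- sample_stratum
  metadata$sex <- donor_sex[match(sample_donor, donors)]
  metadata$age <- donor_age[match(sample_donor, donors)]
  for (mk in config$markers) {
    metadata[[mk$name]] <- pmax(
      0, config$marker_offset + mk$slope * g +
        stats::rnorm(S, sd = mk$noise_sd))
  }

  membership <- lapply(module_rows, rownames)
  names(membership) <- vapply(config$modules, `[[`, character(1), "name")
  beta <- do.call(rbind, lapply(config$modules, function(m)
    m$beta[levels]))
  rownames(beta) <- names(membership)
  colnames(beta) <- levels
  rho <- beta
  for (i in seq_len(nrow(beta)))
    rho[i, ] <- rho_theoretical(beta[i, ], config$modules[[i]]$noise_sd,
                                config$guide_noise_sd)
  truth <- structure(list(
    guide_id = config$guide_id,
    membership = membership,
    beta = beta,
    noise_sd = vapply(config$modules, `[[`, numeric(1), "noise_sd"),
    guide_noise_sd = config$guide_noise_sd,
    rho = rho,
    marker_slopes = vapply(config$markers, `[[`, numeric(1), "slope"),
    background_genes = rownames(background),
    stratum_name = config$stratum_name,
    seed = config$seed), class = "SyntheticTruth")
  names(truth$marker_slopes) <- vapply(config$markers, `[[`,
                                       character(1), "name")
  list(expression = expression, metadata = metadata, truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: guide %s, %d planted modules, seed %d\n",
              x$guide_id, length(x$membership), x$seed))
  print(round(x$rho, 3))
  invisible(x)
}

#' Build planted and decoy gene sets for a synthetic cohort
#'
#' One `PLANTED_<module>` set per planted module (its exact member genes)
#' plus `n_decoy_sets` sets of background genes drawn uniformly without
#' replacement (within each set) from the background pool — so decoys are
#' disjoint from planted modules by construction. Uses the decoy RNG
#' substream (`seed + 2`).
#'
#' @param truth A `SyntheticTruth` from [generate_cohort()].
#' @param config The [synth_config()] that produced it.
#' @return A `GeneSetCollection`, writable via [write_gmt()].
#' @export
generate_gene_sets <- function(truth, config) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            inherits(config, "SynthConfig"))
  pool <- truth$background_genes
  if (config$decoy_set_size > length(pool))
    stop("decoy_set_size exceeds the background gene pool", call. = FALSE)
  sets <- truth$membership
  names(sets) <- paste0("PLANTED_", names(sets))
  desc <- rep("planted co-expression module", length(sets))
  set.seed(config$seed + 2L)
  if (config$n_decoy_sets > 0L) {
    decoys <- lapply(seq_len(config$n_decoy_sets), function(i)
      sample(pool, config$decoy_set_size))
    names(decoys) <- sprintf("DECOY_%03d", seq_len(config$n_decoy_sets))
    sets <- c(sets, decoys)
    desc <- c(desc, rep("random background draw", config$n_decoy_sets))
  }
  gene_set_collection(sets, desc)
}
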