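# Study orchestration: a single configuration drives simulate-or-load,
# preprocessing, per-stratum ranking + enrichment, and the comparison plan,
# writing a reproducible run directory with a manifest.

#' Write a ranked profile as TSV
#'
#' Serializes the entries table (gene_id, r, z, rank) preceded by `#`
#' comment lines carrying the guide id, stratum and sample count. Floats
#' use 17 significant digits so that reading the file back reproduces the
#' in-memory doubles exactly.
#'
#' @param profile A `RankedProfile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "RankedProfile"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# guide_id=%s", profile$guide_id),
               sprintf("# stratum=%s", profile$stratum),
               sprintf("# n_samples=%d", profile$n_samples)), con)
  df <- format_result_frame(profile$entries, 17L)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a ranked profile written by [write_profile()]
#' @param path File path.
#' @return A `RankedProfile` (with an empty exclusion table).
#' @export
read_profile <- function(path) {
  if (!file.exists(path))
    stop("profile file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 10L, warn = FALSE)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    sub(sprintf("^# %s=", key), "", m[1L])
  }
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (col in c("gene_id", "r", "z", "rank"))
    if (!col %in% names(tab))
      stop("profile file lacks column `", col, "`: ", path, call. = FALSE)
  n_samples <- suppressWarnings(as.integer(get("n_samples")))
  new_ranked_profile(get("guide_id"), get("stratum"), tab,
                     if (is.na(n_samples)) 0L else n_samples,
                     data.frame(gene_id = character(0),
                                reason = character(0),
                                stringsAsFactors = FALSE))
}

#' Read a study configuration from YAML
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a study configuration
#'
#' Fails fast with the offending field path. A configuration holds exactly
#' one of `input` (paths to expression/metadata/gene_sets files) or
#' `simulate` (arguments for [synth_config()]); a `seed`; named `strata`
#' (each a possibly-empty `label = value` map); and optional `preprocess`,
#' `selection`, `enrichment` and `compare` blocks.
#'
#' @param config Configuration list (e.g. from YAML).
#' @return `config`, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  fail <- function(path, msg) stop("config$", path, ": ", msg, call. = FALSE)
  if (is.null(config$seed) || length(config$seed) != 1L ||
      is.na(suppressWarnings(as.integer(config$seed))))
    fail("seed", "a single integer seed is required")
  config$seed <- as.integer(config$seed)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    fail("input|simulate", "exactly one of `input` or `simulate` required")
  if (has_input) {
    for (f in c("expression", "metadata", "gene_sets"))
      if (is.null(config$input[[f]]))
        fail(paste0("input$", f), "path required")
    if (is.null(config$input$scale)) config$input$scale <- "linear"
    if (!config$input$scale %in% c("linear", "log2p1"))
      fail("input$scale", "must be `linear` or `log2p1`")
    if (is.null(config$guide_id))
      fail("guide_id", "required when using `input`")
  }
  if (is.null(config$strata) || !length(config$strata) ||
      is.null(names(config$strata)))
    fail("strata", "a named list of strata is required")
  if (is.null(config$preprocess)) config$preprocess <- list()
  if (is.null(config$preprocess$log_transform))
    config$preprocess$log_transform <- TRUE
  if (is.null(config$selection))
    config$selection <- list(rule = "top_fraction", parameter = 0.01)
  if (!config$selection$rule %in% c("top_count", "top_fraction", "r_cutoff"))
    fail("selection$rule", "unknown selection rule")
  if (is.null(config$enrichment)) config$enrichment <- list()
  config$enrichment <- do.call(enrichment_config,
                               c(config$enrichment[
                                 setdiff(names(config$enrichment), "seed")],
                                 list(seed = config$seed)))
  if (is.null(config$compare)) config$compare <- list()
  strata_names <- names(config$strata)
  check_refs <- function(block, arity) {
    for (i in seq_along(config$compare[[block]])) {
      ref <- unlist(config$compare[[block]][[i]])
      if (arity > 1L && !(length(ref) %in% c(2L, 3L)))
        fail(sprintf("compare$%s[[%d]]", block, i), "need 2 or 3 strata")
      unknown <- setdiff(ref, strata_names)
      if (length(unknown))
        fail(sprintf("compare$%s[[%d]]", block, i),
             paste("unknown stratum:", paste(unknown, collapse = ", ")))
    }
  }
  check_refs("venn", 2L)
  check_refs("r_distributions", 2L)
  for (s in config$compare$median_split)
    if (!s %in% strata_names)
      fail("compare$median_split", paste("unknown stratum:", s))
  config
}

stage_log <- function(state, stage, t0) {
  dt <- as.numeric(proc.time()["elapsed"]) - t0
  state$wall_time[[stage]] <- round(dt, 3)
  state$log <- c(state$log,
                 sprintf("stage %-12s completed in %.3f s", stage, dt))
  state
}

#' Run a full guide-gene co-expression study
#'
#' Executes, for each configured stratum: preprocessing, the guide
#' correlation profile, centring/scaling, gene selection and pre-ranked
#' enrichment — then the comparison plan (Venn overlaps of selections,
#' correlation-distribution tests, median splits with marker tests, and
#' guide-marker correlations). All outputs are written under `output_dir`
#' (`profiles/`, `selections/`, `enrichment/`, `comparisons/`,
#' `manifest.json`, `log.txt`). Deterministic given the configured seed:
#' result files are byte-identical across reruns (the manifest and log,
#' which record wall times, are the only exceptions).
#'
#' @param config Configuration list (see [validate_run_config()]).
#' @param output_dir Output directory (default `config$output_dir`).
#' @return The run manifest, invisibly.
#' @export
run_study <- function(config, output_dir = config$output_dir) {
  config <- validate_run_config(config)
  if (is.null(output_dir))
    stop("an output directory is required", call. = FALSE)
  for (d in file.path(output_dir, c("", "profiles", "selections",
                                    "enrichment", "comparisons")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  state <- list(wall_time = list(), log = character(0),
                outputs = character(0), filter_reports = list())
  declare <- function(rel) state$outputs <<- c(state$outputs, rel)
  t0 <- as.numeric(proc.time()["elapsed"])

  # --- data stage -----------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    scfg <- do.call(synth_config, sim_args)
    cohort <- generate_cohort(scfg)
    expression <- cohort$expression
    metadata <- cohort$metadata
    collection <- generate_gene_sets(cohort$truth, scfg)
    guide_id <- scfg$guide_id
    dir.create(file.path(output_dir, "simulated"), showWarnings = FALSE)
    write_metadata(metadata, file.path(output_dir, "simulated",
                                       "metadata.tsv"))
    declare("simulated/metadata.tsv")
    write_gmt(collection, file.path(output_dir, "simulated",
                                    "gene_sets.gmt"))
    declare("simulated/gene_sets.gmt")
    jsonlite::write_json(
      list(guide_id = cohort$truth$guide_id,
           membership = cohort$truth$membership,
           beta = as.data.frame(cohort$truth$beta),
           rho = as.data.frame(cohort$truth$rho),
           marker_slopes = as.list(cohort$truth$marker_slopes),
           seed = cohort$truth$seed),
      file.path(output_dir, "simulated", "truth.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE)
    declare("simulated/truth.json")
  } else {
    expression <- read_expression(config$input$expression,
                                  config$input$scale)
    metadata <- read_metadata(config$input$metadata)
    validate_metadata(metadata, expression)
    collection <- read_gmt(config$input$gene_sets)
    guide_id <- config$guide_id
  }
  state <- stage_log(state, "data", t0)

  # --- preprocess stage ----------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  if (!is.null(config$preprocess$mean_filter) &&
      expression$scale == "linear") {
    mf <- mean_expression_filter(expression, config$preprocess$mean_filter)
    expression <- mf$matrix
    state$filter_reports$mean_filter <- unclass(mf$report)
  }
  if (isTRUE(config$preprocess$log_transform) &&
      expression$scale == "linear")
    expression <- log_transform(expression)
  state <- stage_log(state, "preprocess", t0)

  # --- per-stratum ranking + enrichment -------------------------------
  profiles <- list()
  selections <- list()
  for (stratum in names(config$strata)) {
    t0 <- as.numeric(proc.time()["elapsed"])
    filt <- config$strata[[stratum]]
    if (!length(filt)) filt <- NULL
    prof <- center_scale(guide_correlation_profile(
      expression, guide_id, metadata, filt, stratum = stratum))
    profiles[[stratum]] <- prof
    write_profile(prof, file.path(output_dir, "profiles",
                                  paste0(stratum, ".tsv")))
    declare(paste0("profiles/", stratum, ".tsv"))

    sel <- select_genes(prof, config$selection$rule,
                        config$selection$parameter)
    selections[[stratum]] <- sel
    sel_df <- prof$entries[match(sel$genes, prof$entries$gene_id),
                           c("gene_id", "r", "rank")]
    write_results(sel_df, file.path(output_dir, "selections",
                                    paste0(stratum, ".tsv")), digits = 7L)
    declare(paste0("selections/", stratum, ".tsv"))

    enr <- run_enrichment(prof, collection, config$enrichment)
    write_results(enr, file.path(output_dir, "enrichment",
                                 paste0(stratum, ".tsv")))
    declare(paste0("enrichment/", stratum, ".tsv"))
    state <- stage_log(state, paste0("stratum:", stratum), t0)
  }

  # --- comparison plan ------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  for (ref in config$compare$venn) {
    ref <- unlist(ref)
    ov <- venn_overlap(stats::setNames(
      lapply(ref, function(s) selections[[s]]$genes), ref))
    base <- paste0("venn_", paste(ref, collapse = "_"))
    write_results(ov$pairwise,
                  file.path(output_dir, "comparisons",
                            paste0(base, ".tsv")))
    declare(paste0("comparisons/", base, ".tsv"))
    jsonlite::write_json(list(list_names = ov$list_names,
                              sizes = as.list(ov$sizes),
                              region_counts = as.list(ov$region_counts)),
                         file.path(output_dir, "comparisons",
                                   paste0(base, ".json")),
                         auto_unbox = TRUE, pretty = TRUE)
    declare(paste0("comparisons/", base, ".json"))
  }
  for (ref in config$compare$r_distributions) {
    ref <- unlist(ref)
    pa <- profiles[[ref[1L]]]
    pb <- profiles[[ref[2L]]]
    ra <- pa$entries$r[pa$entries$gene_id %in% selections[[ref[1L]]]$genes]
    rb <- pb$entries$r[pb$entries$gene_id %in% selections[[ref[2L]]]$genes]
    cmp <- compare_r_distributions(ra, rb)
    df <- data.frame(stratum_a = ref[1L], stratum_b = ref[2L],
                     n_a = length(ra), n_b = length(rb),
                     statistic = cmp$statistic, p_value = cmp$p_value,
                     median_difference = cmp$median_difference,
                     test = cmp$test, stringsAsFactors = FALSE)
    base <- paste0("rdist_", ref[1L], "_", ref[2L])
    write_results(df, file.path(output_dir, "comparisons",
                                paste0(base, ".tsv")))
    declare(paste0("comparisons/", base, ".tsv"))
  }
  guide_log <- expression$values[guide_id, ]
  for (stratum in config$compare$median_split) {
    filt <- config$strata[[stratum]]
    ms <- median_split(guide_log, metadata,
                       if (length(filt)) filt else NULL,
                       guide_id = guide_id)
    ms$stratum <- stratum
    ms <- marker_tests(ms, metadata, config$compare$markers)
    write_results(ms$tests,
                  file.path(output_dir, "comparisons",
                            paste0("median_split_", stratum, ".tsv")))
    declare(paste0("comparisons/median_split_", stratum, ".tsv"))

    samp <- c(ms$lo_samples, ms$hi_samples)
    markers <- config$compare$markers
    if (is.null(markers))
      markers <- setdiff(
        names(metadata)[vapply(metadata, is.numeric, logical(1))], "age")
    corr_rows <- lapply(markers, function(m) {
      v <- metadata[[m]][match(samp, metadata$sample_id)]
      gm <- guide_marker_correlation(guide_log[samp], v)
      data.frame(marker = m, r = gm$r, p_value = gm$p_value, n = gm$n,
                 stringsAsFactors = FALSE)
    })
    write_results(do.call(rbind, corr_rows),
                  file.path(output_dir, "comparisons",
                            paste0("marker_correlation_", stratum,
                                   ".tsv")))
    declare(paste0("comparisons/marker_correlation_", stratum, ".tsv"))
  }
  state <- stage_log(state, "comparisons", t0)

  # --- manifest -------------------------------------------------------
  manifest <- list(config = config[setdiff(names(config), "enrichment")],
                   enrichment = unclass(config$enrichment),
                   package_version =
                     as.character(utils::packageVersion("coexrank")),
                   r_version = as.character(getRversion()),
                   filter_reports = state$filter_reports,
                   outputs = sort(state$outputs),
                   wall_time_s = state$wall_time)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(state$log, file.path(output_dir, "log.txt"))
  missing <- state$outputs[!file.exists(file.path(output_dir,
                                                  state$outputs))]
  if (length(missing))
    stop("declared output(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(structure(manifest, class = "RunManifest"))
}
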