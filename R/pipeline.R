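# Full-pipeline orchestration from a single YAML/JSON configuration:
# filter -> network -> anchor module -> (preservation) -> %G.A.M.E. ->
# enrichment -> survival, with a JSON manifest checksumming every output.

config_defaults <- function() {
  list(anchor_gene = "COL10A1",
       unit = "log2",
       candidate_powers = 1:20,
       fit_r2_target = 0.85,
       min_module_size = 30,
       deep_split = 2,
       correlation = "pearson",
       n_perm = 200,
       low_intensity_threshold = NULL,
       seed = 1L)
}

known_config_keys <- function() {
  c("expression", "clinical", "test_expression", "gene_sets", "output_dir",
    names(config_defaults()))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration, fills defaults (min_module_size 30,
#' deep_split 2, anchor gene COL10A1, ...), and aggregates all problems
#' (missing required paths, unknown keys, nonexistent files) into one
#' error.
#'
#' @param path config file path, or a named list already in memory.
#' @return the resolved \code{RunConfig} list.
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  problems <- character(0)
  unknown <- setdiff(names(cfg), known_config_keys())
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  if (is.null(cfg$expression))
    problems <- c(problems, "missing required key: expression")
  if (is.null(cfg$output_dir))
    problems <- c(problems, "missing required key: output_dir")
  for (key in c("expression", "clinical", "test_expression", "gene_sets")) {
    p <- cfg[[key]]
    if (!is.null(p) && !all(file.exists(unlist(p))))
      problems <- c(problems, paste0(key, " path does not exist: ",
                                     paste(unlist(p)[!file.exists(unlist(p))], collapse = ", ")))
  }
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  defs <- config_defaults()
  for (nm in names(defs))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defs[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "RunConfig")
}

write_tsv_result <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full anchor-module pipeline
#'
#' Stages: read expression (and clinical / test-cohort / gene sets when
#' configured), low-expression filter matched to the declared unit, soft
#' power selection, signed network + TOM + module detection, anchor module
#' extraction, preservation against the test cohort, %G.A.M.E. scoring and
#' Jenks stratification, overlap enrichment for each gene-set collection,
#' and Cox/KM survival models. Every output table is written as TSV and
#' checksummed in a JSON run manifest; the manifest is identical for
#' identical (config, seed).
#'
#' @param config a \code{RunConfig} (from [validate_config()]) or a path.
#' @return list with the per-stage results and \code{manifest_path}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log <- list()

  X <- read_expression_matrix(config$expression, unit = config$unit)
  log$input <- list(genes = nrow(X$values), samples = ncol(X$values), unit = X$unit)

  filt <- switch(X$unit,
    rsem = filter_low_expression_rsem(X),
    counts = filter_low_expression_counts(X),
    log_intensity = {
      if (is.null(config$low_intensity_threshold))
        stop("low_intensity_threshold is required for log_intensity input")
      filter_low_intensity(X, threshold = config$low_intensity_threshold)
    },
    log2 = list(matrix = X, report = filter_report("none (log2 input)", character(0),
                                                   nrow(X$values))))
  Xf <- filt$matrix
  if (!config$anchor_gene %in% rownames(Xf$values)) {
    if (config$anchor_gene %in% filt$report$genes_removed)
      stop("anchor gene '", config$anchor_gene, "' was removed by filter [",
           filt$report$rule, "]")
    stop("anchor gene '", config$anchor_gene, "' absent from the expression matrix")
  }
  log$filter <- list(rule = filt$report$rule,
                     removed = length(filt$report$genes_removed),
                     kept = filt$report$genes_kept_count)

  net_cfg <- network_config(candidate_powers = config$candidate_powers,
                            fit_r2_target = config$fit_r2_target,
                            min_module_size = config$min_module_size,
                            deep_split_level = config$deep_split,
                            correlation = config$correlation)
  sp <- select_soft_power(Xf, net_cfg)
  outputs <- c(outputs, write_tsv_result(sp$fit_table,
                                         file.path(config$output_dir, "soft_power_fit.tsv")))
  A <- signed_adjacency(Xf, sp$beta, net_cfg$correlation)
  TOM <- topological_overlap(A)
  part <- detect_modules(TOM, net_cfg, X = Xf, anchor_gene = config$anchor_gene)
  outputs <- c(outputs, write_tsv_result(
    data.frame(gene = names(part$labels), module = unname(part$labels)),
    file.path(config$output_dir, "module_labels.tsv")))
  if (!is.null(part$eigengenes))
    outputs <- c(outputs, write_tsv_result(
      data.frame(sample_id = rownames(part$eigengenes), part$eigengenes,
                 check.names = FALSE),
      file.path(config$output_dir, "module_eigengenes.tsv")))
  anchor <- extract_anchor_module(part, config$anchor_gene)
  log$modules <- list(beta = sp$beta, reached_target = sp$reached_target,
                      n_modules = length(setdiff(unique(part$labels), 0)),
                      anchor_module = anchor$module_id,
                      anchor_module_size = length(anchor$genes))
  if (anchor$status == "unassigned")
    stop("anchor gene was not assigned to any module at this configuration")

  results <- list(soft_power = sp, partition = part, anchor = anchor)

  if (!is.null(config$test_expression)) {
    Xt <- read_expression_matrix(config$test_expression, unit = config$unit)
    pres <- z_summary(anchor$genes, Xf, Xt, beta = sp$beta,
                      n_perm = config$n_perm, seed = config$seed)
    jsonlite::write_json(
      list(z_summary = pres$z_summary, z_density = pres$z_density,
           z_connectivity = pres$z_connectivity,
           n_permutations = pres$n_permutations),
      file.path(config$output_dir, "preservation.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(config$output_dir, "preservation.json"))
    results$preservation <- pres
    log$preservation <- list(z_summary = pres$z_summary)
  }

  strata <- stratify_samples(Xf, anchor$genes)
  outputs <- c(outputs, write_tsv_result(
    data.frame(sample_id = names(strata$game), game = unname(strata$game),
               group = as.character(strata$group),
               km_label = as.character(strata$km_label)),
    file.path(config$output_dir, "game_strata.tsv")))
  jsonlite::write_json(list(breaks = strata$breaks),
                       file.path(config$output_dir, "game_breaks.json"),
                       auto_unbox = FALSE, digits = NA)
  outputs <- c(outputs, file.path(config$output_dir, "game_breaks.json"))
  results$strata <- strata
  log$strata <- as.list(table(strata$group))

  if (!is.null(config$gene_sets)) {
    for (gmt in unlist(config$gene_sets)) {
      coll <- read_gene_sets_gmt(gmt)
      enr <- enrichment_screen(coll, anchor$genes, rownames(Xf$values))
      out <- file.path(config$output_dir,
                       paste0("enrichment_", tools::file_path_sans_ext(basename(gmt)), ".tsv"))
      outputs <- c(outputs, write_tsv_result(enr, out))
      act <- activity_screen(coll, Xf, as.character(strata$km_label),
                             anchor$genes, rownames(Xf$values))
      outa <- file.path(config$output_dir,
                        paste0("activity_", tools::file_path_sans_ext(basename(gmt)), ".tsv"))
      outputs <- c(outputs, write_tsv_result(act, outa))
      results$enrichment[[basename(gmt)]] <- enr
      results$activity[[basename(gmt)]] <- act
    }
  }

  if (!is.null(config$clinical)) {
    clin <- read_clinical_table(config$clinical)
    me <- part$eigengenes[, paste0("ME", anchor$module_id)]
    names(me) <- rownames(part$eigengenes)
    signals <- list(anchor_expression = Xf$values[config$anchor_gene, ],
                    anchor_ME = me, game = strata$game)
    fits <- list()
    for (nm in names(signals)) {
      fits[[nm]] <- tryCatch(
        fit_coxph(clin, signals[[nm]], outcome = "os", signal_name = nm),
        error = function(e) NULL)
    }
    fits <- Filter(Negate(is.null), fits)
    if (length(fits)) {
      fam <- adjust_cox_family(fits)
      outputs <- c(outputs, write_tsv_result(fam, file.path(config$output_dir, "cox_os.tsv")))
      results$cox <- fits
      results$cox_family <- fam
    }
    km_df <- data.frame(sample_id = clin$sample_id,
                        time = clin$os_time, event = clin$os_event)
    km_df$label <- as.character(strata$km_label[km_df$sample_id])
    km_df <- km_df[stats::complete.cases(km_df), ]
    km <- tryCatch(km_estimate(km_df$time, km_df$event, km_df$label),
                   error = function(e) NULL)
    if (!is.null(km)) {
      outputs <- c(outputs, write_tsv_result(km$curves,
                                             file.path(config$output_dir, "km_curves.tsv")))
      results$km <- km
      log$km <- list(p = km$p)
    }
  }

  manifest <- list(config = unclass(config), seed = config$seed, log = log,
                   outputs = lapply(stats::setNames(outputs, basename(outputs)),
                                    function(f) unname(tools::md5sum(f))))
  manifest_path <- file.path(config$output_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  results$manifest_path <- manifest_path
  results$manifest <- manifest
  invisible(results)
}
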