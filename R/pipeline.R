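#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return config list, validated by [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

default_contrasts <- function() list(
  SPN_vs_normal = list(a = "SPN", b = "normal"),
  PanNET_vs_normal = list(a = "PanNET", b = "normal"),
  PDAC_vs_normal = list(a = "PDAC", b = "normal"),
  SPN_vs_PanNET = list(a = "SPN", b = "PanNET"),
  SPN_vs_PDAC = list(a = "SPN", b = "PDAC"))

biomarker_contrasts <- function() list(
  SPN_vs_malignant = list(a = "SPN", b = c("PanNET", "PDAC")),
  SPN_vs_PanNET = list(a = "SPN", b = "PanNET"),
  SPN_vs_PDAC = list(a = "SPN", b = "PDAC"))

#' Run the full network-to-biomarker pipeline
#'
#' Executes, in order: input simulation or loading, preprocessing
#' (log2 + quantile normalization of each platform independently, skipped
#' for data that is already normalized), candidate-network assembly,
#' co-expression scoring, cutoff scan, GRN construction, differential
#' expression over the configured contrasts, seed-pair shortest paths and
#' path-gene extraction, DE enrichment of the path genes, and KNN
#' biomarker selection for each diagnostic contrast. All stage outputs are
#' collected into a machine-readable report (and written to `out_dir` when
#' given).
#'
#' @param config a list (or the result of [read_pipeline_config()]) with
#'   exactly one of `simulate` (arguments for [synthetic_config()]) or
#'   `input` (paths: `mrna`, `mirna`, `metadata`, `annotation`, `edges` =
#'   list of `list(path=, provenance=)`, `seeds`); optional entries
#'   `preprocess` (`skip`, `log2_offset`), `correlation_classes` (default
#'   `"SPN"`; `"all"` for every sample), `cutoff_grid`, `cutoff_tf`,
#'   `cutoff_mirna`, `de` (`p_threshold`, `fc_threshold`), `path_mode`,
#'   `knn` ([knn_config()] arguments), `selection_strategy`, `out_dir`,
#'   `rng_seed`.
#' @return list of class `grn_pipeline_report`.
#' @export
run_pipeline <- function(config) {
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    stop("config must contain exactly one of `simulate` or `input`",
         call. = FALSE)
  seed <- config$rng_seed %||% 1L
  set.seed(as.integer(seed) %% .Machine$integer.max)

  # --- inputs ---------------------------------------------------------
  if (has_sim) {
    cfg <- do.call(synthetic_config, c(config$simulate,
                                       if (is.null(config$simulate$rng_seed))
                                         list(rng_seed = seed)))
    sim <- simulate_study(cfg)
    mrna <- sim$mrna; mirna <- sim$mirna
    metadata <- sim$metadata; annotation <- sim$annotation
    candidates <- merge_candidate_edges(list(sim$candidates))
    seeds <- sim$seeds
    truth <- sim$truth
  } else {
    inp <- config$input
    scale_hint <- inp$scale %||% "log2"
    mrna <- read_expression_matrix(inp$mrna, scale_hint)
    mirna <- read_expression_matrix(inp$mirna, scale_hint)
    metadata <- read_sample_metadata(inp$metadata)
    annotation <- read_feature_annotation(inp$annotation)
    loaded <- lapply(inp$edges, function(e)
      load_candidate_edges(e$path, e$provenance, annotation))
    candidates <- merge_candidate_edges(loaded)
    seeds <- readLines(inp$seeds)
    seeds <- seeds[nzchar(seeds)]
    truth <- NULL
  }

  # --- preprocessing --------------------------------------------------
  pp <- config$preprocess %||% list()
  skip <- pp$skip %||% (expr_scale(mrna) == "log2")
  if (!skip) {
    off <- pp$log2_offset %||% 0
    if (expr_scale(mrna) == "raw") mrna <- log2_transform(mrna, off)
    if (expr_scale(mirna) == "raw") mirna <- log2_transform(mirna, off)
    mrna <- quantile_normalize(mrna)
    mirna <- quantile_normalize(mirna)
  }

  # --- co-expression scoring and GRN ----------------------------------
  corr_classes <- config$correlation_classes %||% "SPN"
  shared <- intersect(colnames(mrna), colnames(mirna))
  subset <- if (identical(corr_classes, "all")) shared else
    intersect(shared, metadata$sample_id[metadata$class_label %in% corr_classes])
  scored <- score_edges(candidates, mrna, mirna, subset)
  scan <- scan_cutoffs(scored, config$cutoff_grid %||% seq(0, 0.9, by = 0.1))
  grn <- build_grn(scored, config$cutoff_tf %||% 0.8,
                   config$cutoff_mirna %||% 0.8, annotation)

  # --- differential expression ----------------------------------------
  de_cfg <- config$de %||% list()
  contrasts <- de_cfg$contrasts %||% default_contrasts()
  present <- unique(metadata$class_label)
  de <- list()
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    if (!all(c(ct$a, ct$b) %in% present)) next
    de[[nm]] <- rbind(
      call_de(mrna, metadata, ct$a, ct$b,
              de_cfg$p_threshold %||% 0.01, de_cfg$fc_threshold %||% 2),
      call_de(mirna, metadata, ct$a, ct$b,
              de_cfg$p_threshold %||% 0.01, de_cfg$fc_threshold %||% 2))
  }

  # --- shortest paths --------------------------------------------------
  graph <- to_path_graph(grn, config$path_mode %||% "undirected")
  paths <- seed_pair_paths(graph, seeds)
  roles <- stats::setNames(annotation$role, annotation$feature_id)
  path_genes <- extract_path_genes(paths, seeds, roles)
  subnet <- export_subnetwork(paths, seeds)

  # --- enrichment of path genes in DE (disease vs normal) --------------
  enrich <- list()
  if (!is.null(de$SPN_vs_normal)) {
    de_ids <- de$SPN_vs_normal$feature_id[de$SPN_vs_normal$is_de]
    for (role in c("TF", "miRNA")) {
      bg <- grn$nodes$id[grn$nodes$role == role]
      cand <- intersect(path_genes$genes$gene_id, bg)
      if (length(cand) && length(bg) > length(cand))
        enrich[[role]] <- enrichment_report(cand, intersect(de_ids, bg), bg)
    }
  }

  # --- biomarker classification ---------------------------------------
  knn_cfg <- do.call(knn_config, config$knn %||% list())
  combined <- expression_matrix(
    rbind(unclass(mrna), unclass(mirna))[, shared, drop = FALSE],
    scale = "log2")
  candidate_genes <- intersect(
    unique(c(seeds, path_genes$genes$gene_id)), rownames(combined))
  biomarkers <- list()
  for (nm in names(biomarker_contrasts())) {
    ct <- biomarker_contrasts()[[nm]]
    if (!all(c(ct$a, ct$b) %in% present)) next
    keep <- metadata$class_label %in% c(ct$a, ct$b)
    sub_meta <- metadata[keep, , drop = FALSE]
    lab <- stats::setNames(
      ifelse(sub_meta$class_label %in% ct$a, paste(ct$a, collapse = "+"),
             paste(ct$b, collapse = "+")), sub_meta$sample_id)
    sub_m <- expression_matrix(
      unclass(combined)[, intersect(colnames(combined), sub_meta$sample_id),
                        drop = FALSE], scale = "log2")
    pg <- per_gene_accuracy(sub_m, lab, candidate_genes, knn_cfg)
    sel <- select_biomarker_set(pg, sub_m, lab, knn_cfg,
                                strategy = config$selection_strategy %||% "greedy")
    biomarkers[[nm]] <- list(per_gene = pg, gene_set = sel$gene_set,
                             accuracy_percent =
                               if (is.null(sel$result)) NA_real_
                               else sel$result$accuracy_percent,
                             per_sample =
                               if (is.null(sel$result)) NULL
                               else sel$result$per_sample)
  }

  report <- structure(list(
    config = config,
    config_hash = config_hash(config),
    stages = c("inputs", "preprocess", "candidate_network", "grn", "de",
               "paths", "enrichment", "classification"),
    candidate_counts = as.list(candidates$counts),
    n_scored_edges = nrow(scored),
    grn_summary = list(n_nodes = nrow(grn$nodes),
                       n_edges = nrow(grn$edges),
                       counts = as.list(grn$counts),
                       cutoffs = as.list(grn$cutoffs)),
    de_counts = lapply(de, function(d) sum(d$is_de)),
    n_paths = nrow(paths),
    n_unreachable_pairs = length(attr(paths, "unreachable_pairs")),
    n_path_genes = nrow(path_genes$genes),
    path_gene_roles = if (is.null(path_genes$role_counts)) NULL
                      else as.list(path_genes$role_counts),
    enrichment = enrich,
    biomarkers = lapply(biomarkers, function(b)
      list(gene_set = b$gene_set, accuracy_percent = b$accuracy_percent)),
    truth = truth,
    artifacts = list(grn = grn, scan = scan, de = de, paths = paths,
                     path_genes = path_genes, subnetwork = subnet,
                     biomarkers = biomarkers, scored = scored,
                     mrna = mrna, mirna = mirna, metadata = metadata,
                     annotation = annotation, seeds = seeds)),
    class = "grn_pipeline_report")

  if (!is.null(config$out_dir)) write_pipeline_artifacts(report, config$out_dir)
  report
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config[sort(names(config))]), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.grn_pipeline_report <- function(x, ...) {
  cat("grn pipeline report\n")
  cat(sprintf("  config hash   %s\n", x$config_hash))
  cat(sprintf("  GRN           %d nodes, %d edges\n",
              x$grn_summary$n_nodes, x$grn_summary$n_edges))
  for (nm in names(x$de_counts))
    cat(sprintf("  DE %-18s %d features\n", nm, x$de_counts[[nm]]))
  cat(sprintf("  paths         %d (unreachable pairs: %d)\n",
              x$n_paths, x$n_unreachable_pairs))
  cat(sprintf("  path genes    %d\n", x$n_path_genes))
  for (nm in names(x$biomarkers))
    cat(sprintf("  biomarkers %-16s %d gene(s), %.1f%% accuracy\n", nm,
                length(x$biomarkers[[nm]]$gene_set),
                x$biomarkers[[nm]]$accuracy_percent))
  invisible(x)
}

# write the TSV/JSON artifacts of a finished run
write_pipeline_artifacts <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- report$artifacts
  write_grn(a$grn, file.path(dir, "grn.tsv"))
  write_tsv(a$scan, file.path(dir, "cutoff_scan.tsv"))
  for (nm in names(a$de))
    write_tsv(a$de[[nm]], file.path(dir, sprintf("de_%s.tsv", nm)))
  write_tsv(a$paths, file.path(dir, "paths.tsv"))
  write_tsv(a$path_genes$genes, file.path(dir, "path_genes.tsv"))
  write_tsv(a$subnetwork$edges, file.path(dir, "subnetwork_edges.tsv"))
  write_tsv(a$subnetwork$nodes, file.path(dir, "subnetwork_nodes.tsv"))
  for (nm in names(a$biomarkers)) {
    b <- a$biomarkers[[nm]]
    write_tsv(b$per_gene, file.path(dir, sprintf("per_gene_accuracy_%s.tsv", nm)))
    if (!is.null(b$per_sample))
      write_tsv(b$per_sample, file.path(dir, sprintf("jackknife_%s.tsv", nm)))
  }
  slim <- report[setdiff(names(report), c("artifacts", "truth"))]
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
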