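#' Configuration for the synthetic study generator
#'
#' Defines the simulated study: sample sizes per diagnostic class
#' (defaults mirror a four-class pancreatic-tumour cohort of 14 SPN, 6
#' PanNET, 6 PDAC and 5 non-neoplastic samples), feature counts per role,
#' the density of planted regulations, and the effect sizes of planted
#' signal. Co-expression for a true regulator->target edge is planted
#' through a shared latent signal so that the population Pearson
#' correlation equals `alpha_true` exactly; miRNA->target edges are planted
#' with a negative sign (miRNAs repress their targets), which the pipeline
#' neutralizes by working with |alpha|.
#'
#' @param n_per_class named integer vector of samples per class.
#' @param n_genes,n_tfs,n_mirnas feature counts per role.
#' @param regulation_density fraction of possible regulator->target pairs
#'   that become candidate edges, in (0, 1).
#' @param decoy_fraction fraction of candidate edges with no planted
#'   co-expression, in [0, 1).
#' @param validated_fraction fraction of candidate edges flagged as
#'   experimentally validated.
#' @param alpha_true planted Pearson correlation of true edges, in (0, 1).
#' @param de_log2fc planted class-mean shift (log2 units) of differentially
#'   expressed genes.
#' @param biomarker_shift planted class-mean separation (log2 units) of
#'   biomarker genes.
#' @param noise_sd within-class standard deviation of log2 expression.
#' @param baseline mean log2 intensity.
#' @param n_seeds,n_seed_tfs,n_seed_mirnas size and role composition of the
#'   generated seed-gene list (default 26 seeds: 4 TFs, 7 miRNAs, 15
#'   genes).
#' @param n_plant_paths number of designated path-intermediate regulators
#'   ("hubs"); each regulates `targets_per_hub` of the seed genes, so seed
#'   pairs are connected through it.
#' @param targets_per_hub seed-gene targets per hub.
#' @param n_de_genes planted differentially expressed genes (SPN vs
#'   normal; half up, half down).
#' @param n_biomarkers planted biomarker genes separating SPN from every
#'   other class (half up, half down in SPN); drawn from the hub-target
#'   seed genes so the biomarkers sit inside the seed-plus-path candidate
#'   pool the classifier searches, as literature seeds do.
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = c(SPN = 14, PanNET = 6, PDAC = 6, normal = 5),
                             n_genes = 80, n_tfs = 12, n_mirnas = 12,
                             regulation_density = 0.04,
                             decoy_fraction = 0.5,
                             validated_fraction = 0.2,
                             alpha_true = 0.9,
                             de_log2fc = 2,
                             biomarker_shift = 3,
                             noise_sd = 0.5,
                             baseline = 8,
                             n_seeds = 26, n_seed_tfs = 4, n_seed_mirnas = 7,
                             n_plant_paths = 2, targets_per_hub = 7,
                             n_de_genes = 10, n_biomarkers = 6,
                             rng_seed = 1L) {
  stopifnot(length(n_per_class) >= 2, all(n_per_class > 0),
            !is.null(names(n_per_class)), !any(names(n_per_class) == ""))
  if (n_genes < 1 || n_mirnas < 0 || n_tfs < 0)
    stop("feature counts must be positive (n_tfs / n_mirnas may be 0)", call. = FALSE)
  if (regulation_density <= 0 || regulation_density >= 1)
    stop("`regulation_density` must be in (0, 1)", call. = FALSE)
  if (decoy_fraction < 0 || decoy_fraction >= 1)
    stop("`decoy_fraction` must be in [0, 1)", call. = FALSE)
  if (alpha_true <= 0 || alpha_true >= 1)
    stop("`alpha_true` must be in (0, 1)", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  n_seed_genes <- n_seeds - n_seed_tfs - n_seed_mirnas
  if (n_seed_genes < 0) stop("seed role counts exceed `n_seeds`", call. = FALSE)
  structure(list(
    n_per_class = n_per_class, n_genes = n_genes, n_tfs = n_tfs,
    n_mirnas = n_mirnas, regulation_density = regulation_density,
    decoy_fraction = decoy_fraction, validated_fraction = validated_fraction,
    alpha_true = alpha_true, de_log2fc = de_log2fc,
    biomarker_shift = biomarker_shift, noise_sd = noise_sd,
    baseline = baseline, n_seeds = n_seeds, n_seed_tfs = n_seed_tfs,
    n_seed_mirnas = n_seed_mirnas, n_seed_genes = n_seed_genes,
    n_plant_paths = n_plant_paths, targets_per_hub = targets_per_hub,
    n_de_genes = n_de_genes, n_biomarkers = n_biomarkers,
    rng_seed = as.integer(rng_seed)), class = "synthetic_config")
}

synthetic_features <- function(cfg) {
  data.frame(
    feature_id = c(sprintf("tf%03d", seq_len(cfg$n_tfs)),
                   sprintf("mir%03d", seq_len(cfg$n_mirnas)),
                   sprintf("g%04d", seq_len(cfg$n_genes))),
    role = rep(c("TF", "miRNA", "gene"), c(cfg$n_tfs, cfg$n_mirnas, cfg$n_genes)),
    stringsAsFactors = FALSE)
}

# Gene index blocks: hub-target seed genes first (the first n_biomarkers of
# them double as planted biomarkers -- a class-constant shift leaves
# within-class correlations, and hence edge recovery, untouched), then a
# reserved tail of pure-noise genes for DE planting; the middle is free for
# ordinary edges.
synthetic_layout <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  n_hub_targets <- cfg$n_plant_paths * cfg$targets_per_hub
  if (cfg$n_biomarkers > max(n_hub_targets, 0))
    stop("`n_biomarkers` exceeds the number of hub-target seed genes",
         call. = FALSE)
  n_reserved <- cfg$n_de_genes
  if (n_hub_targets + n_reserved > cfg$n_genes)
    stop("not enough genes for hub targets plus reserved DE genes",
         call. = FALSE)
  list(hub_targets = genes[seq_len(n_hub_targets)],
       de_genes = genes[cfg$n_genes - n_reserved + seq_len(cfg$n_de_genes)],
       biomarker_genes = genes[seq_len(cfg$n_biomarkers)],
       free = genes[setdiff(seq_len(cfg$n_genes),
                            c(seq_len(n_hub_targets),
                              cfg$n_genes - n_reserved + seq_len(n_reserved)))])
}

#' Generate candidate regulations with planted true edges
#'
#' Emits candidate edges of the three modelled categories (TF->gene,
#' TF->miRNA, miRNA->gene). A `1 - decoy_fraction` share are true edges
#' whose co-expression is later planted in the expression matrices; the
#' rest are decoys connecting statistically independent features,
#' emulating false predictions from target-prediction tools. Every target
#' has at most one true regulator, so the planted correlation of each true
#' edge is exactly `alpha_true`. A subset of the designated hub regulators'
#' edges wires the future seed genes together for path recovery.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `candidates` (data.frame: regulator, target, category,
#'   validated), `true_edges` (same shape), `features` (annotation
#'   data.frame), `hubs` (hub regulator ids) and `regulator_of` (named
#'   vector: true regulator per regulated target).
#' @export
generate_regulations <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$rng_seed %% .Machine$integer.max)
  feat <- synthetic_features(cfg)
  lay <- synthetic_layout(cfg)
  tfs <- feat$feature_id[feat$role == "TF"]
  mirs <- feat$feature_id[feat$role == "miRNA"]
  genes <- feat$feature_id[feat$role == "gene"]

  n_pairs <- cfg$n_tfs * cfg$n_genes + cfg$n_tfs * cfg$n_mirnas +
    cfg$n_mirnas * cfg$n_genes
  n_total <- round(cfg$regulation_density * n_pairs)
  if (n_total < 1)
    stop("`regulation_density` implies zero candidate edges", call. = FALSE)
  n_true <- round(n_total * (1 - cfg$decoy_fraction))

  # hub regulators: alternate miRNA / TF so both roles appear on paths
  n_hubs <- cfg$n_plant_paths
  hubs <- character(0)
  if (n_hubs > 0) {
    k <- max(length(mirs), length(tfs))
    pad <- function(x) c(x, rep(NA_character_, k - length(x)))
    interleaved <- as.vector(rbind(pad(mirs), pad(tfs)))
    hubs <- utils::head(interleaved[!is.na(interleaved)], n_hubs)
    if (length(hubs) < n_hubs)
      stop("not enough regulators for the requested hubs", call. = FALSE)
  }
  hub_edges <- NULL
  if (length(hubs)) {
    tgt <- split(lay$hub_targets, rep(seq_along(hubs), each = cfg$targets_per_hub))
    hub_edges <- do.call(rbind, lapply(seq_along(hubs), function(i) {
      data.frame(regulator = hubs[i], target = tgt[[i]], stringsAsFactors = FALSE)
    }))
  }
  regulated <- if (is.null(hub_edges)) character(0) else hub_edges$target
  true_edges <- hub_edges

  # remaining true edges: unregulated free genes / miRNAs, one regulator each
  n_more <- max(0L, n_true - NROW(hub_edges))
  open_targets <- c(setdiff(lay$free, regulated), setdiff(mirs, c(hubs, regulated)))
  open_targets <- sample(open_targets, min(n_more, length(open_targets)))
  if (length(open_targets)) {
    more <- do.call(rbind, lapply(open_targets, function(tg) {
      is_mir <- tg %in% mirs
      reg_pool <- if (is_mir) setdiff(tfs, tg) else c(tfs, mirs)
      reg_pool <- setdiff(reg_pool, tg)
      if (!length(reg_pool)) return(NULL)
      data.frame(regulator = sample(reg_pool, 1L), target = tg,
                 stringsAsFactors = FALSE)
    }))
    true_edges <- rbind(true_edges, more)
  }
  if (is.null(true_edges))
    true_edges <- data.frame(regulator = character(0), target = character(0),
                             stringsAsFactors = FALSE)

  # root of each feature's latent chain (for decoy independence)
  root_of <- stats::setNames(feat$feature_id, feat$feature_id)
  if (nrow(true_edges)) {
    reg_of <- stats::setNames(true_edges$regulator, true_edges$target)
    for (tg in names(reg_of)) {
      r <- reg_of[[tg]]
      while (r %in% names(reg_of)) r <- reg_of[[r]]
      root_of[[tg]] <- r
    }
  } else reg_of <- stats::setNames(character(0), character(0))

  # decoys: pairs not planted and with independent latent roots; budgeted by
  # decoy_fraction (an unfilled true-edge budget is never converted to decoys)
  n_decoy <- min(round(n_total * cfg$decoy_fraction),
                 n_total - nrow(true_edges))
  decoys <- NULL
  if (n_decoy > 0) {
    planted_key <- paste(true_edges$regulator, true_edges$target)
    all_pairs <- rbind(
      expand.grid(regulator = tfs, target = c(genes, mirs),
                  stringsAsFactors = FALSE),
      expand.grid(regulator = mirs, target = genes, stringsAsFactors = FALSE))
    all_pairs <- all_pairs[all_pairs$regulator != all_pairs$target, ]
    ok <- !(paste(all_pairs$regulator, all_pairs$target) %in% planted_key) &
      root_of[all_pairs$regulator] != root_of[all_pairs$target]
    pool <- all_pairs[ok, ]
    idx <- sample(nrow(pool), min(n_decoy, nrow(pool)))
    decoys <- pool[idx, ]
  }

  finish <- function(df) {
    if (is.null(df) || !nrow(df)) return(NULL)
    df$category <- ifelse(df$regulator %in% mirs, "miRNA->gene",
                          ifelse(df$target %in% mirs, "TF->miRNA", "TF->gene"))
    df
  }
  true_edges <- finish(true_edges)
  decoys <- finish(decoys)
  candidates <- rbind(true_edges, decoys)
  if (is.null(candidates))
    stop("no candidate edges could be generated", call. = FALSE)
  candidates$validated <- stats::runif(nrow(candidates)) < cfg$validated_fraction
  rownames(candidates) <- NULL
  if (is.null(true_edges))
    true_edges <- data.frame(regulator = character(0), target = character(0),
                             category = character(0), validated = logical(0),
                             stringsAsFactors = FALSE)
  else {
    true_edges$validated <- candidates$validated[seq_len(nrow(true_edges))]
    rownames(true_edges) <- NULL
  }
  list(candidates = candidates, true_edges = true_edges, features = feat,
       hubs = hubs, regulator_of = reg_of)
}

#' Generate paired expression matrices with planted signal
#'
#' Builds log2-scale mRNA (TFs + genes) and miRNA matrices over a shared
#' sample set. Each feature's latent signal is standard normal; a true
#' edge's target mixes its regulator's (standardized) signal with fresh
#' noise as `alpha * u_reg + sqrt(1 - alpha^2) * eps`, so the population
#' Pearson correlation along every true edge is `alpha_true` (negative for
#' miRNA regulators). Expression is `baseline + noise_sd * u` plus planted
#' class-mean shifts for DE genes (SPN vs normal) and biomarker genes (SPN
#' vs every other class).
#'
#' @param cfg a [synthetic_config()].
#' @param reg output of [generate_regulations()].
#' @return list with `mrna`, `mirna` ([expression_matrix()]s), `metadata`,
#'   `annotation`, and `truth` (true/decoy edges, DE genes with direction,
#'   biomarker genes, hub intermediates).
#' @export
generate_expression <- function(cfg, reg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed((cfg$rng_seed + 1L) %% .Machine$integer.max)
  feat <- reg$features
  lay <- synthetic_layout(cfg)
  classes <- rep(names(cfg$n_per_class), cfg$n_per_class)
  n <- length(classes)
  sample_ids <- sprintf("s%02d", seq_len(n))
  metadata <- data.frame(sample_id = sample_ids, class_label = classes,
                         stringsAsFactors = FALSE)

  mirs <- feat$feature_id[feat$role == "miRNA"]
  # latent signals in topological order: TFs, miRNAs, then genes
  u <- matrix(stats::rnorm(nrow(feat) * n), nrow = nrow(feat),
              dimnames = list(feat$feature_id, sample_ids))
  reg_of <- reg$regulator_of
  ord <- feat$feature_id[order(match(feat$role, c("TF", "miRNA", "gene")))]
  a <- cfg$alpha_true
  for (f in ord) {
    if (f %in% names(reg_of)) {
      r <- reg_of[[f]]
      s <- if (r %in% mirs) -1 else 1
      u[f, ] <- s * a * u[r, ] + sqrt(1 - a^2) * u[f, ]
    }
  }
  expr <- cfg$baseline + cfg$noise_sd * u

  spn <- metadata$class_label == "SPN"
  normal <- metadata$class_label == "normal"
  # DE genes: shift SPN relative to normal (and everything else), half down
  de_dir <- rep(c("up", "down"), length.out = cfg$n_de_genes)
  for (i in seq_along(lay$de_genes)) {
    sgn <- if (de_dir[i] == "up") 1 else -1
    expr[lay$de_genes[i], spn] <- expr[lay$de_genes[i], spn] + sgn * cfg$de_log2fc
  }
  # biomarker genes: separate SPN from all non-SPN classes
  bm_dir <- rep(c("up", "down"), length.out = cfg$n_biomarkers)
  for (i in seq_along(lay$biomarker_genes)) {
    sgn <- if (bm_dir[i] == "up") 1 else -1
    expr[lay$biomarker_genes[i], spn] <-
      expr[lay$biomarker_genes[i], spn] + sgn * cfg$biomarker_shift
  }

  is_mir <- rownames(expr) %in% mirs
  truth <- list(
    true_edges = reg$true_edges,
    decoy_edges = reg$candidates[!paste(reg$candidates$regulator, reg$candidates$target) %in%
                                   paste(reg$true_edges$regulator, reg$true_edges$target), ],
    de_genes = list("SPN_vs_normal" = data.frame(feature_id = lay$de_genes,
                                                 direction = de_dir,
                                                 stringsAsFactors = FALSE)),
    biomarker_genes = data.frame(feature_id = lay$biomarker_genes,
                                 direction = bm_dir, stringsAsFactors = FALSE),
    plant_path_intermediates = reg$hubs,
    hub_targets = lay$hub_targets)
  list(mrna = expression_matrix(expr[!is_mir, , drop = FALSE], scale = "log2"),
       mirna = expression_matrix(expr[is_mir, , drop = FALSE], scale = "log2"),
       metadata = metadata, annotation = feat, truth = truth)
}

#' Generate a seed gene list wired through the planted hubs
#'
#' Seeds mimic a literature-derived disease-gene list: by default 26
#' features (4 TFs, 7 miRNAs, 15 genes). The hub-target genes are always
#' included, so seed pairs sharing a hub are connected in the true network
#' through that designated intermediate.
#'
#' @param cfg a [synthetic_config()].
#' @param reg output of [generate_regulations()].
#' @return character vector of seed feature ids.
#' @export
generate_seed_list <- function(cfg, reg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed((cfg$rng_seed + 2L) %% .Machine$integer.max)
  feat <- reg$features
  lay <- synthetic_layout(cfg)
  tfs <- feat$feature_id[feat$role == "TF"]
  mirs <- feat$feature_id[feat$role == "miRNA"]
  genes <- feat$feature_id[feat$role == "gene"]
  if (cfg$n_seed_tfs > length(setdiff(tfs, reg$hubs)) ||
      cfg$n_seed_mirnas > length(setdiff(mirs, reg$hubs)) ||
      cfg$n_seed_genes > length(genes))
    stop("seed list requests more features than available", call. = FALSE)
  gene_seeds <- lay$hub_targets
  if (length(gene_seeds) > cfg$n_seed_genes)
    stop("hub targets exceed the number of gene seeds; increase n_seeds",
         call. = FALSE)
  extra <- setdiff(setdiff(genes, gene_seeds),
                   c(lay$de_genes, lay$biomarker_genes))
  gene_seeds <- c(gene_seeds,
                  sample(extra, cfg$n_seed_genes - length(gene_seeds)))
  # hubs are the intermediates under test, so keep them off the seed list
  tf_seeds <- sample(setdiff(tfs, reg$hubs), cfg$n_seed_tfs)
  mir_seeds <- sample(setdiff(mirs, reg$hubs), cfg$n_seed_mirnas)
  c(tf_seeds, mir_seeds, gene_seeds)
}

#' Simulate a complete synthetic study
#'
#' Runs regulation, expression and seed-list generation with one
#' configuration; optionally writes all standard pipeline inputs (TSV) and
#' the ground truth (JSON) to a directory.
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory for the TSV/JSON artifacts.
#' @return list with `mrna`, `mirna`, `metadata`, `annotation`,
#'   `candidates`, `seeds` and `truth`.
#' @export
simulate_study <- function(cfg = synthetic_config(), dir = NULL) {
  reg <- generate_regulations(cfg)
  ex <- generate_expression(cfg, reg)
  seeds <- generate_seed_list(cfg, reg)
  out <- list(mrna = ex$mrna, mirna = ex$mirna, metadata = ex$metadata,
              annotation = ex$annotation, candidates = reg$candidates,
              seeds = seeds, truth = ex$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_expression_matrix(out$mrna, file.path(dir, "mrna.tsv"))
    write_expression_matrix(out$mirna, file.path(dir, "mirna.tsv"))
    write_tsv(out$metadata, file.path(dir, "metadata.tsv"))
    write_tsv(out$annotation, file.path(dir, "annotation.tsv"))
    write_tsv(out$candidates[out$candidates$validated,
                             c("regulator", "target")],
              file.path(dir, "edges_validated.tsv"))
    write_tsv(out$candidates[, c("regulator", "target")],
              file.path(dir, "edges_predicted.tsv"))
    writeLines(out$seeds, file.path(dir, "seeds.txt"))
    jsonlite::write_json(out$truth, file.path(dir, "ground_truth.json"),
                         dataframe = "columns", auto_unbox = TRUE)
  }
  out
}
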