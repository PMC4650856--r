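test_that("same seed gives bit-identical synthetic studies", {
  s1 <- simulate_study(synthetic_config(rng_seed = 5))
  s2 <- simulate_study(synthetic_config(rng_seed = 5))
  expect_identical(s1, s2)
  s3 <- simulate_study(synthetic_config(rng_seed = 6))
  expect_false(identical(unclass(s1$mrna), unclass(s3$mrna)))
})

test_that("edge generation honours density, decoy fraction and role constraints", {
  # density chosen so the candidate budget is exactly 100 pairs
  n_pairs <- 12 * 80 + 12 * 12 + 12 * 80
  cfg <- synthetic_config(regulation_density = 100 / n_pairs, rng_seed = 2)
  reg <- generate_regulations(cfg)
  expect_equal(nrow(reg$candidates), 100L)
  expect_equal(nrow(reg$true_edges), 50L)

  cfg0 <- synthetic_config(decoy_fraction = 0, rng_seed = 2)
  reg0 <- generate_regulations(cfg0)
  expect_setequal(paste(reg0$candidates$regulator, reg0$candidates$target),
                  paste(reg0$true_edges$regulator, reg0$true_edges$target))

  cfg_nt <- synthetic_config(n_tfs = 0, n_plant_paths = 2, rng_seed = 2,
                             n_seed_tfs = 0, n_seed_mirnas = 7, n_seeds = 22)
  reg_nt <- generate_regulations(cfg_nt)
  expect_true(all(reg_nt$candidates$category == "miRNA->gene"))

  expect_error(generate_regulations(
    synthetic_config(regulation_density = 1e-6, n_plant_paths = 0,
                     n_biomarkers = 0, rng_seed = 1)),
    "zero candidate edges")
})

test_that("true edges carry the planted correlation, decoys do not", {
  cfg <- synthetic_config(n_per_class = c(A = 16, B = 15),
                          n_de_genes = 0, n_biomarkers = 0, rng_seed = 3)
  reg <- generate_regulations(cfg)
  ex <- generate_expression(cfg, reg)
  all_expr <- rbind(unclass(ex$mrna), unclass(ex$mirna))
  edge_cor <- function(e) {
    vapply(seq_len(nrow(e)), function(i)
      stats::cor(all_expr[e$regulator[i], ], all_expr[e$target[i], ]),
      numeric(1))
  }
  r_true <- edge_cor(ex$truth$true_edges)
  expect_gte(mean(abs(r_true) >= 0.8 & abs(r_true) <= 0.97), 0.95)
  # miRNA regulators plant negative correlations
  mir_edges <- ex$truth$true_edges$category == "miRNA->gene"
  expect_true(all(r_true[mir_edges] < 0))
  r_decoy <- edge_cor(ex$truth$decoy_edges)
  expect_gte(mean(abs(r_decoy) < 0.5), 0.99)
})

test_that("mean true-edge correlation converges to alpha_true at large n", {
  cfg <- synthetic_config(n_per_class = c(A = 250, B = 250),
                          n_de_genes = 0, n_biomarkers = 0, rng_seed = 4)
  reg <- generate_regulations(cfg)
  ex <- generate_expression(cfg, reg)
  all_expr <- rbind(unclass(ex$mrna), unclass(ex$mirna))
  r <- vapply(seq_len(nrow(ex$truth$true_edges)), function(i)
    stats::cor(all_expr[ex$truth$true_edges$regulator[i], ],
               all_expr[ex$truth$true_edges$target[i], ]), numeric(1))
  expect_lt(abs(mean(abs(r)) - cfg$alpha_true), 0.02)
})

test_that("planted biomarkers dominate between-class separation", {
  for (s in 1:3) {
    sim <- simulate_study(synthetic_config(rng_seed = s))
    all_expr <- rbind(unclass(sim$mrna), unclass(sim$mirna))
    spn <- sim$metadata$sample_id[sim$metadata$class_label == "SPN"]
    rest <- setdiff(sim$metadata$sample_id, spn)
    sep <- abs(rowMeans(all_expr[, spn]) - rowMeans(all_expr[, rest]))
    bm <- sim$truth$biomarker_genes$feature_id
    de <- sim$truth$de_genes$SPN_vs_normal$feature_id
    null_sep <- sep[setdiff(names(sep), c(bm, de))]
    expect_gt(min(sep[bm]), max(null_sep))
  }
})

test_that("seed list has the configured composition and planted structure", {
  cfg <- synthetic_config(rng_seed = 8)
  reg <- generate_regulations(cfg)
  seeds <- generate_seed_list(cfg, reg)
  expect_length(seeds, 26L)
  roles <- stats::setNames(reg$features$role, reg$features$feature_id)[seeds]
  expect_equal(unname(table(factor(roles, c("TF", "miRNA", "gene")))),
               c(4L, 7L, 15L), ignore_attr = TRUE)
  # designated intermediates are recorded and regulate seed genes
  ex <- generate_expression(cfg, reg)
  expect_length(ex$truth$plant_path_intermediates, cfg$n_plant_paths)
  expect_true(all(ex$truth$hub_targets %in% seeds))

  cfg5 <- synthetic_config(n_plant_paths = 5, targets_per_hub = 3,
                           n_biomarkers = 6, rng_seed = 8)
  ex5 <- generate_expression(cfg5, generate_regulations(cfg5))
  expect_length(ex5$truth$plant_path_intermediates, 5L)

  expect_error(
    generate_seed_list(synthetic_config(n_seeds = 500, n_seed_tfs = 4,
                                        n_seed_mirnas = 7, rng_seed = 1),
                       reg),
    "more features than available")
})

test_that("planted DE genes show the configured fold change", {
  sim <- simulate_study(synthetic_config(rng_seed = 9))
  spn <- sim$metadata$sample_id[sim$metadata$class_label == "SPN"]
  nrm <- sim$metadata$sample_id[sim$metadata$class_label == "normal"]
  de <- sim$truth$de_genes$SPN_vs_normal
  up <- de$feature_id[de$direction == "up"]
  fc <- vapply(up, function(g)
    median_ratio_fc(unclass(sim$mrna)[g, spn], unclass(sim$mrna)[g, nrm]),
    numeric(1))
  # de_log2fc = 2 -> linear fold change close to 4
  expect_true(all(fc > 2.5 & fc < 6.5))
})
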