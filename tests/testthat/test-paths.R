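chain_grn <- function(alphas, nodes) {
  # chain n1 - n2 - ... with given alphas as TF->gene edges
  sc <- data.frame(regulator = nodes[-length(nodes)], target = nodes[-1L],
                   category = "TF->gene", validated = FALSE, alpha = alphas,
                   stringsAsFactors = FALSE)
  build_grn(sc, 0, 0)
}

test_that("path graph carries beta weights and merges antiparallel edges", {
  g1 <- chain_grn(0.9, c("A", "B"))
  gr <- to_path_graph(g1)
  expect_equal(igraph::E(gr)$weight, 0.1)

  sc <- data.frame(regulator = c("A", "B"), target = c("B", "A"),
                   category = "TF->gene", validated = FALSE,
                   alpha = c(0.9, 0.7), stringsAsFactors = FALSE)
  grn <- build_grn(sc, 0, 0)
  und <- to_path_graph(grn, "undirected")
  expect_equal(igraph::ecount(und), 1)
  expect_equal(igraph::E(und)$weight, 0.1) # keeps the smaller beta
  dir <- to_path_graph(grn, "directed")
  expect_equal(igraph::ecount(dir), 2)
})

test_that("seed-pair shortest paths match brute-force enumeration", {
  # 4-node chain: only route A-B-C-D
  grn <- chain_grn(c(0.9, 0.8, 0.9), c("A", "B", "C", "D"))
  p <- seed_pair_paths(to_path_graph(grn), c("A", "D"))
  expect_equal(p$node_sequence, "A,B,C,D")
  expect_equal(p$total_beta, 0.4, tolerance = 1e-9)

  # direct edge beta 0.5 loses to a 0.3 detour
  sc <- data.frame(regulator = c("A", "A", "C"), target = c("B", "C", "B"),
                   category = "TF->gene", validated = FALSE,
                   alpha = c(0.5, 0.9, 0.8), stringsAsFactors = FALSE)
  p2 <- seed_pair_paths(to_path_graph(build_grn(sc, 0, 0)), c("A", "B"))
  expect_equal(p2$node_sequence, "A,C,B")
  expect_equal(p2$total_beta, 0.3, tolerance = 1e-9)

  # disconnected seed yields no paths for its pairs, with a warning
  sc3 <- rbind(sc, data.frame(regulator = "X", target = "Y",
                              category = "TF->gene", validated = FALSE,
                              alpha = 0.9))
  expect_message(
    p3 <- seed_pair_paths(to_path_graph(build_grn(sc3, 0, 0)), c("A", "B", "X")),
    "unreachable")
  expect_equal(nrow(p3), 1L)
  expect_length(attr(p3, "unreachable_pairs"), 2L)

  expect_warning(
    expect_error(seed_pair_paths(to_path_graph(grn), c("A", "nope")),
                 "fewer than 2 seeds"),
    "absent")
})

test_that("Dijkstra equals exhaustive simple-path enumeration on random graphs", {
  set.seed(1234)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    df <- random_edge_df(n, p = 0.45)
    sc <- data.frame(regulator = df$from, target = df$to,
                     category = "TF->gene", validated = FALSE,
                     alpha = 1 - df$w, stringsAsFactors = FALSE)
    g <- to_path_graph(build_grn(sc, 0, 0))
    seeds <- sample(paste0("n", 1:n), 2)
    seeds <- intersect(seeds, igraph::V(g)$name)
    if (length(seeds) < 2) next
    oracle <- enum_shortest(df, seeds[1], seeds[2])
    res <- tryCatch(
      suppressMessages(suppressWarnings(seed_pair_paths(g, seeds))),
      error = function(e) NULL)
    if (is.infinite(oracle)) {
      expect_true(is.null(res) || nrow(res) == 0)
    } else {
      expect_equal(res$total_beta, oracle, tolerance = 1e-9)
    }
  }
})

test_that("tie-breaking prefers fewer hops then lexicographic order", {
  # two co-optimal routes A-B-D and A-C-D (same beta): lexicographic pick
  sc <- data.frame(regulator = c("A", "B", "A", "C"),
                   target = c("B", "D", "C", "D"),
                   category = "TF->gene", validated = FALSE,
                   alpha = c(0.9, 0.9, 0.9, 0.9), stringsAsFactors = FALSE)
  g <- to_path_graph(build_grn(sc, 0, 0))
  p <- seed_pair_paths(g, c("A", "D"))
  expect_equal(p$node_sequence, "A,B,D")
  pall <- seed_pair_paths(g, c("A", "D"), all_co_optimal = TRUE)
  expect_setequal(pall$node_sequence, c("A,B,D", "A,C,D"))
})

test_that("path genes are interior nodes minus seeds, with provenance", {
  grn <- chain_grn(c(0.9, 0.8, 0.9), c("A", "X", "Y", "B"))
  p <- seed_pair_paths(to_path_graph(grn), c("A", "B"))
  pg <- extract_path_genes(p, c("A", "B"),
                           roles = c(A = "gene", X = "TF", Y = "miRNA", B = "gene"))
  expect_setequal(pg$genes$gene_id, c("X", "Y"))
  expect_equal(pg$genes$pairs, rep("A|B", 2))
  expect_equal(as.integer(pg$role_counts[c("TF", "miRNA")]), c(1L, 1L))

  # a direct-edge path contributes no interior genes
  direct <- seed_pair_paths(to_path_graph(chain_grn(0.9, c("A", "B"))), c("A", "B"))
  expect_equal(nrow(extract_path_genes(direct, c("A", "B"))$genes), 0L)
})

test_that("sub-network export unions path edges without duplicates", {
  sc <- data.frame(regulator = c("A", "X", "X"), target = c("X", "B", "C"),
                   category = "TF->gene", validated = FALSE,
                   alpha = rep(0.9, 3), stringsAsFactors = FALSE)
  g <- to_path_graph(build_grn(sc, 0, 0))
  p <- suppressMessages(seed_pair_paths(g, c("A", "B", "C")))
  sub <- export_subnetwork(p, c("A", "B", "C"))
  # brute-force union of consecutive node pairs
  oracle <- unique(do.call(rbind, lapply(strsplit(p$node_sequence, ","), function(ns) {
    data.frame(from = pmin(ns[-length(ns)], ns[-1]),
               to = pmax(ns[-length(ns)], ns[-1]))
  })))
  expect_equal(nrow(sub$edges), nrow(oracle))
  expect_setequal(paste(sub$edges$from, sub$edges$to),
                  paste(oracle$from, oracle$to))
  expect_setequal(sub$nodes$type[sub$nodes$id == "X"], "candidate")

  empty <- p[0, ]
  expect_equal(nrow(export_subnetwork(empty, "A")$edges), 0L)
})

test_that("planted path intermediates are recovered on synthetic data", {
  sim <- simulate_study(synthetic_config(rng_seed = 41))
  net <- merge_candidate_edges(list(sim$candidates))
  spn <- sim$metadata$sample_id[sim$metadata$class_label == "SPN"]
  sc <- suppressMessages(score_edges(net, sim$mrna, sim$mirna, spn))
  grn <- build_grn(sc, 0.8, 0.8, sim$annotation)
  p <- suppressMessages(suppressWarnings(
    seed_pair_paths(to_path_graph(grn), sim$seeds)))
  pg <- extract_path_genes(p, sim$seeds, sim$annotation)
  expect_true(all(sim$truth$plant_path_intermediates %in% pg$genes$gene_id))
})
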