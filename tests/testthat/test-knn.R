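test_that("Chou cumulative voting matches direct evaluation of the sum", {
  y <- chou_score(c("A", "A", "B"), 3)
  expect_equal(y[["A"]], 5) # ranks 1,2 contribute 3 + 2
  expect_equal(y[["B"]], 1)

  y2 <- chou_score(c("A", "B"), 2)
  expect_equal(y2[["A"]], 2)
  expect_equal(y2[["B"]], 1)

  # all neighbours one class: closed form k_max (k_max + 1) / 2
  for (k in c(1, 3, 5))
    expect_equal(chou_score(rep("C", k), k)[["C"]], k * (k + 1) / 2)

  expect_error(chou_score(character(0), 1), "empty")
  expect_error(chou_score(c("A", "B"), 5), "exceeds")
})

knn_fixture <- function(n_per_class = c(A = 6, B = 6), mu = c(A = 0, B = 10),
                        sd = 0.1, n_genes = 2, seed = 1) {
  set.seed(seed)
  labs <- rep(names(n_per_class), n_per_class)
  v <- sapply(labs, function(cl) rnorm(n_genes, mu[[cl]], sd))
  dimnames(v) <- list(paste0("g", seq_len(n_genes)),
                      sprintf("s%02d", seq_along(labs)))
  list(m = expression_matrix(v, "log2"),
       labels = stats::setNames(labs, colnames(v)))
}

test_that("KNN prediction respects separation and deterministic tie rules", {
  fx <- knn_fixture()
  # query identical to a training sample at k_max = 1 returns its label
  q <- unclass(fx$m)[, "s01"]
  expect_equal(knn_predict(fx$m, fx$labels, q, rownames(fx$m),
                           knn_config(k_max = 1)), "A")
  # well-separated clusters classify by locality for any config
  for (cfg in list(knn_config(1), knn_config(3), knn_config(voting = "plain_majority"))) {
    expect_equal(knn_predict(fx$m, fx$labels, c(g1 = 9.9, g2 = 10.2),
                             rownames(fx$m), cfg), "B")
    expect_equal(knn_predict(fx$m, fx$labels, c(g1 = 0.1, g2 = -0.1),
                             rownames(fx$m), cfg), "A")
  }
  # equidistant neighbours rank by sample id
  v <- matrix(c(1, -1), 1, 2, dimnames = list("g1", c("s01", "s02")))
  m <- expression_matrix(v, "log2")
  lab <- c(s01 = "A", s02 = "B")
  expect_equal(knn_predict(m, lab, c(g1 = 0), "g1", knn_config(k_max = 2)), "A")
  expect_error(knn_predict(fx$m, fx$labels, c(g1 = 1), rownames(fx$m)),
               "lacks values")
})

test_that("Chou voting at k_max = 1 equals plain 1-NN on random data", {
  set.seed(8)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    v <- matrix(rnorm(3 * n), 3,
                dimnames = list(paste0("g", 1:3), sprintf("s%02d", 1:n)))
    m <- expression_matrix(v, "log2")
    labs <- stats::setNames(sample(c("A", "B"), n, replace = TRUE), colnames(v))
    if (length(unique(labs)) < 2) next
    q <- rnorm(3); names(q) <- rownames(v)
    p_chou <- knn_predict(m, labs, q, rownames(v), knn_config(k_max = 1))
    p_1nn <- knn_predict(m, labs, q, rownames(v),
                         knn_config(voting = "plain_majority", k_plain = 1))
    expect_identical(p_chou, p_1nn)
  }
})

test_that("jackknife accuracy follows its defining ratio and flags bad classes", {
  fx <- knn_fixture()
  jk <- jackknife_accuracy(fx$m, fx$labels, rownames(fx$m))
  expect_equal(jk$accuracy_percent, 100)
  expect_equal(jk$accuracy_percent, accuracy_from_records(jk))

  fx2 <- knn_fixture(mu = c(A = 0, B = 0.05), sd = 1, seed = 2)
  jk2 <- jackknife_accuracy(fx2$m, fx2$labels, rownames(fx2$m))
  expect_equal(jk2$accuracy_percent, accuracy_from_records(jk2))

  bad <- c(s01 = "A", s02 = "B", s03 = "B", s04 = "B")
  v <- matrix(rnorm(4), 1, dimnames = list("g1", names(bad)))
  expect_error(jackknife_accuracy(expression_matrix(v, "log2"), bad, "g1"),
               "single sample.*A")
})

test_that("predictions are translation invariant and feature-order invariant", {
  fx <- knn_fixture(n_genes = 4, seed = 3)
  jk <- jackknife_accuracy(fx$m, fx$labels, rownames(fx$m))
  shifted <- expression_matrix(unclass(fx$m) + 7.5, "log2")
  jk_s <- jackknife_accuracy(shifted, fx$labels, rownames(fx$m))
  expect_equal(jk$per_sample$predicted_label, jk_s$per_sample$predicted_label)
  jk_r <- jackknife_accuracy(fx$m, fx$labels, rev(rownames(fx$m)))
  expect_equal(jk$per_sample$predicted_label, jk_r$per_sample$predicted_label)
})

test_that("a dominant-variance gene controls the joint prediction", {
  set.seed(9)
  n <- 10
  big <- rep(c(0, 100), each = n / 2) + rnorm(n)
  small <- rnorm(n, 0, 0.01)
  v <- rbind(gBig = big, gSmall = small)
  colnames(v) <- sprintf("s%02d", 1:n)
  m <- expression_matrix(v, "log2")
  labs <- stats::setNames(rep(c("A", "B"), each = n / 2), colnames(v))
  joint <- jackknife_accuracy(m, labs, c("gBig", "gSmall"))
  solo <- jackknife_accuracy(m, labs, "gBig")
  expect_equal(joint$per_sample$predicted_label, solo$per_sample$predicted_label)
})

test_that("per-gene table ranks planted biomarkers first on synthetic data", {
  sim <- simulate_study(synthetic_config(rng_seed = 15))
  md <- sim$metadata[sim$metadata$class_label %in% c("SPN", "PanNET", "PDAC"), ]
  labs <- stats::setNames(ifelse(md$class_label == "SPN", "SPN", "malignant"),
                          md$sample_id)
  all_expr <- rbind(unclass(sim$mrna), unclass(sim$mirna))
  m <- expression_matrix(all_expr[, md$sample_id], "log2")
  bm <- sim$truth$biomarker_genes$feature_id
  others <- sample(setdiff(rownames(m), bm), 12)
  tab <- per_gene_accuracy(m, labs, c(bm, others))
  expect_equal(nrow(tab), length(bm) + 12L)
  expect_true(all(bm %in% tab$gene_id[seq_along(bm)]))
})

test_that("biomarker set selection reaches perfect planted separation", {
  sim <- simulate_study(synthetic_config(rng_seed = 16))
  md <- sim$metadata[sim$metadata$class_label %in% c("SPN", "PanNET", "PDAC"), ]
  labs <- stats::setNames(ifelse(md$class_label == "SPN", "SPN", "malignant"),
                          md$sample_id)
  all_expr <- rbind(unclass(sim$mrna), unclass(sim$mirna))
  m <- expression_matrix(all_expr[, md$sample_id], "log2")
  bm <- sim$truth$biomarker_genes$feature_id
  pool <- c(bm, sample(setdiff(rownames(m), bm), 10))
  tab <- per_gene_accuracy(m, labs, pool)
  sel <- select_biomarker_set(tab, m, labs)
  expect_equal(sel$result$accuracy_percent, 100)

  thr <- select_biomarker_set(tab, m, labs, strategy = "threshold",
                              threshold = 100)
  expect_setequal(thr$gene_set, tab$gene_id[tab$accuracy_percent >= 100])
})
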