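#' KNN classifier configuration
#'
#' Distance is Euclidean over the selected genes' log2 expression. Chou's
#' cumulative voting scores each class by summing its neighbour counts
#' over every horizon K = 1..k_max — equivalently the neighbour at rank r
#' contributes `k_max - r + 1` votes — which removes the need to commit to
#' a single K. `k_max = 1` reduces to plain 1-NN. Plain majority voting
#' over a fixed odd `k_plain` is available as an alternative.
#'
#' @param k_max cumulative voting horizon (default 3: with the smallest
#'   class holding 5-6 samples, leave-one-out leaves 4-5 same-class
#'   neighbours).
#' @param voting `"chou"` or `"plain_majority"`.
#' @param k_plain odd neighbour count for plain majority voting.
#' @return list of class `knn_config`.
#' @export
knn_config <- function(k_max = 3L, voting = c("chou", "plain_majority"),
                       k_plain = 3L) {
  voting <- match.arg(voting)
  if (k_max < 1L) stop("`k_max` must be >= 1", call. = FALSE)
  if (voting == "plain_majority" && k_plain %% 2L == 0L)
    stop("`k_plain` must be odd", call. = FALSE)
  structure(list(k_max = as.integer(k_max), voting = voting,
                 k_plain = as.integer(k_plain)), class = "knn_config")
}

#' Chou cumulative voting scores
#'
#' @param ranked_labels class labels of the training samples ordered
#'   nearest-first.
#' @param k_max voting horizon, at most `length(ranked_labels)`.
#' @return named numeric vector of per-class scores Y_m.
#' @export
chou_score <- function(ranked_labels, k_max) {
  if (!length(ranked_labels)) stop("empty neighbour list", call. = FALSE)
  if (k_max > length(ranked_labels))
    stop("`k_max` exceeds the number of neighbours", call. = FALSE)
  lab <- ranked_labels[seq_len(k_max)]
  w <- rev(seq_len(k_max)) # rank r contributes k_max - r + 1
  vapply(split(w, lab), sum, numeric(1))
}

# rank training samples by distance; ties broken by sample id
rank_neighbours <- function(train, query) {
  d <- sqrt(colSums((train - query)^2))
  colnames(train)[order(d, colnames(train), method = "radix")]
}

#' Predict the class of one sample by KNN
#'
#' Ties are deterministic: equidistant neighbours rank by sample id;
#' tied class scores go to the single nearest neighbour's class when it
#' is among the tied classes, else to the lexicographically first tied
#' class.
#'
#' @param m an [expression_matrix()] (features x samples) of training
#'   samples.
#' @param labels named character vector (or metadata data.frame) of
#'   training class labels.
#' @param query numeric vector named by feature, or a single-column
#'   matrix.
#' @param gene_set features to use.
#' @param cfg a [knn_config()].
#' @return predicted class label (character scalar).
#' @export
knn_predict <- function(m, labels, query, gene_set, cfg = knn_config()) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$class_label, labels$sample_id)
  if (!length(gene_set)) stop("`gene_set` is empty", call. = FALSE)
  v <- unclass(m)
  missing_g <- setdiff(gene_set, rownames(v))
  if (length(missing_g))
    stop("feature(s) missing from the matrix: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  if (length(unique(labels[colnames(v)])) < 2L)
    stop("training data must contain >= 2 classes", call. = FALSE)
  q <- if (is.matrix(query)) query[gene_set, 1L] else query[gene_set]
  if (anyNA(q)) stop("query lacks values for some features", call. = FALSE)
  train <- v[gene_set, , drop = FALSE]
  ranked <- rank_neighbours(train, q)
  ranked_labels <- unname(labels[ranked])
  if (cfg$voting == "chou") {
    scores <- chou_score(ranked_labels, min(cfg$k_max, length(ranked_labels)))
  } else {
    k <- min(cfg$k_plain, length(ranked_labels))
    scores <- vapply(split(rep(1, k), ranked_labels[seq_len(k)]), sum, numeric(1))
  }
  winners <- names(scores)[scores == max(scores)]
  if (length(winners) == 1L) return(winners)
  if (ranked_labels[1L] %in% winners) return(ranked_labels[1L])
  sort(winners)[1L]
}

#' Jackknife (leave-one-out) accuracy of a gene set
#'
#' Each sample is predicted from all remaining samples; accuracy is
#' 100 x (correct predictions) / (prediction events).
#'
#' @inheritParams knn_predict
#' @return Object of class `jackknife_result`: `gene_set`, `per_sample`
#'   (sample_id, true_label, predicted_label, correct) and
#'   `accuracy_percent`.
#' @export
jackknife_accuracy <- function(m, labels, gene_set, cfg = knn_config()) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$class_label, labels$sample_id)
  v <- unclass(m)
  samples <- intersect(colnames(v), names(labels))
  labels <- labels[samples]
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("class(es) with a single sample cannot be jackknifed: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  pred <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    train <- expression_matrix(v[, setdiff(samples, s), drop = FALSE],
                               scale = expr_scale(m) %||% "log2")
    pred[i] <- knn_predict(train, labels[setdiff(samples, s)],
                           v[, s], gene_set, cfg)
  }
  per_sample <- data.frame(sample_id = samples,
                           true_label = unname(labels),
                           predicted_label = pred,
                           correct = pred == unname(labels),
                           stringsAsFactors = FALSE)
  structure(list(gene_set = gene_set, per_sample = per_sample,
                 accuracy_percent = 100 * sum(per_sample$correct) /
                   nrow(per_sample)),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("jackknife_result: %d gene(s), %d samples, accuracy %.1f%%\n",
              length(x$gene_set), nrow(x$per_sample), x$accuracy_percent))
  invisible(x)
}

#' Per-gene jackknife accuracy table
#'
#' Evaluates every candidate gene as a singleton classifier; rows are
#' sorted by decreasing accuracy (ties by gene id for determinism).
#'
#' @inheritParams knn_predict
#' @param candidate_genes features to evaluate one at a time.
#' @return data.frame: gene_id, accuracy_percent.
#' @export
per_gene_accuracy <- function(m, labels, candidate_genes, cfg = knn_config()) {
  acc <- vapply(candidate_genes, function(g)
    jackknife_accuracy(m, labels, g, cfg)$accuracy_percent, numeric(1))
  out <- data.frame(gene_id = candidate_genes, accuracy_percent = unname(acc),
                    stringsAsFactors = FALSE)
  out[order(-out$accuracy_percent, out$gene_id), , drop = FALSE]
}

#' Select a biomarker gene set
#'
#' `"greedy"` (default): walk the per-gene table in decreasing singleton
#' accuracy, adding a gene whenever it strictly improves the joint
#' jackknife accuracy, stopping at 100 percent or exhaustion. The
#' published analyses report the final set and its joint accuracy without
#' stating the assembly rule, so the strategy is pluggable:
#' `"threshold"` keeps every gene whose singleton accuracy reaches
#' `threshold` (default 100).
#'
#' @inheritParams knn_predict
#' @param per_gene data.frame from [per_gene_accuracy()].
#' @param strategy `"greedy"` or `"threshold"`.
#' @param threshold singleton accuracy cutoff for `"threshold"`.
#' @return list: `gene_set`, `result` (a `jackknife_result` for the set).
#' @export
select_biomarker_set <- function(per_gene, m, labels, cfg = knn_config(),
                                 strategy = c("greedy", "threshold"),
                                 threshold = 100) {
  strategy <- match.arg(strategy)
  if (strategy == "threshold") {
    set <- per_gene$gene_id[per_gene$accuracy_percent >= threshold]
    if (!length(set)) return(list(gene_set = character(0), result = NULL))
    return(list(gene_set = set,
                result = jackknife_accuracy(m, labels, set, cfg)))
  }
  set <- character(0)
  best <- -Inf
  best_res <- NULL
  for (g in per_gene$gene_id) {
    cand <- c(set, g)
    res <- jackknife_accuracy(m, labels, cand, cfg)
    if (res$accuracy_percent > best) {
      set <- cand; best <- res$accuracy_percent; best_res <- res
      if (best >= 100) break
    }
  }
  list(gene_set = set, result = best_res)
}
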