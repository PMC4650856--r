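#' Median-ratio fold change on log2 data
#'
#' Linear-scale ratio of group medians, computed from log2 values as
#' `2^(median(A) - median(B))`.
#'
#' @param a,b numeric vectors of log2 expression for groups A and B.
#' @return positive scalar fold change (A over B).
#' @export
median_ratio_fc <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  2^(stats::median(a) - stats::median(b))
}

#' Two-sample t-test p-value
#'
#' Equal-variance Student's t by default (`var_equal = FALSE` switches to
#' Welch). Degenerate data where both groups are constant yields `p = 1`
#' when the means agree and `p = 0` otherwise, by convention.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return two-sided p-value.
#' @export
de_t_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 samples", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

#' Call differentially expressed features between two sample groups
#'
#' A feature is differentially expressed when its two-sided t-test p-value
#' is below `p_threshold` (strict `<`) and its median-ratio fold change is
#' `>= fc_threshold` or `<= 1/fc_threshold`. No multiple-testing
#' correction enters the call; a Benjamini-Hochberg FDR column is emitted
#' for information only.
#'
#' @param m an [expression_matrix()] on the log2 scale.
#' @param metadata data.frame (`sample_id`, `class_label`).
#' @param class_a,class_b character vectors of class labels forming the
#'   two sides of the contrast (pooled when more than one label, e.g.
#'   `c("PanNET", "PDAC")` for a malignant group).
#' @param p_threshold p-value cutoff (default 0.01).
#' @param fc_threshold linear fold-change cutoff (default 2).
#' @param var_equal see [de_t_test()].
#' @return data.frame: feature_id, p_value, fold_change, fdr, is_de,
#'   direction ("up"/"down"/"none", A relative to B).
#' @export
call_de <- function(m, metadata, class_a, class_b,
                    p_threshold = 0.01, fc_threshold = 2, var_equal = TRUE) {
  stopifnot(inherits(m, "expr_matrix"))
  known <- unique(metadata$class_label)
  bad <- setdiff(c(class_a, class_b), known)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  sa <- metadata$sample_id[metadata$class_label %in% class_a]
  sb <- metadata$sample_id[metadata$class_label %in% class_b]
  sa <- intersect(sa, colnames(m)); sb <- intersect(sb, colnames(m))
  if (length(sa) < 2L || length(sb) < 2L)
    stop("both contrast groups need >= 2 samples in the matrix", call. = FALSE)
  v <- unclass(m)
  p <- fc <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    p[i] <- de_t_test(v[i, sa], v[i, sb], var_equal = var_equal)
    fc[i] <- median_ratio_fc(v[i, sa], v[i, sb])
  }
  is_de <- p < p_threshold & (fc >= fc_threshold | fc <= 1 / fc_threshold)
  data.frame(feature_id = rownames(v), p_value = p, fold_change = fc,
             fdr = stats::p.adjust(p, method = "BH"),
             is_de = is_de,
             direction = ifelse(!is_de, "none", ifelse(fc > 1, "up", "down")),
             stringsAsFactors = FALSE)
}
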