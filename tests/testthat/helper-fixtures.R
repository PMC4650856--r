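# shared fixtures and independent oracles, built in code

# small expression matrix with default ids
em <- function(values, scale = "log2", features = NULL, samples = NULL) {
  m <- as.matrix(values)
  dimnames(m) <- list(features %||% sprintf("f%02d", seq_len(nrow(m))),
                      samples %||% sprintf("s%02d", seq_len(ncol(m))))
  expression_matrix(m, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force minimum-weight simple path by DFS over all simple paths
enum_shortest <- function(edges, s, t) {
  # edges: data.frame(from, to, w), undirected
  nbr <- function(v) {
    i <- edges$from == v; j <- edges$to == v
    rbind(data.frame(v = edges$to[i], w = edges$w[i]),
          data.frame(v = edges$from[j], w = edges$w[j]))
  }
  best <- Inf
  walk <- function(v, visited, len) {
    if (len >= best) return(invisible())
    if (v == t) { best <<- len; return(invisible()) }
    nb <- nbr(v)
    for (k in seq_len(nrow(nb))) {
      if (!(nb$v[k] %in% visited))
        walk(nb$v[k], c(visited, nb$v[k]), len + nb$w[k])
    }
  }
  walk(s, s, 0)
  best
}

# random connected-ish weighted graph on <= n_max nodes
random_edge_df <- function(n, p = 0.5) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1L)] <- TRUE
  data.frame(from = paste0("n", pairs[keep, 1]),
             to = paste0("n", pairs[keep, 2]),
             w = stats::runif(sum(keep)), stringsAsFactors = FALSE)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- stats::dhyper(x, m, n, k)
  # standard tie tolerance for "as likely or less likely"
  sum(pr[pr <= pr[a - lo + 1L] * (1 + 1e-7)])
}

# tiny scored edge table for GRN tests
scored_fixture <- function(alpha, category = "TF->gene") {
  data.frame(regulator = sprintf("r%02d", seq_along(alpha)),
             target = sprintf("t%02d", seq_along(alpha)),
             category = rep(category, length.out = length(alpha)),
             validated = FALSE, alpha = alpha, stringsAsFactors = FALSE)
}

# jackknife accuracy recomputed by definition from per-sample records
accuracy_from_records <- function(jk) {
  100 * sum(jk$per_sample$predicted_label == jk$per_sample$true_label) /
    nrow(jk$per_sample)
}
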