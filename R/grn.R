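#' Score candidate edges by Pearson co-expression
#'
#' Attaches to each candidate edge the Pearson correlation `alpha` of its
#' regulator and target expression vectors across a chosen sample subset.
#' Regulator/target vectors are looked up in the miRNA matrix for miRNA
#' features and in the mRNA matrix otherwise. The default subset for a
#' tissue-specific network is the disease-class samples only; pass all
#' sample ids to correlate across the whole cohort. Edges with a constant
#' expression vector (undefined correlation) or an endpoint missing from
#' both matrices are dropped with a message.
#'
#' @param network a `candidate_network` or an edge data.frame with columns
#'   `regulator`, `target`, `category`.
#' @param mrna,mirna [expression_matrix()]s sharing sample ids.
#' @param sample_subset character vector of >= 3 sample ids.
#' @return The edge data.frame with an `alpha` column appended.
#' @export
score_edges <- function(network, mrna, mirna, sample_subset) {
  edges <- if (inherits(network, "candidate_network")) network$edges else network
  if (length(sample_subset) < 3L)
    stop("correlation needs >= 3 samples", call. = FALSE)
  missing_s <- setdiff(sample_subset, intersect(colnames(mrna), colnames(mirna)))
  if (length(missing_s))
    stop("sample(s) absent from the expression matrices: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  get_vec <- function(id) {
    if (id %in% rownames(mirna)) return(unclass(mirna)[id, sample_subset])
    if (id %in% rownames(mrna)) return(unclass(mrna)[id, sample_subset])
    NULL
  }
  alpha <- rep(NA_real_, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    r <- get_vec(edges$regulator[i]); tg <- get_vec(edges$target[i])
    if (is.null(r) || is.null(tg)) next
    if (stats::sd(r) == 0 || stats::sd(tg) == 0) next
    alpha[i] <- stats::cor(r, tg)
  }
  dropped <- sum(is.na(alpha))
  if (dropped > 0L)
    message(sprintf("score_edges: dropped %d edge(s) with missing or constant expression",
                    dropped))
  out <- edges[!is.na(alpha), , drop = FALSE]
  out$alpha <- alpha[!is.na(alpha)]
  rownames(out) <- NULL
  out
}

#' Fit a power law to a degree distribution
#'
#' Models the degree distribution as `p(k) = k^-lambda` and estimates
#' `lambda` by ordinary least squares of `log10 p(k)` on `log10 k` over
#' the distinct degrees `k >= 1` with nonzero frequency (zero-frequency
#' bins are undefined on the log scale and excluded; no binning is
#' applied). The fit's R-squared measures scale-free-ness: biological
#' regulatory networks typically show `2 < lambda < 3`.
#'
#' @param k either an integer vector of node degrees (a histogram is
#'   formed internally over `k >= 1`), or, when `p` is given, the distinct
#'   degree values.
#' @param p optional probabilities `p(k)` aligned with `k`.
#' @return list with `lambda_hat`, `r_squared`, `n_points`.
#' @export
fit_power_law <- function(k, p = NULL) {
  if (is.null(p)) {
    k <- k[k >= 1]
    if (!length(k)) stop("no nodes with degree >= 1", call. = FALSE)
    tab <- table(k)
    kk <- as.numeric(names(tab))
    p <- as.numeric(tab) / sum(tab)
  } else {
    stopifnot(length(k) == length(p))
    keep <- p > 0 & k >= 1
    kk <- as.numeric(k[keep]); p <- as.numeric(p[keep])
  }
  if (length(kk) < 3L)
    stop("power-law fit needs >= 3 distinct degrees with nonzero frequency",
         call. = FALSE)
  x <- log10(kk); y <- log10(p)
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  ss_res <- sum((y - my - slope * (x - mx))^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  list(lambda_hat = -slope, r_squared = r2, n_points = length(kk))
}

# degrees of one regulator-class sub-network at a cutoff
subnetwork_degrees <- function(edges, subnetwork, direction) {
  sel <- if (subnetwork == "miRNA_regulator") edges$category == "miRNA->gene"
         else edges$category %in% c("TF->gene", "TF->miRNA")
  e <- edges[sel, , drop = FALSE]
  deg <- if (direction == "in_degree") table(e$target) else table(e$regulator)
  list(degrees = as.integer(deg), n_edges = nrow(e),
       n_targets = length(unique(e$target)),
       n_regulators = length(unique(e$regulator)))
}

#' Scan correlation cutoffs by power-law fitness
#'
#' For each cutoff in `grid`, each regulator-class sub-network (miRNA
#' regulators; TF regulators) and each degree direction, thresholds the
#' scored edges at `|alpha| >= cutoff` and fits the power law to the
#' resulting degree distribution. In-degree fitness (targets per
#' regulator) is the selection criterion; out-degree fits are reported for
#' completeness. The scan is advisory: it reproduces the
#' fitness-versus-size trade-off a user inspects before fixing the cutoff
#' (default 0.8) in [build_grn()].
#'
#' @param scored edge data.frame with `alpha` (see [score_edges()]).
#' @param grid numeric vector of cutoffs in `[0, 1)`.
#' @return data.frame: cutoff, subnetwork, direction, lambda_hat,
#'   r_squared, n_edges, n_targets, n_regulators, fit_ok.
#' @export
scan_cutoffs <- function(scored, grid = seq(0, 0.9, by = 0.1)) {
  stopifnot(all(grid >= 0 & grid < 1))
  rows <- list()
  for (cut in grid) {
    retained <- scored[abs(scored$alpha) >= cut, , drop = FALSE]
    for (sub in c("miRNA_regulator", "TF_regulator")) {
      for (dir in c("in_degree", "out_degree")) {
        d <- subnetwork_degrees(retained, sub, dir)
        fit <- tryCatch(fit_power_law(d$degrees), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          cutoff = cut, subnetwork = sub, direction = dir,
          lambda_hat = if (is.null(fit)) NA_real_ else fit$lambda_hat,
          r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
          n_edges = d$n_edges, n_targets = d$n_targets,
          n_regulators = d$n_regulators,
          fit_ok = !is.null(fit), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build the weighted gene regulatory network
#'
#' Retains scored candidate edges whose `|alpha|` reaches the cutoff for
#' their regulator class (ties at the cutoff are kept) and attaches the
#' path weight `beta = 1 - |alpha|`, so strong co-expression means short
#' path distance.
#'
#' @param scored edge data.frame with `alpha` (see [score_edges()]).
#' @param cutoff_tf,cutoff_mirna correlation cutoffs in `[0, 1)` for
#'   TF-regulated and miRNA-regulated edges (default 0.8 for both).
#' @param annotation optional feature annotation used for node roles;
#'   when absent, roles are inferred from edge categories.
#' @return Object of class `grn`: `nodes` (id, role), `edges` (regulator,
#'   target, category, alpha, beta, validated flag), `cutoffs`, `counts`.
#' @export
build_grn <- function(scored, cutoff_tf = 0.8, cutoff_mirna = 0.8,
                      annotation = NULL) {
  if (cutoff_tf < 0 || cutoff_tf >= 1 || cutoff_mirna < 0 || cutoff_mirna >= 1)
    stop("cutoffs must be in [0, 1)", call. = FALSE)
  cut_for <- ifelse(scored$category == "miRNA->gene", cutoff_mirna, cutoff_tf)
  edges <- scored[abs(scored$alpha) >= cut_for, , drop = FALSE]
  edges$beta <- 1 - abs(edges$alpha)
  rownames(edges) <- NULL
  if (!nrow(edges)) warning("GRN is empty at the chosen cutoffs", call. = FALSE)
  ids <- unique(c(edges$regulator, edges$target))
  if (!is.null(annotation)) {
    role <- stats::setNames(annotation$role, annotation$feature_id)[ids]
  } else {
    role <- rep("gene", length(ids)); names(role) <- ids
    role[ids %in% edges$regulator[edges$category != "miRNA->gene"]] <- "TF"
    role[ids %in% c(edges$regulator[edges$category == "miRNA->gene"],
                    edges$target[edges$category == "TF->miRNA"])] <- "miRNA"
  }
  nodes <- data.frame(id = ids, role = unname(role), stringsAsFactors = FALSE)
  counts <- c(table(factor(edges$category,
                           levels = c("TF->gene", "TF->miRNA", "miRNA->gene"))),
              validated = if ("validated" %in% names(edges)) sum(edges$validated) else 0L)
  structure(list(nodes = nodes, edges = edges,
                 cutoffs = c(TF = cutoff_tf, miRNA = cutoff_mirna),
                 counts = counts),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("grn: %d nodes (%d TF, %d miRNA, %d gene), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "TF"),
              sum(x$nodes$role == "miRNA"), sum(x$nodes$role == "gene"),
              nrow(x$edges)))
  cat(sprintf("cutoffs: |alpha| >= %.2f (TF), >= %.2f (miRNA)\n",
              x$cutoffs[["TF"]], x$cutoffs[["miRNA"]]))
  invisible(x)
}

#' @export
summary.grn <- function(object, ...) {
  cat(sprintf("Gene regulatory network (beta = 1 - |alpha|)\n"))
  print(object)
  for (nm in names(object$counts))
    cat(sprintf("  %-12s %d\n", nm, object$counts[[nm]]))
  if (nrow(object$edges))
    cat(sprintf("  |alpha| range: %.3f - %.3f\n",
                min(abs(object$edges$alpha)), max(abs(object$edges$alpha))))
  invisible(object)
}

#' Write a GRN edge table to TSV
#' @param grn a `grn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grn <- function(grn, path) {
  cols <- intersect(c("regulator", "target", "category", "alpha", "beta",
                      "predicted", "validated"), names(grn$edges))
  write_tsv(grn$edges[, cols], path)
}
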