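#' Convert a GRN to a beta-weighted path graph
#'
#' Edge weight is `beta = 1 - |alpha|`, so the shortest path is the chain
#' of strongest regulations. The default undirected view lets paths run
#' against regulation direction — many seed genes are pure targets with no
#' outgoing edges, and paths between such pairs only exist undirected.
#' Antiparallel duplicates are merged keeping the smaller beta; directed
#' mode preserves both directions.
#'
#' @param grn a `grn` (see [build_grn()]).
#' @param mode `"undirected"` (default) or `"directed"`.
#' @return An igraph graph with edge attribute `weight` (= beta).
#' @export
to_path_graph <- function(grn, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  e <- grn$edges
  if (!nrow(e)) stop("GRN has no edges", call. = FALSE)
  if (mode == "undirected") {
    a <- pmin(e$regulator, e$target)
    b <- pmax(e$regulator, e$target)
    beta <- stats::ave(e$beta, paste(a, b, sep = "\r"), FUN = min)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    df <- data.frame(from = a[keep], to = b[keep], weight = beta[keep],
                     stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(df, directed = FALSE,
                                  vertices = grn$nodes$id)
  } else {
    df <- data.frame(from = e$regulator, to = e$target, weight = e$beta,
                     stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(df, directed = TRUE, vertices = grn$nodes$id)
  }
}

# TRUE when sequence a precedes b: fewer hops first, then lexicographic
path_precedes <- function(a, b) {
  if (length(a) != length(b)) return(length(a) < length(b))
  for (i in seq_along(a)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  FALSE
}

#' Shortest beta-weighted paths between all seed pairs
#'
#' Runs Dijkstra between every unordered pair of mapped seeds. Seeds
#' absent from the graph are skipped with a warning; pairs in different
#' components yield no path and are reported in the `unreachable`
#' attribute — with real data not every literature seed participates.
#' Among co-optimal (equal total beta) paths the default pick is
#' deterministic: fewest hops, then the lexicographically smallest node
#' sequence; `all_co_optimal = TRUE` returns every co-optimal path
#' instead.
#'
#' @param graph weighted graph from [to_path_graph()].
#' @param seeds character vector of seed feature ids.
#' @param all_co_optimal return all tied-optimal paths per pair.
#' @return data.frame: source, target, total_beta, n_hops, node_sequence
#'   (comma-joined); attributes `unmapped_seeds`, `unreachable_pairs`.
#' @export
seed_pair_paths <- function(graph, seeds, all_co_optimal = FALSE) {
  seeds <- unique(seeds)
  mapped <- sort(intersect(seeds, igraph::V(graph)$name))
  unmapped <- setdiff(seeds, mapped)
  if (length(unmapped))
    warning(sprintf("%d seed(s) absent from the network: %s",
                    length(unmapped), paste(unmapped, collapse = ", ")),
            call. = FALSE)
  if (length(mapped) < 2L)
    stop("fewer than 2 seeds map to the network", call. = FALSE)
  rows <- list()
  unreachable <- list()
  for (i in seq_len(length(mapped) - 1L)) {
    for (j in seq((i + 1L), length(mapped))) {
      s <- mapped[i]; t <- mapped[j]
      res <- suppressWarnings(
        igraph::all_shortest_paths(graph, from = s, to = t,
                                   weights = igraph::E(graph)$weight))
      paths <- res$vpaths %||% res$res
      if (!length(paths)) {
        unreachable[[length(unreachable) + 1L]] <- c(s, t)
        next
      }
      seqs <- lapply(paths, function(p) igraph::V(graph)$name[as.integer(p)])
      total <- vapply(seqs, function(nm) path_length(graph, nm), numeric(1))
      if (all_co_optimal) {
        keep <- seq_along(seqs)
      } else {
        best <- 1L
        for (k in seq_along(seqs)[-1L])
          if (path_precedes(seqs[[k]], seqs[[best]])) best <- k
        keep <- best
      }
      for (k in keep)
        rows[[length(rows) + 1L]] <- data.frame(
          source = s, target = t, total_beta = total[k],
          n_hops = length(seqs[[k]]) - 1L,
          node_sequence = paste(seqs[[k]], collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), target = character(0),
               total_beta = numeric(0), n_hops = integer(0),
               node_sequence = character(0), stringsAsFactors = FALSE)
  if (length(unreachable))
    message(sprintf("seed_pair_paths: %d seed pair(s) are unreachable",
                    length(unreachable)))
  attr(out, "unmapped_seeds") <- unmapped
  attr(out, "unreachable_pairs") <- unreachable
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# total edge weight along a node sequence
path_length <- function(graph, node_sequence) {
  if (length(node_sequence) < 2L) return(0)
  ids <- igraph::get_edge_ids(graph,
                              rbind(node_sequence[-length(node_sequence)],
                                    node_sequence[-1L]))
  sum(igraph::E(graph)$weight[ids])
}

#' Collect path genes (interior nodes) from seed-pair paths
#'
#' Interior nodes of the shortest paths, minus the seeds themselves, are
#' the new disease-gene candidates under guilt-by-association. Each gene
#' carries the seed pairs whose paths contain it.
#'
#' @param paths data.frame from [seed_pair_paths()].
#' @param seeds seed ids to exclude.
#' @param roles optional named role vector (or annotation data.frame) for
#'   role counts.
#' @return Object of class `path_gene_set`: data.frame `genes` (gene_id,
#'   role, n_pairs, pairs) and `role_counts`.
#' @export
extract_path_genes <- function(paths, seeds, roles = NULL) {
  if (is.data.frame(roles))
    roles <- stats::setNames(roles$role, roles$feature_id)
  found <- list()
  for (i in seq_len(nrow(paths))) {
    nodes <- strsplit(paths$node_sequence[i], ",", fixed = TRUE)[[1L]]
    interior <- setdiff(nodes[-c(1L, length(nodes))], seeds)
    pair <- paste(paths$source[i], paths$target[i], sep = "|")
    for (g in interior) found[[g]] <- c(found[[g]], pair)
  }
  ids <- sort(names(found))
  genes <- data.frame(
    gene_id = ids,
    role = if (is.null(roles)) rep(NA_character_, length(ids)) else unname(roles[ids]),
    n_pairs = vapply(found[ids], function(p) length(unique(p)), integer(1)),
    pairs = vapply(found[ids], function(p) paste(unique(p), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  role_counts <- if (is.null(roles)) NULL else
    table(factor(genes$role, levels = c("TF", "miRNA", "gene")))
  structure(list(genes = genes, role_counts = role_counts),
            class = "path_gene_set")
}

#' @export
print.path_gene_set <- function(x, ...) {
  cat(sprintf("path_gene_set: %d candidate genes on seed-pair shortest paths\n",
              nrow(x$genes)))
  if (!is.null(x$role_counts))
    cat("  roles:", paste(sprintf("%s=%d", names(x$role_counts), x$role_counts),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Export the union sub-network of all seed-pair paths
#'
#' @param paths data.frame from [seed_pair_paths()].
#' @param seeds seed ids, used to annotate node types.
#' @return list: `nodes` (id, type = seed/candidate), `edges` (from, to),
#'   each edge appearing once regardless of how many paths share it.
#' @export
export_subnetwork <- function(paths, seeds) {
  efrom <- character(0); eto <- character(0)
  for (i in seq_len(nrow(paths))) {
    nodes <- strsplit(paths$node_sequence[i], ",", fixed = TRUE)[[1L]]
    if (length(nodes) < 2L) next
    a <- nodes[-length(nodes)]; b <- nodes[-1L]
    efrom <- c(efrom, pmin(a, b)); eto <- c(eto, pmax(a, b))
  }
  keep <- !duplicated(paste(efrom, eto, sep = "\r"))
  edges <- data.frame(from = efrom[keep], to = eto[keep],
                      stringsAsFactors = FALSE)
  ids <- unique(c(edges$from, edges$to))
  nodes <- data.frame(id = ids,
                      type = ifelse(ids %in% seeds, "seed", "candidate"),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
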