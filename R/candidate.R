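#' Load candidate regulation edge lists
#'
#' Reads 2-column TSV files (regulator, target; header row required), one
#' provenance tag per file, attaches regulator roles from the feature
#' annotation and drops
#' edges whose endpoints are not annotated (counted and reported via a
#' message). Edges are restricted to the three modelled categories:
#' TF->gene, TF->miRNA and miRNA->gene. Regulation of a TF by a miRNA is
#' kept as miRNA->gene (TFs are protein-coding); miRNA->miRNA edges and
#' self-loops are rejected as out of model.
#'
#' @param paths character vector of edge-list file paths.
#' @param provenance character vector parallel to `paths`, each
#'   `"predicted"` or `"validated"`.
#' @param annotation feature annotation data.frame (`feature_id`, `role`).
#' @return data.frame with columns `regulator`, `target`, `category`,
#'   `provenance`; attribute `n_dropped` counts discarded rows.
#' @export
load_candidate_edges <- function(paths, provenance, annotation) {
  stopifnot(length(paths) == length(provenance),
            all(provenance %in% c("predicted", "validated")))
  out <- list()
  n_dropped <- 0L
  for (i in seq_along(paths)) {
    lines <- readLines(paths[i], encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) <= 1L) {
      warning(sprintf("%s: no edges found", paths[i]), call. = FALSE)
      next
    }
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 2L)
    if (length(bad))
      stop(sprintf("%s: line %d: expected 2 tab-separated columns",
                   paths[i], bad[1L] + 1L), call. = FALSE)
    df <- data.frame(regulator = vapply(fields, `[[`, "", 1L),
                     target = vapply(fields, `[[`, "", 2L),
                     provenance = provenance[i], stringsAsFactors = FALSE)
    role <- stats::setNames(annotation$role, annotation$feature_id)
    keep <- df$regulator %in% annotation$feature_id &
      df$target %in% annotation$feature_id &
      role[df$regulator] %in% c("TF", "miRNA") &
      df$regulator != df$target &
      !(role[df$regulator] == "miRNA" & role[df$target] == "miRNA")
    n_dropped <- n_dropped + sum(!keep)
    df <- df[keep, , drop = FALSE]
    if (nrow(df)) {
      tgt_role <- role[df$target]
      df$category <- ifelse(role[df$regulator] == "miRNA", "miRNA->gene",
                            ifelse(tgt_role == "miRNA", "TF->miRNA", "TF->gene"))
      out[[length(out) + 1L]] <- df[, c("regulator", "target", "category", "provenance")]
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(regulator = character(0), target = character(0),
               category = character(0), provenance = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (n_dropped > 0L)
    message(sprintf("load_candidate_edges: dropped %d edge(s) with unknown or invalid endpoints",
                    n_dropped))
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Merge candidate edge lists into one candidate network
#'
#' Unions edges over (regulator, target); the provenance of a duplicated
#' edge is the union of its sources, so an edge listed both as predicted
#' and validated ends up with both flags. Merging is idempotent and
#' independent of input order.
#'
#' @param ... edge data.frames as returned by [load_candidate_edges()], or
#'   a single list of them.
#' @return list of class `candidate_network`: `edges` (regulator, target,
#'   category, predicted, validated) and `counts` (edges per category and
#'   validated total).
#' @export
merge_candidate_edges <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is.data.frame(parts[[1L]]))
    parts <- parts[[1L]]
  all <- do.call(rbind, lapply(parts, function(df) {
    if (!is.null(df$provenance)) return(df)
    df$provenance <- ifelse(df$validated, "validated", "predicted")
    df[, c("regulator", "target", "category", "provenance")]
  }))
  key <- paste(all$regulator, all$target, sep = "\r")
  first <- !duplicated(key)
  edges <- all[first, c("regulator", "target", "category")]
  prov <- split(all$provenance, factor(key, levels = key[first]))
  edges$predicted <- vapply(prov, function(p) "predicted" %in% p, logical(1))
  edges$validated <- vapply(prov, function(p) "validated" %in% p, logical(1))
  o <- order(edges$regulator, edges$target)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  counts <- c(table(factor(edges$category,
                           levels = c("TF->gene", "TF->miRNA", "miRNA->gene"))),
              validated = sum(edges$validated))
  structure(list(edges = edges, counts = counts), class = "candidate_network")
}

#' @export
print.candidate_network <- function(x, ...) {
  cat(sprintf("candidate_network: %d edges\n", nrow(x$edges)))
  for (nm in names(x$counts)) cat(sprintf("  %-12s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
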