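#' Construct an expression matrix object
#'
#' An `expr_matrix` is a numeric features x samples matrix of microarray
#' intensities together with the scale it lives on (`"raw"` linear
#' intensities or `"log2"` transformed values). Feature and sample
#' identifiers are carried as dimnames and must be unique.
#'
#' @param values numeric matrix, rows = features, columns = samples, with
#'   complete dimnames.
#' @param scale `"raw"` or `"log2"`.
#' @return An object of class `expr_matrix` (a matrix with a `scale`
#'   attribute).
#' @export
expression_matrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  fid <- rownames(values)
  sid <- colnames(values)
  # R normalizes zero-length dimnames to NULL, so empty margins are exempt
  if ((is.null(fid) && nrow(values) > 0) || (is.null(sid) && ncol(values) > 0))
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(fid))
    stop("duplicate feature ids: ", paste(unique(fid[duplicated(fid)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite; missing values are not supported",
         call. = FALSE)
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' Scale of an expression matrix
#' @param m an `expr_matrix`.
#' @return `"raw"` or `"log2"`.
#' @export
expr_scale <- function(m) attr(m, "scale")

#' Read an expression matrix from TSV
#'
#' Expected layout: tab-separated, UTF-8, '.' decimal; first column feature
#' ids, header row sample ids.
#'
#' @param path file path.
#' @param scale_hint declared scale of the stored values, `"raw"` or
#'   `"log2"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale_hint = c("raw", "log2")) {
  scale_hint <- match.arg(scale_hint)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L)
    stop(sprintf("%s: need a header line and at least one feature row", path),
         call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop(sprintf("%s: line 1: malformed header (need >= 2 tab-separated fields)", path),
         call. = FALSE)
  sample_ids <- header[-1L]
  ncol_expect <- length(header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids))
  feature_ids <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != ncol_expect)
      stop(sprintf("%s: line %d: expected %d fields, found %d",
                   path, i + 1L, ncol_expect, length(f)), call. = FALSE)
    feature_ids[i] <- f[[1L]]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v))
      stop(sprintf("%s: line %d: non-numeric expression value", path, i + 1L),
           call. = FALSE)
    vals[i, ] <- v
  }
  if (anyDuplicated(feature_ids)) {
    dup <- feature_ids[duplicated(feature_ids)][1L]
    line <- which(feature_ids == dup)[2L] + 1L
    stop(sprintf("%s: line %d: duplicate feature id '%s'", path, line, dup),
         call. = FALSE)
  }
  dimnames(vals) <- list(feature_ids, sample_ids)
  expression_matrix(vals, scale = scale_hint)
}

#' Write an expression matrix to TSV
#' @param m an `expr_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata (sample_id, class_label)
#' @param path 2-column TSV with header.
#' @return data.frame with columns `sample_id`, `class_label`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) != 2L)
    stop(sprintf("%s: sample metadata must have exactly 2 columns", path), call. = FALSE)
  names(df) <- c("sample_id", "class_label")
  if (anyDuplicated(df$sample_id))
    stop(sprintf("%s: duplicate sample ids in metadata", path), call. = FALSE)
  df
}

#' Read feature annotation (feature_id, role)
#'
#' Roles partition features into `TF`, `miRNA` and (non-TF protein-coding)
#' `gene`; they are exhaustive and mutually exclusive per feature.
#'
#' @param path 2-column TSV with header.
#' @return data.frame with columns `feature_id`, `role`.
#' @export
read_feature_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) != 2L)
    stop(sprintf("%s: feature annotation must have exactly 2 columns", path), call. = FALSE)
  names(df) <- c("feature_id", "role")
  bad <- setdiff(unique(df$role), c("TF", "miRNA", "gene"))
  if (length(bad))
    stop(sprintf("%s: unknown feature role(s): %s", path, paste(bad, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(df$feature_id))
    stop(sprintf("%s: duplicate feature ids in annotation", path), call. = FALSE)
  df
}

#' Write sample metadata / feature annotation TSVs
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Log2-transform raw intensities
#'
#' @param m an `expr_matrix` on the raw scale.
#' @param offset non-negative pseudo-count added before taking logs.
#' @return An `expr_matrix` on the log2 scale.
#' @export
log2_transform <- function(m, offset = 0) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "raw")
    stop("matrix is already on the log2 scale", call. = FALSE)
  if (offset < 0) stop("`offset` must be >= 0", call. = FALSE)
  if (any(unclass(m) + offset <= 0))
    stop("non-positive value encountered; increase `offset`", call. = FALSE)
  expression_matrix(log2(unclass(m) + offset), scale = "log2")
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto a common distribution: values are ranked
#' within each column and replaced by the mean, across columns, of the
#' column-sorted values at that rank. Tied values within a column receive
#' the mean of the reference values at the ranks the tie occupies, so the
#' result does not depend on how the sort breaks ties.
#'
#' @param m an `expr_matrix` with at least two samples.
#' @return A quantile-normalized `expr_matrix` on the same scale.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- unclass(m)
  if (ncol(v) < 2L)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  ref <- rowMeans(apply(v, 2L, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    # ave() pools the reference values over each tied group
    out[, j] <- stats::ave(assigned, match(col, col), FUN = mean)
  }
  expression_matrix(out, scale = expr_scale(m))
}
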