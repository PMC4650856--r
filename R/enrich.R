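#' Build a 2x2 enrichment contingency table
#'
#' Rows: candidate set vs rest of the background; columns: differentially
#' expressed vs not. Two background conventions are supported: `"disjoint"`
#' removes the candidate set from the background row (standard enrichment
#' practice) and `"overlapping"` keeps the full background as printed in
#' typical overlap tables; both are reported by [enrichment_report()].
#'
#' @param candidates character vector, must be a subset of `background`.
#' @param de character vector of differentially expressed ids.
#' @param background character vector, the tested universe.
#' @param convention `"disjoint"` or `"overlapping"`.
#' @return named integer vector `c(a, b, c, d)`: candidate DE, candidate
#'   non-DE, background DE, background non-DE.
#' @export
make_contingency <- function(candidates, de, background,
                             convention = c("disjoint", "overlapping")) {
  convention <- match.arg(convention)
  candidates <- unique(candidates); de <- unique(de)
  background <- unique(background)
  if (length(setdiff(candidates, background)))
    stop("candidate set is not a subset of the background", call. = FALSE)
  rest <- if (convention == "disjoint") setdiff(background, candidates)
          else background
  c(a = length(intersect(candidates, de)),
    b = length(setdiff(candidates, de)),
    c = length(intersect(rest, de)),
    d = length(setdiff(rest, de)))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric p-value with fixed margins; the two-sided p sums
#' the probabilities of all tables at most as likely as the observed one.
#' Degenerate margins (an empty row or column) give `p = 1` by convention.
#'
#' @param tab numeric vector `c(a, b, c, d)` or a 2x2 matrix.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return list with `p_value` and `odds_ratio` (conditional MLE).
#' @export
fisher_enrichment <- function(tab, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  m <- if (is.matrix(tab)) tab else matrix(as.numeric(tab), nrow = 2, byrow = TRUE)
  if (any(m < 0) || any(m != round(m)))
    stop("table entries must be non-negative integers", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_))
  ft <- stats::fisher.test(m, alternative = alternative)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Enrichment report under both background conventions
#'
#' @inheritParams make_contingency
#' @param alternative passed to [fisher_enrichment()].
#' @return data.frame with one row per convention: the table entries,
#'   odds ratio and p-value.
#' @export
enrichment_report <- function(candidates, de, background,
                              alternative = "two.sided") {
  rows <- lapply(c("disjoint", "overlapping"), function(conv) {
    tab <- make_contingency(candidates, de, background, convention = conv)
    fe <- fisher_enrichment(tab, alternative = alternative)
    data.frame(convention = conv, a = tab[["a"]], b = tab[["b"]],
               c = tab[["c"]], d = tab[["d"]],
               odds_ratio = fe$odds_ratio, p_value = fe$p_value,
               alternative = alternative, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
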