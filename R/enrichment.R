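# Over-representation analysis of prioritized gene lists against gene-set
# collections: upper-tail hypergeometric test per set, Benjamini-Hochberg
# control across the collection, significance at FDR < 0.1.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, preserving input
#' order. Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted vector, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis against a gene-set collection
#'
#' For each set: `k = |query intersect set intersect background|` and
#' `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)` with `N` the background
#' size, `K` the in-background set size and `n` the in-background query
#' size. BH adjustment is applied across all sets in the collection;
#' significance at `fdr < fdr_max`. The query is intersected with the
#' background first.
#'
#' @param query Character vector of genes of interest.
#' @param collections Named list of gene-id vectors (one collection).
#' @param background Character vector of background genes (defaults to the
#'   union of all sets and the query).
#' @param fdr_max FDR significance threshold (default 0.1).
#' @return `data.frame(set_id, k, K, n, N, p_hyper, fdr, significant)`,
#'   ordered as the collection.
#' @export
ora <- function(query, collections, background = NULL, fdr_max = 0.1) {
  if (!length(collections)) stop("collections must be nonempty")
  if (is.null(background)) {
    background <- unique(c(unlist(collections), query))
  }
  background <- unique(background)
  if (length(background) < length(unique(query))) {
    stop("background smaller than query")
  }
  query <- unique(intersect(query, background))
  N <- length(background)
  n <- length(query)
  res <- lapply(names(collections), function(sid) {
    set <- unique(intersect(collections[[sid]], background))
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = sid, k = k, K = K, n = n, N = N, p_hyper = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p_hyper)
  out$significant <- out$fdr < fdr_max
  out
}

#' Read / write gene-set collections in GMT format
#'
#' GMT is line-oriented: set id, description, then member genes, all
#' tab-separated.
#'
#' @param path File path.
#' @param sets Named list of gene-id vectors.
#' @param descriptions Optional per-set description strings.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
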