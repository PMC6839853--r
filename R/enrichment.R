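# Hypergeometric over-representation testing with Benjamini-Hochberg
# false discovery rates.

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes in a query of size `n` from a background
#' of `N` genes of which `K` carry the annotation. Computed through the
#' numerically stable distribution-function routine (log-space tail).
#'
#' @param k overlap count.
#' @param K annotated genes in the background.
#' @param n query size.
#' @param N background size.
#' @return p-value in (0, 1\].
#' @export
hypergeometric_pvalue <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > K || K > N || k > n || n > N)
    stop("inconsistent hypergeometric counts", call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (Benjamini-Yekutieli available for
#' dependence-robust control). Adjusted values are order-invariant,
#' never below the raw p, and capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted values in the input order.
#' @export
bh_adjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}

#' Hypergeometric gene-set over-representation test
#'
#' Tests each annotation term for over-representation in a query gene
#' list against a background universe. Query genes outside the background
#' are dropped (with a message); term sets are intersected with the
#' background; terms with zero overlap are excluded from testing and from
#' the FDR family.
#'
#' @param query character vector of query genes.
#' @param annotation_sets named list of term gene sets.
#' @param background character vector: the gene universe.
#' @param fdr_cutoff significance threshold on the adjusted value
#'   (default 0.01).
#' @param method FDR flavor passed to [bh_adjust()].
#' @return list with `records` (data.frame `term`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, sorted by fdr then p) and `significant` (the
#'   subset at `fdr < fdr_cutoff`).
#' @export
enrich <- function(query, annotation_sets, background, fdr_cutoff = 0.01,
                   method = "BH") {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0L)
    message(length(outside), " query genes outside the background dropped")
  query <- intersect(query, background)
  n <- length(query)
  N <- length(background)
  empty <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0),
                      p_value = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(annotation_sets) == 0L || n == 0L)
    return(list(records = empty, significant = empty))
  sets <- lapply(annotation_sets, intersect, background)
  K <- vapply(sets, length, 0L)
  k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  keep <- k >= 1L
  if (!any(keep)) return(list(records = empty, significant = empty))
  terms <- names(sets)[keep]
  k <- k[keep]; K <- K[keep]
  p <- mapply(hypergeometric_pvalue, k = k, K = K,
              MoreArgs = list(n = n, N = N))
  rec <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                    p_value = unname(p), fdr = bh_adjust(unname(p), method),
                    stringsAsFactors = FALSE, row.names = NULL)
  rec <- rec[order(rec$fdr, rec$p_value, rec$term), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec,
       significant = rec[rec$fdr < fdr_cutoff, , drop = FALSE])
}
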