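# Tissue-specificity filter: keep interactome edges whose partners are
# co-expressed (Pearson rho above threshold) across the disease (case)
# samples of at least one expression dataset.

#' Pearson correlation of two expression profiles
#'
#' Standard product-moment correlation; requires equal length >= 3 and
#' nonzero variance in both vectors (returns NA with a warning message
#' otherwise, so callers can skip the pair for that dataset).
#'
#' @param x,y numeric vectors.
#' @return correlation in \[-1, 1\], or NA when undefined.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired samples", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Co-expression support of interactome edges
#'
#' For every edge and every dataset in which both partners are measured,
#' computes the Pearson correlation of the partners' log2 expression
#' across CASE samples only (controls never enter), using one designated
#' normalization variant per dataset. An edge's support is the number of
#' datasets with rho strictly greater than `rho_threshold`; edges with
#' support at least `min_support` are retained. Edges whose partners are
#' never jointly measured are dropped and counted.
#'
#' @param interactome data.frame with `a`, `b` edge columns.
#' @param datasets list as from [generate_expression_datasets()].
#' @param rho_threshold correlation cut-off (strict inequality).
#' @param min_support minimum number of supporting datasets.
#' @param variant which normalization variant to correlate (default
#'   `"B"`, the log2-scale one).
#' @return list with `edges` (retained rows plus `support`), `support`
#'   (per-edge data.frame with one `rho_<dataset>` column per dataset and
#'   the support count, all assessed edges), and `n_unmeasured` (edges
#'   never jointly measured).
#' @export
filter_coexpressed <- function(interactome, datasets, rho_threshold = 0.7,
                               min_support = 1L, variant = "B") {
  stopifnot(nrow(interactome) >= 0L)
  n_edges <- nrow(interactome)
  rho_mat <- matrix(NA_real_, n_edges, length(datasets),
                    dimnames = list(NULL, vapply(datasets, `[[`, "", "id")))
  for (j in seq_along(datasets)) {
    ds <- datasets[[j]][[variant]]
    lg <- log2_matrix(ds)[, case_samples(ds), drop = FALSE]
    ia <- match(interactome$a, rownames(lg))
    ib <- match(interactome$b, rownames(lg))
    ok <- !is.na(ia) & !is.na(ib)
    if (!any(ok)) next
    va <- lg[ia[ok], , drop = FALSE]
    vb <- lg[ib[ok], , drop = FALSE]
    # row-wise Pearson across case samples
    va_c <- va - rowMeans(va)
    vb_c <- vb - rowMeans(vb)
    num <- rowSums(va_c * vb_c)
    den <- sqrt(rowSums(va_c^2) * rowSums(vb_c^2))
    r <- ifelse(den > 0, num / den, NA_real_)
    rho_mat[ok, j] <- r
  }
  support <- rowSums(rho_mat > rho_threshold, na.rm = TRUE)
  measured_any <- rowSums(!is.na(rho_mat)) > 0L
  sup_df <- data.frame(a = interactome$a, b = interactome$b,
                       rho_mat, support = support,
                       stringsAsFactors = FALSE, row.names = NULL)
  names(sup_df)[2L + seq_along(datasets)] <- paste0("rho_", colnames(rho_mat))
  keep <- measured_any & support >= min_support
  edges <- data.frame(a = interactome$a[keep], b = interactome$b[keep],
                      support = support[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(edges = edges, support = sup_df,
       n_unmeasured = sum(!measured_any))
}

#' Histogram of edge support levels
#'
#' Tallies retained edges by the number of datasets supporting them.
#'
#' @param supports integer vector of per-edge support counts (only
#'   supported edges, i.e. values >= 1, are tallied).
#' @return named integer vector (support level -> edge count); the sum
#'   equals the number of supported edges.
#' @export
support_histogram <- function(supports) {
  supports <- supports[supports >= 1L]
  if (length(supports) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(supports)
  stats::setNames(as.integer(tab), names(tab))
}
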