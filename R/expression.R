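#' Construct an expression dataset object
#'
#' A gene-by-sample intensity matrix plus case/control labels and a
#' normalization-variant tag. Intensities must be strictly positive on the
#' linear scale; log2-scale matrices are unconstrained.
#'
#' @param id dataset name.
#' @param matrix numeric matrix, genes in rows (rownames required),
#'   samples in columns (colnames required).
#' @param groups named character vector mapping each sample to `"case"` or
#'   `"control"`.
#' @param variant normalization-variant tag (e.g. `"A"`, `"B"`).
#' @param scale `"linear"` or `"log2"`.
#' @return a `mitonet_expr` object.
#' @export
new_expression_dataset <- function(id, matrix, groups,
                                   variant = "A", scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  if (anyNA(rownames(matrix)) || any(rownames(matrix) == ""))
    stop("missing gene symbols in expression matrix", call. = FALSE)
  if (!all(colnames(matrix) %in% names(groups)))
    stop("every sample column needs a group label", call. = FALSE)
  groups <- groups[colnames(matrix)]
  if (!all(groups %in% c("case", "control")))
    stop("groups must be 'case' or 'control'", call. = FALSE)
  if (any(table(factor(groups, c("case", "control"))) < 2L))
    stop("need at least 2 samples per group", call. = FALSE)
  if (scale == "linear" && any(matrix <= 0))
    stop("linear-scale intensities must be strictly positive", call. = FALSE)
  structure(list(id = id, matrix = matrix, groups = groups,
                 variant = variant, scale = scale),
            class = "mitonet_expr")
}

#' @export
print.mitonet_expr <- function(x, ...) {
  cat(sprintf("<mitonet_expr> %s variant %s (%s scale): %d genes x %d samples (%d case / %d control)\n",
              x$id, x$variant, x$scale, nrow(x$matrix), ncol(x$matrix),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Expression matrix on the log2 scale
#'
#' @param ds a `mitonet_expr` object.
#' @return matrix of log2 intensities.
#' @export
log2_matrix <- function(ds) {
  if (ds$scale == "log2") ds$matrix else log2(ds$matrix)
}

#' Expression matrix on the linear scale
#'
#' @param ds a `mitonet_expr` object.
#' @return matrix of linear intensities.
#' @export
linear_matrix <- function(ds) {
  if (ds$scale == "linear") ds$matrix else 2^ds$matrix
}

case_samples <- function(ds) names(ds$groups)[ds$groups == "case"]
control_samples <- function(ds) names(ds$groups)[ds$groups == "control"]

#' Collapse a probe-level matrix to gene level
#'
#' Microarray platforms measure several probes per gene; downstream
#' analysis needs one row per gene. The default policy keeps, per gene,
#' the probe with the highest mean intensity across samples;
#' `"any-probe"` keeps the first probe in row order. Probes without a
#' mapping are dropped (count reported via a message).
#'
#' @param probe_matrix numeric matrix, probes in rows.
#' @param probe_to_gene named character vector: probe id -> gene symbol.
#' @param policy `"max-mean"` (default) or `"any-probe"`.
#' @return gene-level matrix with gene rownames.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene,
                            policy = c("max-mean", "any-probe")) {
  policy <- match.arg(policy)
  probes <- rownames(probe_matrix)
  if (is.null(probes)) stop("probe matrix needs probe rownames", call. = FALSE)
  mapped <- probes %in% names(probe_to_gene)
  if (any(!mapped))
    message(sum(!mapped), " unmapped probes dropped")
  probe_matrix <- probe_matrix[mapped, , drop = FALSE]
  gene <- unname(probe_to_gene[rownames(probe_matrix)])
  score <- switch(policy,
                  "max-mean" = rowMeans(probe_matrix),
                  "any-probe" = -seq_len(nrow(probe_matrix)))
  ord <- order(gene, -score)
  keep <- ord[!duplicated(gene[ord])]
  out <- probe_matrix[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out[order(rownames(out)), , drop = FALSE]
}
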