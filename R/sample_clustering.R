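# Therapy-effect robustness check: hierarchically cluster samples on a
# selected gene panel, flag case samples that fall in the control-majority
# cluster, remove them, and re-run the consensus differential-expression
# analysis.

#' Hierarchically cluster samples on a gene panel
#'
#' Restricts the expression matrix to the panel genes, z-scores each gene
#' across samples (so the result is invariant to per-gene affine
#' rescaling), computes Euclidean distances between samples and cuts an
#' agglomerative tree (average linkage by default) at two clusters.
#'
#' @param matrix gene-by-sample numeric matrix (log2 scale recommended).
#' @param gene_panel character vector of panel genes; genes absent from
#'   the matrix are skipped with a message.
#' @param linkage agglomeration method for [stats::hclust()].
#' @param dist_method distance for [stats::dist()].
#' @return a `mitonet_clustering` list: `assignment` (named integer,
#'   sample -> cluster in {1, 2}), `tree` (the hclust object),
#'   `panel_used`, `degenerate` (TRUE when all pairwise distances are
#'   zero, making the 2-cut arbitrary).
#' @export
cluster_samples <- function(matrix, gene_panel,
                            linkage = "average", dist_method = "euclidean") {
  present <- intersect(gene_panel, rownames(matrix))
  missing <- setdiff(gene_panel, rownames(matrix))
  if (length(missing) > 0L)
    message(length(missing), " panel genes absent from the matrix skipped")
  if (length(present) < 2L)
    stop("fewer than 2 panel genes present in the matrix", call. = FALSE)
  if (ncol(matrix) < 4L) stop("need at least 4 samples", call. = FALSE)
  x <- matrix[present, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  z <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  d <- stats::dist(t(z), method = dist_method)
  tree <- stats::hclust(d, method = linkage)
  assignment <- stats::cutree(tree, k = 2L)
  structure(list(assignment = assignment, tree = tree, panel_used = present,
                 degenerate = all(d == 0)),
            class = "mitonet_clustering")
}

#' Flag case samples clustering with controls
#'
#' Identifies the control-majority cluster (larger fraction of that
#' cluster's samples are controls) and lists the case samples inside it.
#' When the two clusters have equal control fractions no removal is
#' proposed and both compositions are reported.
#'
#' @param clustering a [cluster_samples()] result.
#' @param groups named character vector (sample -> `"case"`/`"control"`).
#' @return list: `flagged` (case samples in the control-majority
#'   cluster), `composition` (per-cluster case/control counts), `tie`
#'   (TRUE when control fractions are equal).
#' @export
flag_misclustered_cases <- function(clustering, groups) {
  assignment <- clustering$assignment
  groups <- groups[names(assignment)]
  comp <- table(cluster = assignment, group = factor(groups, c("case", "control")))
  ctrl_frac <- comp[, "control"] / rowSums(comp)
  if (length(unique(ctrl_frac)) == 1L) {
    return(list(flagged = character(0), composition = comp, tie = TRUE))
  }
  ctrl_cluster <- as.integer(names(which.max(ctrl_frac)))
  flagged <- names(assignment)[assignment == ctrl_cluster & groups == "case"]
  list(flagged = flagged, composition = comp, tie = FALSE)
}

drop_samples <- function(ds, drop) {
  keep <- setdiff(colnames(ds$matrix), drop)
  new_expression_dataset(ds$id, ds$matrix[, keep, drop = FALSE],
                         ds$groups[keep], variant = ds$variant, scale = ds$scale)
}

#' Re-run consensus DE after removing flagged case samples
#'
#' Removes the flagged samples from both normalization variants of every
#' dataset, re-runs the full per-dataset calling and cross-dataset
#' consensus, and reports genes gained and lost relative to the original
#' consensus set. A dataset left with fewer than 2 case samples is
#' excluded with a warning.
#'
#' @param datasets list as from [generate_expression_datasets()].
#' @param flagged_samples character vector of case sample names to drop.
#' @param original_consensus the consensus data.frame from a prior
#'   [consensus_de()] run.
#' @param ... passed to [consensus_de()].
#' @return list: `consensus` (the re-run consensus table), `retained`,
#'   `lost`, `gained` (gene character vectors), `excluded_datasets`.
#' @export
rerun_after_removal <- function(datasets, flagged_samples, original_consensus,
                                ...) {
  for (d in datasets) {
    if (any(flagged_samples %in% names(d$A$groups)[d$A$groups == "control"]))
      stop("flagged samples must be case samples", call. = FALSE)
  }
  excluded <- character(0)
  pruned <- list()
  for (d in datasets) {
    n_cases_left <- sum(d$A$groups == "case" &
                          !names(d$A$groups) %in% flagged_samples)
    if (n_cases_left < 2L) {
      warning("dataset ", d$id, " left with fewer than 2 cases; excluded",
              call. = FALSE)
      excluded <- c(excluded, d$id)
      next
    }
    pruned[[d$id]] <- list(id = d$id, measured = d$measured,
                           A = drop_samples(d$A, flagged_samples),
                           B = drop_samples(d$B, flagged_samples))
  }
  if (length(pruned) == 0L) stop("no datasets left after removal", call. = FALSE)
  res <- consensus_de(pruned, ...)
  before <- original_consensus$gene
  after <- res$consensus$gene
  list(consensus = res$consensus,
       retained = intersect(before, after),
       lost = setdiff(before, after),
       gained = setdiff(after, before),
       excluded_datasets = excluded)
}
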