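# Multi-source interaction integration: per-source reliability filters,
# canonical merge with provenance, and organelle-catalog restriction.

#' Median confidence-score cutoff for a scored source
#'
#' The reliability rule for score-bearing sources keeps interactions whose
#' confidence exceeds the median of that source's full score distribution
#' (midpoint of the two central order statistics for even n).
#'
#' @param records data.frame with a `score` column.
#' @return the median score.
#' @export
score_cutoff <- function(records) {
  if (nrow(records) == 0L) stop("empty source table", call. = FALSE)
  if (is.null(records$score) || anyNA(records$score))
    stop("source table has missing scores", call. = FALSE)
  stats::median(records$score)
}

#' Filter a scored source at its median
#'
#' Keeps records with score strictly greater than [score_cutoff()]. With
#' continuous scores this retains at most half the table; heavy ties can
#' drop more (all records are dropped if every score is equal).
#'
#' @param records data.frame with a `score` column.
#' @return the retained records.
#' @export
filter_scored <- function(records) {
  if (is.null(records$score))
    stop("source table has no score column", call. = FALSE)
  bad <- which(is.na(records$score))
  if (length(bad) > 0L)
    stop("missing scores in rows: ", paste(bad, collapse = ", "), call. = FALSE)
  records[records$score > score_cutoff(records), , drop = FALSE]
}

#' Filter a source by curation-quality flag
#'
#' Keeps records whose `core_flag` is TRUE (the source's high-quality
#' curation subset).
#'
#' @param records data.frame with a logical `core_flag` column.
#' @return the retained records.
#' @export
filter_quality <- function(records) {
  if (is.null(records$core_flag))
    stop("source table has no core_flag column", call. = FALSE)
  records[records$core_flag %in% TRUE, , drop = FALSE]
}

#' Filter a source by publication evidence
#'
#' Keeps records supported by at least `min_pubs` publications.
#'
#' @param records data.frame with a `pubs` column.
#' @param min_pubs minimum publication count (default 2).
#' @return the retained records.
#' @export
filter_evidence <- function(records, min_pubs = 2L) {
  if (is.null(records$pubs))
    stop("source table has no pubs column", call. = FALSE)
  if (any(records$pubs < 0, na.rm = TRUE))
    stop("negative publication counts", call. = FALSE)
  records[!is.na(records$pubs) & records$pubs >= min_pubs, , drop = FALSE]
}

#' Apply the declared reliability filter for one source
#'
#' @param records one source table.
#' @param filter one of `"score_median"`, `"core_flag"`, `"min_pubs"`,
#'   `"none"`.
#' @param min_pubs publication threshold for `"min_pubs"`.
#' @return the retained records.
#' @export
filter_source <- function(records,
                          filter = c("score_median", "core_flag", "min_pubs", "none"),
                          min_pubs = 2L) {
  filter <- match.arg(filter)
  switch(filter,
         score_median = filter_scored(records),
         core_flag = filter_quality(records),
         min_pubs = filter_evidence(records, min_pubs),
         none = records)
}

canonical_pairs <- function(a, b) {
  data.frame(a = pmin(a, b), b = pmax(a, b), stringsAsFactors = FALSE)
}

#' Merge filtered source tables into one deduplicated interactome
#'
#' Canonicalizes pair order (unordered identity), drops self-loops, unions
#' edges across sources and records, per edge, the contributing sources.
#'
#' @param tables named list of already source-filtered data.frames with
#'   `protein_a`, `protein_b` columns (and optionally `source`).
#' @return a `mitonet_interactome`: data.frame `a`, `b`, `sources`
#'   (comma-separated provenance), `n_sources`; attribute `counts` with
#'   staged totals.
#' @export
merge_sources <- function(tables) {
  stopifnot(is.list(tables))
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("source", seq_along(tables))
  rows <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    if (nrow(tab) == 0L)
      return(data.frame(a = character(0), b = character(0), src = character(0),
                        stringsAsFactors = FALSE))
    if (any(is.na(tab$protein_a) | is.na(tab$protein_b) |
            tab$protein_a == "" | tab$protein_b == ""))
      stop("malformed gene symbols in source ", nm, call. = FALSE)
    cp <- canonical_pairs(tab$protein_a, tab$protein_b)
    src <- if (!is.null(tab$source)) tab$source else nm
    data.frame(a = cp$a, b = cp$b, src = src, stringsAsFactors = FALSE)
  })
  all_rows <- do.call(rbind, rows)
  n_in <- nrow(all_rows)
  self <- all_rows$a == all_rows$b
  if (any(self)) message(sum(self), " self-interactions dropped at merge")
  all_rows <- all_rows[!self, , drop = FALSE]

  key <- paste(all_rows$a, all_rows$b, sep = "\r")
  prov <- lapply(split(all_rows$src, key), function(s) sort(unique(s)))
  keys <- sort(names(prov))
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  edges <- data.frame(a = ab[, 1], b = ab[, 2],
                      sources = vapply(prov[keys], paste, "", collapse = ","),
                      n_sources = vapply(prov[keys], length, 0L),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(edges,
            counts = c(records_in = n_in, self_loops = sum(self),
                       edges = nrow(edges)),
            class = c("mitonet_interactome", "data.frame"))
}

#' Restrict an interactome to an organelle gene catalog
#'
#' Keeps only edges with BOTH endpoints in the catalog and reports how
#' many distinct catalog genes the surviving edges represent.
#'
#' @param interactome a [merge_sources()] result (or data.frame with
#'   `a`, `b`).
#' @param catalog character vector of catalog gene symbols.
#' @return the restricted interactome; attribute `coverage` holds
#'   `genes_represented` and `catalog_fraction`.
#' @export
restrict_to_catalog <- function(interactome, catalog) {
  if (length(catalog) == 0L) stop("empty catalog", call. = FALSE)
  keep <- interactome$a %in% catalog & interactome$b %in% catalog
  out <- interactome[keep, , drop = FALSE]
  rownames(out) <- NULL
  genes <- unique(c(out$a, out$b))
  structure(out,
            counts = c(attr(interactome, "counts"),
                       catalog_edges = nrow(out)),
            coverage = list(genes_represented = length(genes),
                            catalog_fraction = length(genes) / length(catalog)),
            class = c("mitonet_interactome", "data.frame"))
}

#' Run the full integration stage
#'
#' Applies each source's declared reliability filter, merges, and
#' restricts to the catalog.
#'
#' @param sources named list of source tables.
#' @param catalog catalog gene symbols.
#' @param filters named character vector (source -> filter rule); by
#'   default inferred from each table's evidence column.
#' @param min_pubs publication threshold for publication-evidence sources.
#' @return catalog-restricted `mitonet_interactome` with staged counts in
#'   attribute `counts` (`records_in`, `filtered_records`, `edges`,
#'   `catalog_edges`).
#' @export
integrate_sources <- function(sources, catalog, filters = NULL, min_pubs = 2L) {
  if (is.null(filters)) {
    filters <- vapply(sources, function(tab) {
      if (!is.null(tab$score)) "score_median"
      else if (!is.null(tab$core_flag)) "core_flag"
      else if (!is.null(tab$pubs)) "min_pubs"
      else "none"
    }, "")
  }
  filtered <- lapply(names(sources), function(nm) {
    filter_source(sources[[nm]], filters[[nm]], min_pubs = min_pubs)
  })
  names(filtered) <- names(sources)
  n_filtered <- sum(vapply(filtered, nrow, 0L))
  merged <- merge_sources(filtered)
  restricted <- restrict_to_catalog(merged, catalog)
  cnt <- attr(restricted, "counts")
  attr(restricted, "counts") <- c(
    records_in = sum(vapply(sources, nrow, 0L)),
    filtered_records = n_filtered,
    cnt[setdiff(names(cnt), "records_in")]
  )
  restricted
}
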