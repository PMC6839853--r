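# Plain-text readers and writers for every exchange format the pipeline
# touches: expression matrices + sample metadata (TSV), interaction source
# tables (TSV + JSON source config), gene catalogs (one symbol per line),
# annotation sets (GMT), ground truth (JSON), and graphs (GraphML via
# igraph, XGMML written/parsed here since no installed package handles it).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression dataset as TSV (matrix + sample metadata)
#'
#' The matrix file has genes in rows with a leading `gene` column; the
#' metadata file has columns `sample` and `group` (`case`/`control`).
#'
#' @param ds a `mitonet_expr` object.
#' @param matrix_path,meta_path output files.
#' @export
write_expression_tsv <- function(ds, matrix_path, meta_path = NULL) {
  df <- data.frame(gene = rownames(ds$matrix), ds$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  if (!is.null(meta_path)) {
    write_tsv(data.frame(sample = names(ds$groups), group = unname(ds$groups),
                         stringsAsFactors = FALSE), meta_path)
  }
  invisible(matrix_path)
}

#' Read an expression dataset from TSV files
#'
#' @param matrix_path TSV with leading `gene` column.
#' @param meta_path TSV with `sample`, `group` columns.
#' @param id dataset name.
#' @param variant,scale tags for [new_expression_dataset()].
#' @return a `mitonet_expr` object.
#' @export
read_expression_tsv <- function(matrix_path, meta_path, id,
                                variant = "A", scale = "linear") {
  df <- read_tsv(matrix_path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  meta <- read_tsv(meta_path)
  groups <- stats::setNames(meta$group, meta$sample)
  new_expression_dataset(id, mat, groups, variant = variant, scale = scale)
}

#' Write / read a gene catalog (one symbol per line)
#' @param catalog character vector of gene symbols.
#' @param path file path.
#' @export
write_catalog <- function(catalog, path) {
  writeLines(catalog, path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) readLines(path)

#' Write gene sets in GMT format
#'
#' One line per term: term, description, then member genes,
#' tab-separated. Reading is delegated to [fgsea::gmtPathways()] via
#' [read_gmt()].
#'
#' @param sets named list of gene character vectors.
#' @param path output file.
#' @param descriptions optional character vector of term descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write the ground truth of a simulation as JSON
#' @param truth a `mitonet_truth` object.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    catalog = truth$catalog,
    edges = truth$edges,
    communities = as.list(truth$communities),
    planted_up = truth$planted_up,
    planted_down = truth$planted_down
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write all inputs of a simulated study to a directory
#'
#' Lays out the directory exactly as [run_pipeline()] expects: catalog,
#' per-source TSV tables plus a `sources.json` declaring each source's
#' reliability filter, per-dataset matrix/metadata TSVs for both variants
#' plus `datasets.json`, annotations GMT, and the ground truth JSON.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_catalog(sim$truth$catalog, file.path(dir, "catalog.txt"))

  src_dir <- file.path(dir, "sources")
  dir.create(src_dir, showWarnings = FALSE)
  schema <- source_schema(sim$config$n_sources)
  src_cfg <- lapply(names(sim$sources), function(nm) {
    path <- file.path("sources", paste0(nm, ".tsv"))
    write_tsv(sim$sources[[nm]], file.path(dir, path))
    filt <- switch(schema[[nm]], score = "score_median",
                   core_flag = "core_flag", pubs = "min_pubs")
    list(name = nm, path = path, filter = filt)
  })
  jsonlite::write_json(src_cfg, file.path(dir, "sources.json"),
                       auto_unbox = TRUE)

  ds_dir <- file.path(dir, "datasets")
  dir.create(ds_dir, showWarnings = FALSE)
  ds_cfg <- lapply(sim$datasets, function(d) {
    pa <- file.path("datasets", paste0(d$id, "_A.tsv"))
    pb <- file.path("datasets", paste0(d$id, "_B.tsv"))
    pm <- file.path("datasets", paste0(d$id, "_samples.tsv"))
    write_expression_tsv(d$A, file.path(dir, pa), file.path(dir, pm))
    write_expression_tsv(d$B, file.path(dir, pb))
    list(id = d$id, matrix_a = pa, matrix_b = pb, metadata = pm,
         scale_a = d$A$scale, scale_b = d$B$scale)
  })
  jsonlite::write_json(unname(ds_cfg), file.path(dir, "datasets.json"),
                       auto_unbox = TRUE)

  write_gmt(sim$annotations, file.path(dir, "annotations.gmt"))
  write_truth_json(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read the datasets of a written simulation directory
#' @param dir directory written by [write_simulation()].
#' @return list of datasets in the [generate_expression_datasets()] shape.
#' @export
read_datasets_config <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "datasets.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out <- lapply(cfg, function(d) {
    a <- read_expression_tsv(file.path(dir, d$matrix_a),
                             file.path(dir, d$metadata), d$id,
                             variant = "A", scale = d$scale_a)
    b <- read_expression_tsv(file.path(dir, d$matrix_b),
                             file.path(dir, d$metadata), d$id,
                             variant = "B", scale = d$scale_b)
    list(id = d$id, measured = rownames(a$matrix), A = a, B = b)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Read the source tables of a written simulation directory
#' @param dir directory holding `sources.json`.
#' @return list with `tables` (named list of data.frames) and `filters`
#'   (named character vector).
#' @export
read_sources_config <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "sources.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  tables <- list()
  filters <- character(0)
  for (s in cfg) {
    tables[[s$name]] <- read_tsv(file.path(dir, s$path))
    filters[[s$name]] <- s$filter
  }
  list(tables = tables, filters = filters)
}

# ---- graph export -----------------------------------------------------

#' Export a network for visualization
#'
#' GraphML export is delegated to [igraph::write_graph()]; XGMML (the
#' Cytoscape exchange dialect) is serialized here with xml2. Both carry
#' the per-node `regulation` attribute and round-trip through
#' [import_graph()].
#'
#' @param network igraph object with a `regulation` node attribute.
#' @param path output file.
#' @param format `"graphml"` or `"xgmml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("graphml", "xgmml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  nm <- esc(igraph::V(network)$name)
  reg <- igraph::V(network)$regulation
  if (is.null(reg)) reg <- rep("NotDE", length(nm))
  node_lines <- sprintf(
    "  <node id=\"%d\" label=\"%s\">\n    <att name=\"regulation\" type=\"string\" value=\"%s\"/>\n  </node>",
    seq_along(nm), nm, esc(reg))
  el <- igraph::as_edgelist(network, names = FALSE)
  edge_lines <- character(0)
  if (nrow(el) > 0L) {
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    edge_lines <- sprintf("  <edge source=\"%d\" target=\"%d\"/>", el[, 1], el[, 2])
  }
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graph label=\"mitonet\" directed=\"0\" xmlns=\"http://www.cs.rpi.edu/XGMML\">",
    node_lines, edge_lines, "</graph>"), path)
  invisible(path)
}

#' Import a network written by [export_graph()]
#'
#' @param path input file.
#' @param format `"graphml"` or `"xgmml"`.
#' @return igraph object with the `regulation` node attribute.
#' @export
import_graph <- function(path, format = c("graphml", "xgmml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "x")
  nodes <- xml2::xml_find_all(doc, ".//x:node", ns)
  ids <- xml2::xml_attr(nodes, "id")
  labels <- xml2::xml_attr(nodes, "label")
  reg <- vapply(nodes, function(nd) {
    att <- xml2::xml_find_first(nd, ".//x:att[@name='regulation']", ns)
    if (inherits(att, "xml_missing")) "NotDE" else xml2::xml_attr(att, "value")
  }, "")
  edges <- xml2::xml_find_all(doc, ".//x:edge", ns)
  src <- match(xml2::xml_attr(edges, "source"), ids)
  tgt <- match(xml2::xml_attr(edges, "target"), ids)
  g <- igraph::graph_from_data_frame(
    data.frame(from = labels[src], to = labels[tgt], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = labels, regulation = reg,
                          stringsAsFactors = FALSE))
  g
}
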