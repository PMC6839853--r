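# Configuration-driven orchestration of the full analysis: integration ->
# differential expression -> co-expression filter -> topology ->
# enrichment -> sample clustering, with a stage manifest and summary JSON.

#' Pipeline configuration
#'
#' Collects input paths (a directory in the [write_simulation()] layout)
#' and every analysis threshold. Thresholds default to the study's
#' cut-offs: per-variant fold change > 1.5 and p < 0.05, co-expression
#' rho > 0.7 in at least one dataset, publication evidence >= 2,
#' enrichment FDR < 0.01, key hubs with >= 27 neighbours and >= 7 DEG
#' neighbours, clustering panel from genes selected in >= 3 datasets.
#'
#' @param input_dir directory with `catalog.txt`, `sources.json`,
#'   `datasets.json`, `annotations.gmt`.
#' @param out_dir output directory for stage tables and the summary.
#' @param min_pubs publication-evidence threshold.
#' @param fc_threshold,p_threshold differential-expression cut-offs.
#' @param rho_threshold,min_support co-expression filter cut-offs.
#' @param coexpr_variant normalization variant used for co-expression.
#' @param fdr_cutoff enrichment significance threshold.
#' @param enrich_min_datasets consensus genes selected in at least this
#'   many datasets form the enrichment query.
#' @param key_hub_min_neighbours,key_hub_min_degs key-hub thresholds.
#' @param cluster_min_datasets panel threshold for sample clustering.
#' @param var_equal pooled-variance t-test if TRUE, Welch otherwise.
#' @param powerlaw_method `"loglog_ls"` or `"mle"`.
#' @param linkage clustering linkage.
#' @param seed integer seed recorded in the manifest.
#' @return a `mitonet_pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            min_pubs = 2L,
                            fc_threshold = 1.5, p_threshold = 0.05,
                            rho_threshold = 0.7, min_support = 1L,
                            coexpr_variant = "B",
                            fdr_cutoff = 0.01,
                            enrich_min_datasets = 2L,
                            key_hub_min_neighbours = 27L, key_hub_min_degs = 7L,
                            cluster_min_datasets = 3L,
                            var_equal = TRUE,
                            powerlaw_method = "loglog_ls",
                            linkage = "average",
                            seed = 1L) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir,
              min_pubs = as.integer(min_pubs),
              fc_threshold = fc_threshold, p_threshold = p_threshold,
              rho_threshold = rho_threshold, min_support = as.integer(min_support),
              coexpr_variant = coexpr_variant,
              fdr_cutoff = fdr_cutoff,
              enrich_min_datasets = as.integer(enrich_min_datasets),
              key_hub_min_neighbours = as.integer(key_hub_min_neighbours),
              key_hub_min_degs = as.integer(key_hub_min_degs),
              cluster_min_datasets = as.integer(cluster_min_datasets),
              var_equal = isTRUE(var_equal),
              powerlaw_method = powerlaw_method,
              linkage = linkage,
              seed = as.integer(seed))
  class(cfg) <- "mitonet_pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema and range checks with no side effects. Violations are returned,
#' not thrown; an empty character vector means the configuration is
#' valid. Advisory notes (e.g. a publication threshold below 2) are
#' returned separately.
#'
#' @param config a [pipeline_config()] object.
#' @return list with `violations` and `warnings` character vectors;
#'   `ok` is TRUE when there are no violations.
#' @export
validate_config <- function(config) {
  v <- character(0)
  w <- character(0)
  for (f in c("catalog.txt", "sources.json", "datasets.json")) {
    if (!file.exists(file.path(config$input_dir, f)))
      v <- c(v, paste0("missing input file: ", f))
  }
  if (config$fc_threshold <= 1) v <- c(v, "fc_threshold must be > 1")
  if (config$p_threshold <= 0 || config$p_threshold >= 1)
    v <- c(v, "p_threshold must be in (0, 1)")
  if (config$rho_threshold < -1 || config$rho_threshold > 1)
    v <- c(v, "rho_threshold must be in [-1, 1]")
  if (config$min_support < 1) v <- c(v, "min_support must be >= 1")
  if (config$fdr_cutoff <= 0 || config$fdr_cutoff > 1)
    v <- c(v, "fdr_cutoff must be in (0, 1]")
  if (config$key_hub_min_neighbours < 1 || config$key_hub_min_degs < 0)
    v <- c(v, "key-hub thresholds must be positive")
  if (config$min_pubs < 2)
    w <- c(w, "min_pubs below 2 weakens the publication-evidence filter")
  list(ok = length(v) == 0L, violations = v, warnings = w)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the inputs under `config$input_dir`, writing
#' each stage's table under `config$out_dir` and a `summary.json`
#' manifest with input hashes, parameters and the counts at every filter
#' stage (source records in, reliability-filtered records, merged edges,
#' catalog edges, co-expressed edges, network nodes). Aborts naming the
#' failing stage; outputs of completed stages are retained.
#'
#' @param config a valid [pipeline_config()].
#' @return the summary list, invisibly; stage objects in attribute
#'   `results`.
#' @export
run_pipeline <- function(config) {
  val <- validate_config(config)
  if (!val$ok)
    stop("invalid pipeline configuration:\n  ",
         paste(val$violations, collapse = "\n  "), call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  res <- list()
  tryCatch({
    stage <- "ppi_integration"
    catalog <- read_catalog(file.path(config$input_dir, "catalog.txt"))
    src <- read_sources_config(config$input_dir)
    interactome <- integrate_sources(src$tables, catalog,
                                     filters = src$filters,
                                     min_pubs = config$min_pubs)
    write_tsv(as.data.frame(interactome),
              file.path(config$out_dir, "interactome.tsv"))
    res$interactome <- interactome

    stage <- "differential_expression"
    datasets <- read_datasets_config(config$input_dir)
    de <- consensus_de(datasets, fc_threshold = config$fc_threshold,
                       p_threshold = config$p_threshold,
                       var_equal = config$var_equal)
    write_tsv(de$consensus, file.path(config$out_dir, "consensus_degs.tsv"))
    res$de <- de

    stage <- "coexpression_network"
    coexpr <- filter_coexpressed(interactome, datasets,
                                 rho_threshold = config$rho_threshold,
                                 min_support = config$min_support,
                                 variant = config$coexpr_variant)
    write_tsv(coexpr$support, file.path(config$out_dir, "edge_support.tsv"))
    hist <- support_histogram(coexpr$edges$support)
    jsonlite::write_json(as.list(hist),
                         file.path(config$out_dir, "support_histogram.json"),
                         auto_unbox = TRUE)
    res$coexpr <- coexpr

    stage <- "network_topology"
    network <- build_graph(coexpr$edges, de$consensus)
    hubs <- rank_hubs(network, top_n = igraph::vcount(network))
    write_tsv(utils::head(hubs, 50L), file.path(config$out_dir, "hub_table.tsv"))
    key_hubs <- select_key_hubs(hubs,
                                min_neighbours = config$key_hub_min_neighbours,
                                min_degs = config$key_hub_min_degs)
    write_tsv(key_hubs, file.path(config$out_dir, "key_hubs.tsv"))
    export_graph(network, file.path(config$out_dir, "network.graphml"),
                 format = "graphml")
    export_graph(network, file.path(config$out_dir, "network.xgmml"),
                 format = "xgmml")
    topo <- topology_summary(network)
    res$network <- network
    res$hubs <- hubs
    res$key_hubs <- key_hubs
    res$topology <- topo

    stage <- "enrichment"
    annotations <- if (file.exists(file.path(config$input_dir, "annotations.gmt")))
      read_gmt(file.path(config$input_dir, "annotations.gmt")) else list()
    query <- de$consensus$gene[de$consensus$n_selected >= config$enrich_min_datasets]
    background <- igraph::V(network)$name
    enr <- if (length(annotations) > 0L && length(query) > 0L &&
               length(background) > 0L) {
      enrich(query, annotations, background, fdr_cutoff = config$fdr_cutoff)
    } else {
      list(records = data.frame(), significant = data.frame())
    }
    write_tsv(enr$records, file.path(config$out_dir, "enrichment.tsv"))
    res$enrichment <- enr

    stage <- "sample_clustering"
    panel <- de$consensus$gene[de$consensus$n_selected >= config$cluster_min_datasets]
    cluster_out <- list()
    flagged_all <- character(0)
    if (length(panel) >= 2L) {
      for (d in datasets) {
        ds <- d[[config$coexpr_variant]]
        cl <- tryCatch(cluster_samples(log2_matrix(ds), panel,
                                       linkage = config$linkage),
                       error = function(e) NULL)
        if (is.null(cl)) next
        fl <- flag_misclustered_cases(cl, ds$groups)
        cluster_out[[d$id]] <- list(assignment = cl$assignment, flagged = fl$flagged)
        flagged_all <- c(flagged_all, fl$flagged)
      }
      assign_df <- do.call(rbind, lapply(names(cluster_out), function(id) {
        a <- cluster_out[[id]]$assignment
        data.frame(dataset = id, sample = names(a), cluster = unname(a),
                   flagged = names(a) %in% cluster_out[[id]]$flagged,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(assign_df))
        write_tsv(assign_df, file.path(config$out_dir, "cluster_assignments.tsv"))
      rerun <- if (length(flagged_all) > 0L) {
        rerun_after_removal(datasets, flagged_all, de$consensus,
                            fc_threshold = config$fc_threshold,
                            p_threshold = config$p_threshold,
                            var_equal = config$var_equal)
      } else {
        list(retained = de$consensus$gene, lost = character(0),
             gained = character(0), excluded_datasets = character(0))
      }
      jsonlite::write_json(list(flagged = flagged_all,
                                retained = rerun$retained,
                                lost = rerun$lost, gained = rerun$gained,
                                excluded_datasets = rerun$excluded_datasets),
                           file.path(config$out_dir, "rerun_report.json"))
      res$clustering <- cluster_out
      res$rerun <- rerun
    }

    stage <- "summary"
    inputs <- list.files(config$input_dir, recursive = TRUE, full.names = TRUE)
    summary <- list(
      parameters = unclass(config),
      input_hashes = as.list(tools::md5sum(inputs)),
      counts = c(as.list(attr(interactome, "counts")),
                 list(coexpressed_edges = nrow(coexpr$edges),
                      unmeasured_edges = coexpr$n_unmeasured,
                      network_nodes = topo$nodes,
                      network_edges = topo$edges,
                      consensus_degs = nrow(de$consensus),
                      significant_terms = nrow(enr$significant))),
      topology = topo,
      support_histogram = as.list(hist)
    )
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(summary, "results") <- res
    invisible(summary)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' One-command synthetic demonstration run
#'
#' Simulates a study with [simulate_study()], writes its inputs, and runs
#' the full pipeline on them.
#'
#' @param seed integer seed for the generator.
#' @param dir working directory (inputs under `dir`/inputs, outputs under
#'   `dir`/run).
#' @param config optional [generation_config()] (its seed is overridden
#'   by `seed`).
#' @return the pipeline summary, invisibly.
#' @export
run_demo <- function(seed = 1L, dir = tempfile("mitonet_demo"),
                     config = NULL) {
  if (is.null(config)) config <- generation_config(seed = seed)
  else { config$seed <- as.integer(seed); validate_generation_config(config) }
  sim <- simulate_study(config)
  input_dir <- file.path(dir, "inputs")
  write_simulation(sim, input_dir)
  pcfg <- pipeline_config(input_dir, file.path(dir, "run"), seed = seed)
  run_pipeline(pcfg)
}
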