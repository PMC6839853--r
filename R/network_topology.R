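# Undirected tissue-network topology: degree distribution, power-law
# exponent, hub ranking, DEG-neighbour profiles, key-hub selection,
# subnetwork extraction and graph export.

#' Build the tissue PPI network
#'
#' Simple undirected igraph over the co-expression-supported edges, with
#' per-edge support counts and a per-node `regulation` attribute taken
#' from the consensus differential-expression classes (`NotDE` for genes
#' without a consensus call).
#'
#' @param edges data.frame with `a`, `b` and optionally `support`.
#' @param consensus data.frame with `gene` and `class` columns (may be
#'   empty).
#' @return an igraph object.
#' @export
build_graph <- function(edges, consensus = NULL) {
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  el <- data.frame(from = edges$a, to = edges$b, stringsAsFactors = FALSE)
  if (!is.null(edges$support)) el$support <- edges$support
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  reg <- rep("NotDE", igraph::vcount(g))
  if (!is.null(consensus) && nrow(consensus) > 0L) {
    idx <- match(igraph::V(g)$name, consensus$gene)
    reg[!is.na(idx)] <- consensus$class[idx[!is.na(idx)]]
  }
  igraph::V(g)$regulation <- reg
  g
}

#' Empirical degree distribution
#'
#' Fraction of nodes at each observed degree.
#'
#' @param network an igraph object with at least one node.
#' @return data.frame with `k` (degree) and `p` (fraction of nodes);
#'   fractions sum to 1.
#' @export
degree_distribution_table <- function(network) {
  if (igraph::vcount(network) == 0L) stop("empty network", call. = FALSE)
  deg <- igraph::degree(network)
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)),
             p = as.numeric(tab) / length(deg),
             row.names = NULL)
}

#' Fit a power law to the degree distribution
#'
#' Default method: ordinary least squares of log10 P(k) on log10 k over
#' the degrees with nonzero frequency (k >= 1), matching the
#' straight-line-on-log-log-axes presentation of scale-free degree
#' plots; alpha is minus the slope. The `"mle"` alternative delegates to
#' the discrete maximum-likelihood fit of [igraph::fit_power_law()].
#'
#' @param distribution a [degree_distribution_table()] result (for
#'   `"loglog_ls"`) or an igraph object (accepted by both methods).
#' @param method `"loglog_ls"` (default) or `"mle"`.
#' @return a `mitonet_powerlaw` list: `alpha`, `fit_method`, `k_range`,
#'   `goodness` (R^2 for least squares, KS statistic for MLE).
#' @export
fit_power_law_degree <- function(distribution, method = c("loglog_ls", "mle")) {
  method <- match.arg(method)
  if (igraph::is_igraph(distribution)) {
    if (method == "mle") {
      deg <- igraph::degree(distribution)
      deg <- deg[deg > 0]
      fit <- igraph::fit_power_law(deg)
      return(structure(list(alpha = fit$alpha, fit_method = "mle",
                            k_range = range(deg), goodness = fit$KS.stat),
                       class = "mitonet_powerlaw"))
    }
    distribution <- degree_distribution_table(distribution)
  } else if (method == "mle") {
    stop("the MLE method needs the graph itself, not a tabulated distribution",
         call. = FALSE)
  }
  d <- distribution[distribution$p > 0 & distribution$k > 0, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least 3 distinct degrees with nonzero frequency", call. = FALSE)
  fit <- stats::lm(log10(p) ~ log10(k), data = d)
  # a noiseless power law fits exactly; summary.lm warns about that
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(alpha = -unname(stats::coef(fit)[2L]),
                 fit_method = "loglog_ls",
                 k_range = range(d$k),
                 goodness = r2),
            class = "mitonet_powerlaw")
}

#' @export
print.mitonet_powerlaw <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): alpha = %.3f over k in [%d, %d], goodness = %.3f\n",
              x$fit_method, x$alpha, x$k_range[1], x$k_range[2], x$goodness))
  invisible(x)
}

#' DEG profile of a protein's immediate neighbours
#'
#' Degree plus tallies of consensus classes among the node's immediate
#' neighbours.
#'
#' @param network igraph with a `regulation` node attribute.
#' @param protein node name.
#' @return one-row data.frame: `protein`, `n_neighbours`,
#'   `n_deg_neighbours`, `n_up`, `n_down`, `n_mixed`.
#' @export
neighbour_deg_profile <- function(network, protein) {
  if (!protein %in% igraph::V(network)$name)
    stop("unknown protein: ", protein, call. = FALSE)
  nb <- igraph::neighbors(network, protein)
  reg <- nb$regulation
  data.frame(protein = protein,
             n_neighbours = length(nb),
             n_deg_neighbours = sum(reg != "NotDE"),
             n_up = sum(reg == "Up"),
             n_down = sum(reg == "Down"),
             n_mixed = sum(reg == "Mixed"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank hubs by degree
#'
#' All nodes' neighbour-DEG profiles sorted by decreasing degree; ties
#' broken lexicographically by protein symbol.
#'
#' @param network igraph with `regulation` node attribute.
#' @param top_n number of rows to return (capped at the node count).
#' @return data.frame of [neighbour_deg_profile()] rows.
#' @export
rank_hubs <- function(network, top_n = 50L) {
  if (igraph::vcount(network) == 0L) stop("empty network", call. = FALSE)
  prof <- do.call(rbind, lapply(igraph::V(network)$name,
                                neighbour_deg_profile, network = network))
  prof <- prof[order(-prof$n_neighbours, prof$protein), , drop = FALSE]
  rownames(prof) <- NULL
  utils::head(prof, top_n)
}

#' Select key hubs
#'
#' Hubs with many neighbours AND many differentially expressed
#' neighbours (defaults: at least 27 neighbours, at least 7 DEGs among
#' them).
#'
#' @param records hub records from [rank_hubs()] (or all profiles).
#' @param min_neighbours,min_degs selection thresholds.
#' @return the selected rows.
#' @export
select_key_hubs <- function(records, min_neighbours = 27L, min_degs = 7L) {
  out <- records[records$n_neighbours >= min_neighbours &
                   records$n_deg_neighbours >= min_degs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a hub's subnetwork
#'
#' The induced subgraph on the hub and its immediate neighbours (the star
#' plus any edges among the neighbours), with node classes carried over.
#'
#' @param network igraph object.
#' @param hub node name.
#' @return igraph subgraph.
#' @export
extract_subnetwork <- function(network, hub) {
  if (!hub %in% igraph::V(network)$name)
    stop("unknown hub: ", hub, call. = FALSE)
  nodes <- c(hub, igraph::neighbors(network, hub)$name)
  igraph::induced_subgraph(network, unique(nodes))
}

#' Topology summary statistics
#'
#' Node and edge counts, `edges_per_node` (|E| / |N|) and `mean_degree`
#' (2|E| / |N|) — both reported because "each protein is connected to k
#' others" narratives sometimes quote the former — plus the power-law
#' exponent under the default least-squares fit.
#'
#' @param network igraph object.
#' @return named list.
#' @export
topology_summary <- function(network) {
  n <- igraph::vcount(network)
  e <- igraph::ecount(network)
  alpha <- tryCatch(fit_power_law_degree(network)$alpha, error = function(e) NA_real_)
  list(nodes = n, edges = e,
       edges_per_node = if (n > 0) e / n else NA_real_,
       mean_degree = if (n > 0) 2 * e / n else NA_real_,
       alpha_loglog_ls = alpha)
}
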