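# Seeded generator for synthetic study inputs with planted ground truth.
# Every generate_* operation re-seeds deterministically from config$seed
# (with a fixed per-stage offset), so each stage is reproducible on its own
# and the full simulation is byte-stable under a fixed config.

.seed_offsets <- c(truth = 0L, sources = 1L, expression = 2L, annotations = 3L)

gene_ids <- function(n) {
  sprintf("G%0*d", max(4L, nchar(as.character(n))), seq_len(n))
}

#' Generate the scale-free truth interaction network
#'
#' Grows an undirected simple graph over the organelle catalog genes by
#' preferential attachment: nodes arrive one at a time and each new node
#' attaches `scale_free_m` edges (fewer while the graph is smaller) to
#' distinct existing nodes, chosen with probability proportional to
#' current degree + 1. Genes are pre-assigned to co-expression communities
#' (round-robin, `community_size` genes each); with probability `p_intra` an
#' attachment is drawn from the new node's own community, which plants the
#' modular structure that the expression generator's latent factors follow.
#' The resulting degree distribution is heavy-tailed and the graph is
#' connected.
#'
#' Planted differentially expressed gene sets (up and down, disjoint) are
#' drawn uniformly from the catalog.
#'
#' @param config a [generation_config()] object.
#' @return a `mitonet_truth` list with elements `genes`, `catalog`,
#'   `edges` (data.frame `a`, `b`, canonical `a < b`), `communities`
#'   (named integer over catalog genes), `planted_up`, `planted_down`.
#' @export
generate_truth_network <- function(config) {
  validate_generation_config(config)
  set.seed(config$seed + .seed_offsets[["truth"]])
  genes <- gene_ids(config$n_genes)
  n <- config$n_catalog
  m <- config$scale_free_m
  catalog <- genes[seq_len(n)]

  n_comm <- max(1L, ceiling(n / config$community_size))
  comm <- ((seq_len(n) - 1L) %% n_comm) + 1L

  deg <- integer(n)
  ea <- integer(0)
  eb <- integer(0)
  for (i in 2:n) {
    mi <- min(m, i - 1L)
    pool <- seq_len(i - 1L)
    targets <- integer(0)
    for (t in seq_len(mi)) {
      avail <- setdiff(pool, targets)
      own <- avail[comm[avail] == comm[i]]
      use <- if (length(own) > 0L && stats::runif(1) < config$p_intra) own else avail
      pick <- if (length(use) == 1L) use else sample(use, 1L, prob = deg[use] + 1)
      targets <- c(targets, pick)
    }
    deg[targets] <- deg[targets] + 1L
    deg[i] <- deg[i] + mi
    ea <- c(ea, targets)
    eb <- c(eb, rep.int(i, mi))
  }
  edges <- data.frame(a = catalog[pmin(ea, eb)], b = catalog[pmax(ea, eb)],
                      stringsAsFactors = FALSE)

  n_up <- round(config$deg_fraction_up * n)
  n_down <- round(config$deg_fraction_down * n)
  planted <- sample(catalog, n_up + n_down)
  truth <- list(
    genes = genes,
    catalog = catalog,
    edges = edges,
    communities = stats::setNames(comm, catalog),
    planted_up = sort(planted[seq_len(n_up)]),
    planted_down = sort(planted[n_up + seq_len(n_down)]),
    config = config
  )
  class(truth) <- "mitonet_truth"
  truth
}

source_schema <- function(n_sources) {
  types <- character(n_sources)
  types[seq_len(min(4L, n_sources))] <- "score"
  if (n_sources >= 5L) types[5L] <- "core_flag"
  if (n_sources >= 6L) types[6:n_sources] <- "pubs"
  names(types) <- c(paste0("scoreDB", seq_len(min(4L, n_sources))),
                    if (n_sources >= 5L) "coreDB",
                    if (n_sources >= 6L) paste0("litDB", seq_len(n_sources - 5L)))[seq_len(n_sources)]
  types
}

#' Generate multi-source interaction tables
#'
#' Emits `n_sources` candidate-interaction tables mixing a sample of truth
#' edges with decoy pairs drawn from the whole gene universe (so some rows
#' fall outside the organelle catalog and exercise the catalog filter).
#' The first four sources carry confidence scores, with truth edges drawn
#' from a higher-mean distribution than decoys; the fifth carries a binary
#' curation-quality flag; the remaining sources carry publication counts.
#'
#' @param truth a [generate_truth_network()] result.
#' @param config the same [generation_config()].
#' @return named list of data.frames with columns `protein_a`, `protein_b`,
#'   one evidence column (`score`, `core_flag` or `pubs`) and `source`.
#' @export
generate_interaction_sources <- function(truth, config) {
  set.seed(config$seed + .seed_offsets[["sources"]])
  schema <- source_schema(config$n_sources)
  n_edges <- nrow(truth$edges)
  n_genes <- length(truth$genes)
  d <- config$decoy_edge_fraction

  draw_decoys <- function(n_decoy) {
    if (n_decoy == 0L) {
      return(data.frame(protein_a = character(0), protein_b = character(0),
                        stringsAsFactors = FALSE))
    }
    ia <- sample.int(n_genes, 2L * n_decoy, replace = TRUE)
    ib <- sample.int(n_genes, 2L * n_decoy, replace = TRUE)
    keep <- ia != ib
    a <- truth$genes[pmin(ia, ib)[keep]]
    b <- truth$genes[pmax(ia, ib)[keep]]
    key <- paste(a, b)
    truth_key <- paste(truth$edges$a, truth$edges$b)
    ok <- !duplicated(key) & !(key %in% truth_key)
    idx <- which(ok)[seq_len(min(n_decoy, sum(ok)))]
    data.frame(protein_a = a[idx], protein_b = b[idx], stringsAsFactors = FALSE)
  }

  out <- vector("list", config$n_sources)
  names(out) <- names(schema)
  for (s in seq_len(config$n_sources)) {
    n_truth_s <- round(0.6 * n_edges)
    idx <- sample.int(n_edges, n_truth_s)
    tr <- data.frame(protein_a = truth$edges$a[idx], protein_b = truth$edges$b[idx],
                     stringsAsFactors = FALSE)
    n_decoy <- if (d > 0) round(d / (1 - d) * n_truth_s) else 0L
    dc <- draw_decoys(n_decoy)
    tab <- rbind(tr, dc)
    is_truth <- rep(c(TRUE, FALSE), c(nrow(tr), nrow(dc)))
    type <- schema[[s]]
    if (type == "score") {
      tab$score <- pmin(pmax(stats::rnorm(nrow(tab),
                                          mean = ifelse(is_truth, 0.75, 0.45),
                                          sd = 0.12), 0.001), 0.999)
    } else if (type == "core_flag") {
      tab$core_flag <- stats::rbinom(nrow(tab), 1L,
                                     ifelse(is_truth, 0.8, 0.25)) == 1L
    } else {
      tab$pubs <- 1L + stats::rpois(nrow(tab), ifelse(is_truth, 2, 0.5))
    }
    tab$source <- names(schema)[s]
    out[[s]] <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(out[[s]]) <- NULL
  }
  out
}

# Variant B ("second normalization") constants: a strictly monotone affine
# map of the log2 signal plus independent noise. The noise_sd (log2 scale)
# reflects how much two normalization algorithms genuinely disagree on the
# same arrays; it is what gives the dual-normalization agreement rule its
# filtering power (a near-zero value would make variant B a copy of A and
# the agreement rule vacuous).
.variant_b <- list(slope = 0.95, intercept = 0.3, noise_sd = 0.1)

#' Generate case/control expression datasets in two normalization variants
#'
#' Simulates each dataset on the log2 scale: per-gene baselines are
#' N(7, 1); case samples of catalog genes load on one latent Gaussian
#' factor per planted community with weight `sqrt(edge_rho)`, so genes
#' sharing a community (hence most truth-edge partners) have Pearson
#' correlation `edge_rho` among cases, while controls and non-catalog
#' genes are independent noise. Planted DEGs are shifted by
#' `log2(effect_fold)` in cases (up or down). Each dataset measures a
#' `coverage_fraction` subset of the gene universe and is emitted in two
#' variants: variant A on the linear intensity scale (`2^log2signal`) and
#' variant B as a strictly monotone affine transform of the log2 signal
#' plus small noise, tagged log2 scale.
#'
#' @param truth a [generate_truth_network()] result.
#' @param config the same [generation_config()].
#' @return list of datasets; each has `id`, `measured` (gene character
#'   vector), and `A`/`B` expression objects (`mitonet_expr`: `id`,
#'   `variant`, `scale`, `matrix`, `groups`).
#' @export
generate_expression_datasets <- function(truth, config) {
  set.seed(config$seed + .seed_offsets[["expression"]])
  genes <- truth$genes
  n_genes <- length(genes)
  mu <- stats::setNames(stats::rnorm(n_genes, 7, 1), genes)
  delta <- stats::setNames(numeric(n_genes), genes)
  if (config$effect_fold > 1) {
    delta[truth$planted_up] <- log2(config$effect_fold)
    delta[truth$planted_down] <- -log2(config$effect_fold)
  }
  comm <- truth$communities
  n_comm <- max(comm)
  rho <- config$edge_rho

  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    id <- paste0("DS", d)
    nc <- config$cases_per_dataset[d]
    nk <- config$controls_per_dataset[d]
    measured <- sort(sample(genes, round(config$coverage_fraction[d] * n_genes)))
    nm <- length(measured)
    samples <- c(paste0(id, "_RA", sprintf("%02d", seq_len(nc))),
                 paste0(id, "_N", sprintf("%02d", seq_len(nk))))
    groups <- stats::setNames(rep(c("case", "control"), c(nc, nk)), samples)

    f <- matrix(stats::rnorm(n_comm * nc), n_comm, nc)
    z_case <- matrix(stats::rnorm(nm * nc), nm, nc)
    in_cat <- measured %in% names(comm)
    if (any(in_cat) && rho > 0) {
      ci <- comm[measured[in_cat]]
      z_case[in_cat, ] <- sqrt(rho) * f[ci, , drop = FALSE] +
        sqrt(1 - rho) * z_case[in_cat, , drop = FALSE]
    }
    l_case <- mu[measured] + delta[measured] + config$noise_sd * z_case
    l_ctrl <- mu[measured] + config$noise_sd * matrix(stats::rnorm(nm * nk), nm, nk)
    l <- cbind(l_case, l_ctrl)
    dimnames(l) <- list(measured, samples)

    a_mat <- 2^l
    b_mat <- .variant_b$slope * l + .variant_b$intercept +
      matrix(stats::rnorm(length(l), 0, .variant_b$noise_sd), nrow(l), ncol(l))
    dimnames(b_mat) <- dimnames(l)

    datasets[[d]] <- list(
      id = id,
      measured = measured,
      A = new_expression_dataset(id, a_mat, groups, variant = "A", scale = "linear"),
      B = new_expression_dataset(id, b_mat, groups, variant = "B", scale = "log2")
    )
  }
  names(datasets) <- vapply(datasets, `[[`, "", "id")
  datasets
}

#' Generate annotation term sets
#'
#' Builds `n_terms` gene sets over the catalog, each of size `term_size`.
#' When planted DEGs exist, the first three terms are constructed enriched:
#' 60% of their members are drawn from the planted DEG pool. All other
#' terms are uniform catalog samples.
#'
#' @param truth a [generate_truth_network()] result.
#' @param config the same [generation_config()].
#' @return named list of gene character vectors (GMT-writable).
#' @export
generate_annotations <- function(truth, config) {
  if (config$term_size > length(truth$catalog))
    stop("term_size must not exceed the catalog size", call. = FALSE)
  set.seed(config$seed + .seed_offsets[["annotations"]])
  if (config$n_terms == 0L) return(stats::setNames(list(), character(0)))
  planted <- c(truth$planted_up, truth$planted_down)
  n_enriched <- if (length(planted) > 0L) min(3L, config$n_terms) else 0L
  terms <- vector("list", config$n_terms)
  for (i in seq_len(config$n_terms)) {
    if (i <= n_enriched) {
      n_from_planted <- min(length(planted), round(0.6 * config$term_size))
      core <- sample(planted, n_from_planted)
      rest <- sample(setdiff(truth$catalog, core), config$term_size - n_from_planted)
      terms[[i]] <- sort(c(core, rest))
    } else {
      terms[[i]] <- sort(sample(truth$catalog, config$term_size))
    }
  }
  names(terms) <- sprintf("TERM%04d", seq_len(config$n_terms))
  terms
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper: truth network, interaction sources, expression
#' datasets and annotation sets, all from one config and seed.
#'
#' @param config a [generation_config()] object.
#' @return a `mitonet_simulation` list with elements `config`, `truth`,
#'   `sources`, `datasets`, `annotations`.
#' @export
simulate_study <- function(config = generation_config()) {
  truth <- generate_truth_network(config)
  sources <- generate_interaction_sources(truth, config)
  datasets <- generate_expression_datasets(truth, config)
  truth$measured <- lapply(datasets, `[[`, "measured")
  annotations <- generate_annotations(truth, config)
  truth$term_memberships <- annotations
  sim <- list(config = config, truth = truth, sources = sources,
              datasets = datasets, annotations = annotations)
  class(sim) <- "mitonet_simulation"
  sim
}
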