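#' Configuration for the synthetic study generator
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. Defaults emulate the study conditions the analysis assumes:
#' six case/control synovial expression datasets with unequal sample sizes,
#' an organelle catalog of 1158 genes inside a larger measured gene
#' universe, seven interaction sources with heterogeneous evidence types,
#' and a scale-free truth network with planted co-expression communities.
#'
#' @param n_genes total number of genes in the simulated universe.
#' @param n_catalog size of the organelle gene catalog (must be
#'   `<= n_genes`); catalog genes are the only possible truth-edge
#'   endpoints.
#' @param n_sources number of interaction source tables: the first four
#'   carry confidence scores, the fifth a binary curation-quality flag,
#'   the remainder publication counts.
#' @param scale_free_m edges attached per incoming node in the
#'   preferential-attachment truth network.
#' @param community_size target number of genes per planted co-expression
#'   community; large modules (default 150) leave room for hub degree
#'   heterogeneity to survive the co-expression filter.
#' @param p_intra probability that a new node attaches within its own
#'   planted community (when that community already has members); controls
#'   how well truth edges align with the co-expression communities.
#' @param decoy_edge_fraction fraction of each source table made of decoy
#'   (non-truth) pairs, in `[0, 1)`.
#' @param n_datasets number of expression datasets.
#' @param cases_per_dataset,controls_per_dataset integer vectors (recycled
#'   to `n_datasets`) of case and control sample counts.
#' @param coverage_fraction fraction of the gene universe measured by each
#'   dataset (recycled to `n_datasets`).
#' @param edge_rho target Pearson correlation, among case samples, for
#'   genes sharing a co-expression community (hence for most truth-edge
#'   partners).
#' @param deg_fraction_up,deg_fraction_down fractions of catalog genes
#'   planted as up-/down-regulated in cases.
#' @param effect_fold planted linear fold change (> 1 plants an effect;
#'   exactly 1 yields a null study).
#' @param noise_sd per-observation standard deviation on the log2 scale.
#' @param n_terms,term_size annotation set count and approximate size;
#'   a few terms are built enriched in planted DEGs.
#' @param seed integer seed; a fixed seed makes every generated object
#'   reproducible.
#'
#' @return a `mitonet_config` list.
#' @export
generation_config <- function(n_genes = 1500L,
                              n_catalog = 1158L,
                              n_sources = 7L,
                              scale_free_m = 6L,
                              community_size = 150L,
                              p_intra = 0.95,
                              decoy_edge_fraction = 0.5,
                              n_datasets = 6L,
                              cases_per_dataset = c(16L, 5L, 12L, 12L, 13L, 10L),
                              controls_per_dataset = c(7L, 9L, 9L, 4L, 10L, 10L),
                              coverage_fraction = c(0.95, 0.95, 0.6, 0.35, 0.6, 0.6),
                              edge_rho = 0.8,
                              deg_fraction_up = 0.07,
                              deg_fraction_down = 0.10,
                              effect_fold = 2.5,
                              noise_sd = 0.35,
                              n_terms = 50L,
                              term_size = 25L,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_catalog = as.integer(n_catalog),
    n_sources = as.integer(n_sources),
    scale_free_m = as.integer(scale_free_m),
    community_size = as.integer(community_size),
    p_intra = p_intra,
    decoy_edge_fraction = decoy_edge_fraction,
    n_datasets = as.integer(n_datasets),
    cases_per_dataset = as.integer(rep_len(cases_per_dataset, n_datasets)),
    controls_per_dataset = as.integer(rep_len(controls_per_dataset, n_datasets)),
    coverage_fraction = rep_len(coverage_fraction, n_datasets),
    edge_rho = edge_rho,
    deg_fraction_up = deg_fraction_up,
    deg_fraction_down = deg_fraction_down,
    effect_fold = effect_fold,
    noise_sd = noise_sd,
    n_terms = as.integer(n_terms),
    term_size = as.integer(term_size),
    seed = as.integer(seed)
  )
  class(cfg) <- "mitonet_config"
  validate_generation_config(cfg)
  cfg
}

validate_generation_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (cfg$n_catalog > cfg$n_genes)
    stop("n_catalog must not exceed n_genes", call. = FALSE)
  if (cfg$scale_free_m < 1L)
    stop("scale_free_m must be at least 1", call. = FALSE)
  if (cfg$community_size < 1L)
    stop("community_size must be positive", call. = FALSE)
  if (cfg$n_catalog < cfg$scale_free_m + 1L)
    stop("n_catalog must be at least scale_free_m + 1", call. = FALSE)
  fracs <- c(p_intra = cfg$p_intra,
             decoy_edge_fraction = cfg$decoy_edge_fraction,
             coverage = cfg$coverage_fraction,
             edge_rho = cfg$edge_rho,
             deg_fraction_up = cfg$deg_fraction_up,
             deg_fraction_down = cfg$deg_fraction_down)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("fractions out of [0, 1]: ", paste(names(fracs)[bad], collapse = ", "),
         call. = FALSE)
  if (cfg$decoy_edge_fraction >= 1)
    stop("decoy_edge_fraction must be < 1", call. = FALSE)
  if (cfg$deg_fraction_up + cfg$deg_fraction_down > 1)
    stop("planted DEG fractions sum to more than 1", call. = FALSE)
  if (cfg$effect_fold < 1)
    stop("effect_fold must be >= 1", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (any(cfg$cases_per_dataset < 3L))
    stop("cases_per_dataset must be at least 3 (correlation and t-test degenerate below)",
         call. = FALSE)
  if (any(cfg$controls_per_dataset < 2L))
    stop("controls_per_dataset must be at least 2", call. = FALSE)
  if (cfg$n_terms > 0L && cfg$term_size > cfg$n_catalog)
    stop("term_size must not exceed n_catalog", call. = FALSE)
  invisible(cfg)
}
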