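test_that("identical seed and config give identical outputs", {
  s1 <- simulate_study(tiny_config(seed = 5L))
  s2 <- simulate_study(tiny_config(seed = 5L))
  expect_identical(s1$truth$edges, s2$truth$edges)
  expect_identical(s1$truth$planted_up, s2$truth$planted_up)
  expect_identical(s1$sources, s2$sources)
  expect_identical(s1$datasets$DS1$A$matrix, s2$datasets$DS1$A$matrix)
  expect_identical(s1$annotations, s2$annotations)
  s3 <- simulate_study(tiny_config(seed = 6L))
  expect_false(identical(s1$truth$edges, s3$truth$edges))
})

test_that("preferential attachment with m = 1 grows a connected tree", {
  cfg <- tiny_config(n_genes = 5L, n_catalog = 5L, scale_free_m = 1L,
                     n_terms = 0L)
  tr <- generate_truth_network(cfg)
  expect_equal(nrow(tr$edges), 4L)
  g <- igraph::graph_from_data_frame(tr$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::ecount(g), 4)
})

test_that("invalid generator configurations are rejected", {
  expect_error(tiny_config(scale_free_m = 0L), "scale_free_m")
  expect_error(tiny_config(n_catalog = 300L), "n_catalog")
  expect_error(tiny_config(edge_rho = 1.5), "fractions")
  expect_error(tiny_config(effect_fold = 0.5), "effect_fold")
  expect_error(tiny_config(cases_per_dataset = 2L), "cases_per_dataset")
  expect_error(tiny_config(term_size = 121L), "term_size")
  expect_error(tiny_config(decoy_edge_fraction = 1), "decoy_edge_fraction")
})

test_that("truth networks are simple, catalog-only and degree-heterogeneous", {
  tr <- generate_truth_network(tiny_config(seed = 9L))
  expect_true(all(c(tr$edges$a, tr$edges$b) %in% tr$catalog))
  expect_true(all(tr$edges$a < tr$edges$b))            # canonical, no loops
  expect_false(any(duplicated(paste(tr$edges$a, tr$edges$b))))
  expect_length(intersect(tr$planted_up, tr$planted_down), 0)
  g <- igraph::graph_from_data_frame(tr$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("log-log degree slope is stable across seeds", {
  alphas <- vapply(1:20, function(s) {
    cfg <- generation_config(n_genes = 200L, n_catalog = 200L,
                             scale_free_m = 2L, n_datasets = 1L,
                             cases_per_dataset = 4L, controls_per_dataset = 3L,
                             coverage_fraction = 1, n_terms = 0L, seed = s)
    tr <- generate_truth_network(cfg)
    g <- igraph::graph_from_data_frame(tr$edges, directed = FALSE)
    fit_power_law_degree(g)$alpha
  }, 0)
  expect_true(all(abs(alphas - mean(alphas)) <= 0.5))
})

test_that("interaction sources carry the declared evidence columns", {
  sim <- simulate_study(tiny_config(seed = 3L))
  expect_length(sim$sources, 7L)
  expect_true(all(vapply(sim$sources[1:4], function(t) !is.null(t$score), NA)))
  expect_true(is.logical(sim$sources[[5]]$core_flag))
  expect_true(all(vapply(sim$sources[6:7], function(t) !is.null(t$pubs), NA)))
  # decoys reach outside the catalog so the catalog filter is exercised
  all_genes <- unlist(lapply(sim$sources, function(t) c(t$protein_a, t$protein_b)))
  expect_true(any(!all_genes %in% sim$truth$catalog))
})

test_that("zero decoy fraction yields pure truth-edge sources", {
  sim <- simulate_study(tiny_config(seed = 3L, decoy_edge_fraction = 0))
  truth_key <- paste(sim$truth$edges$a, sim$truth$edges$b)
  for (tab in sim$sources) {
    key <- paste(pmin(tab$protein_a, tab$protein_b),
                 pmax(tab$protein_a, tab$protein_b))
    expect_true(all(key %in% truth_key))
  }
})

test_that("the median score filter favours truth edges over decoys", {
  sim <- simulate_study(tiny_config(seed = 8L))
  tab <- sim$sources$scoreDB1
  truth_key <- paste(sim$truth$edges$a, sim$truth$edges$b)
  key <- paste(pmin(tab$protein_a, tab$protein_b),
               pmax(tab$protein_a, tab$protein_b))
  is_truth <- key %in% truth_key
  kept <- filter_scored(tab)
  kept_key <- paste(pmin(kept$protein_a, kept$protein_b),
                    pmax(kept$protein_a, kept$protein_b))
  truth_surv <- mean(key[is_truth] %in% kept_key)
  decoy_surv <- mean(key[!is_truth] %in% kept_key)
  expect_gt(truth_surv, decoy_surv)
})

test_that("full coverage measures every gene in every dataset", {
  sim <- simulate_study(tiny_config(seed = 2L, coverage_fraction = 1))
  for (d in sim$datasets) {
    expect_setequal(rownames(d$A$matrix), sim$truth$genes)
    expect_setequal(rownames(d$B$matrix), sim$truth$genes)
  }
})

test_that("case-sample correlation of truth-edge partners approaches edge_rho", {
  cfg <- generation_config(n_genes = 400L, n_catalog = 300L, scale_free_m = 3L,
                           community_size = 100L, n_datasets = 1L,
                           cases_per_dataset = 50L, controls_per_dataset = 10L,
                           coverage_fraction = 1, edge_rho = 0.9,
                           n_terms = 0L, seed = 17L)
  sim <- simulate_study(cfg)
  lg <- log2_matrix(sim$datasets$DS1$A)
  cs <- names(sim$datasets$DS1$A$groups)[sim$datasets$DS1$A$groups == "case"]
  rhos <- mapply(function(a, b) stats::cor(lg[a, cs], lg[b, cs]),
                 sim$truth$edges$a, sim$truth$edges$b)
  expect_gte(mean(rhos), 0.8)
  expect_lte(mean(rhos), 0.95)
})

test_that("a null study produces calibrated false-positive rates", {
  cfg <- generation_config(n_genes = 1200L, n_catalog = 150L,
                           scale_free_m = 3L, n_datasets = 1L,
                           cases_per_dataset = 10L, controls_per_dataset = 10L,
                           coverage_fraction = 1, effect_fold = 1,
                           edge_rho = 0, n_terms = 0L, seed = 23L)
  sim <- simulate_study(cfg)
  calls <- de_call_variant(sim$datasets$DS1$A)
  expect_lte(mean(calls$direction != "none"), 0.05)
  expect_gt(mean(calls$p_value < 0.05), 0.03)
  expect_lt(mean(calls$p_value < 0.05), 0.07)
})

test_that("annotation sets live in the catalog and mark planted enrichment", {
  sim <- simulate_study(tiny_config(seed = 4L))
  expect_length(sim$annotations, 12L)
  for (s in sim$annotations) expect_true(all(s %in% sim$truth$catalog))
  planted <- c(sim$truth$planted_up, sim$truth$planted_down)
  frac_planted <- vapply(sim$annotations,
                         function(s) mean(s %in% planted), 0)
  expect_gte(max(frac_planted), 0.5)
  empty <- generate_annotations(sim$truth, tiny_config(seed = 4L, n_terms = 0L))
  expect_length(empty, 0L)
})
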