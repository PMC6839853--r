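test_that("fold changes are linear-scale case/control mean ratios", {
  expect_equal(group_fold_change(c(4, 4), c(2, 2), "linear"), 2)
  expect_equal(group_fold_change(c(3, 3), c(3, 3), "linear"), 1)
  expect_equal(group_fold_change(c(2, 2), c(1, 1), "log2"), 2)  # 4/2
  expect_error(group_fold_change(numeric(0), 1, "linear"), "nonempty")
  expect_error(group_fold_change(c(1, 2), c(-1, 1), "linear"), "positive")
})

test_that("the pooled t-test matches the closed-form oracle", {
  expect_equal(two_sample_t(c(5, 5, 5), c(5, 5, 5)), 1)
  # pooled: mean diff 9, s_p = 1, se = sqrt(2/3), t = 11.0227, df = 4
  t_stat <- 9 / sqrt(2 / 3)
  p_oracle <- 2 * stats::pt(-t_stat, df = 4)
  expect_equal(two_sample_t(c(10, 11, 12), c(1, 2, 3)), p_oracle,
               tolerance = 1e-12)
  # Welch flavour differs when variances do
  expect_false(isTRUE(all.equal(
    two_sample_t(c(1, 2, 3, 9), c(4, 4.1, 4.2), var_equal = FALSE),
    two_sample_t(c(1, 2, 3, 9), c(4, 4.1, 4.2), var_equal = TRUE))))
  # degenerate but unequal constant groups
  expect_equal(two_sample_t(c(2, 2), c(3, 3)), 0)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("direction calls obey the fold-change and p-value cut-offs", {
  sim <- simulate_study(tiny_config(seed = 19L, effect_fold = 2))
  calls <- de_call_variant(sim$datasets$DS2$A)
  up <- calls$fold_change > 1.5 & calls$p_value < 0.05
  down <- calls$fold_change < 1 / 1.5 & calls$p_value < 0.05
  expect_identical(calls$direction == "up", up)
  expect_identical(calls$direction == "down", down)
  # p-values are raw t-test output, no multiplicity adjustment
  g <- calls$gene[17]
  ds <- sim$datasets$DS2$A
  lg <- log2_matrix(ds)
  expect_equal(calls$p_value[17],
               two_sample_t(lg[g, ds$groups == "case"],
                            lg[g, ds$groups == "control"]))
})

test_that("dual-normalization agreement follows the selection rule", {
  mk <- function(dirs) data.frame(gene = paste0("g", seq_along(dirs)),
                                  dataset = "DS1", variant = "A",
                                  fold_change = 2, p_value = 0.01,
                                  direction = dirs, stringsAsFactors = FALSE)
  a <- mk(c("up", "up", "up", "none", "down"))
  b <- mk(c("up", "none", "down", "none", "down"))
  expect_message(sel <- dataset_selection(a, b), "opposite-direction")
  expect_equal(sel$status, c("both", "A_only", "conflict", "none", "both"))
  expect_equal(sel$direction, c("up", "up", "none", "none", "down"))
})

test_that("cross-dataset selection honours both-variant and complementary rules", {
  mk_sel <- function(ds, status, dir) {
    data.frame(gene = "g1", dataset = ds,
               dir_A = ifelse(status %in% c("both", "A_only"), dir, "none"),
               dir_B = ifelse(status %in% c("both", "B_only"), dir, "none"),
               status = status, direction = dir, stringsAsFactors = FALSE)
  }
  # both-variant agreement in one dataset qualifies
  res <- cross_dataset_selection(list(mk_sel("DS1", "both", "up")))
  expect_true(res$qualifies)
  expect_equal(res$n_up, 1L)
  # complementary: A-only in DS1, B-only in DS2, same direction
  res2 <- cross_dataset_selection(list(mk_sel("DS1", "A_only", "up"),
                                       mk_sel("DS2", "B_only", "up")))
  expect_true(res2$qualifies)
  expect_equal(res2$n_up, 2L)
  # a lone single-variant call does not qualify
  res3 <- cross_dataset_selection(list(mk_sel("DS1", "A_only", "up")))
  expect_false(res3$qualifies)
  # opposite-direction single-variant calls do not combine
  res4 <- cross_dataset_selection(list(mk_sel("DS1", "A_only", "up"),
                                       mk_sel("DS2", "B_only", "down")))
  expect_false(res4$qualifies)
})

test_that("consensus classes reproduce the reported 23-gene reference table", {
  ref <- ref_table("reference_consensus_degs.tsv")
  expect_equal(nrow(ref), 23L)
  cls <- classify_regulation(ref$n_up, ref$n_down)
  expect_identical(cls, ref$class)
  expect_equal(as.vector(table(cls)[c("Up", "Down", "Mixed")]),
               c(13L, 6L, 4L))
  expect_identical(classify_regulation(0, 0), "NotDE")
  expect_error(classify_regulation(-1, 0), "non-negative")
})

test_that("log2 fold-change reporting truncates toward zero at 2 decimals", {
  expect_equal(fc_log2_trunc(30.45), 4.92)   # rounding would give 4.93
  expect_equal(fc_log2_trunc(7.94), 2.98)    # rounding would give 2.99
  expect_equal(fc_log2_trunc(1), 0)
  ref <- ref_table("reference_consensus_degs.tsv")
  expect_equal(fc_log2_trunc(ref$fc_linear), ref$fc_log2)
})

test_that("the maximum fold change picks the largest deviation from 1", {
  calls <- data.frame(gene = "g", dataset = c("d1", "d2", "d3"),
                      variant = "A", fold_change = c(2, 0.2, 1.4),
                      p_value = 0.01, direction = c("up", "down", "none"),
                      stringsAsFactors = FALSE)
  mf <- max_fold_change("g", calls)
  expect_equal(mf$linear, 0.2)               # |log2 0.2| > |log2 2|
  expect_equal(mf$log2, fc_log2_trunc(0.2))
  expect_null(max_fold_change("absent", calls))
})

test_that("probe collapse keeps the highest-mean probe per gene", {
  m <- matrix(c(5, 5, 50, 50, 7, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  out <- collapse_probes(m, map)
  expect_equal(rownames(out), c("gA", "gB"))
  expect_equal(unname(out["gA", ]), c(50, 50))
  # identity when one probe per gene
  one <- collapse_probes(m[3, , drop = FALSE], map)
  expect_equal(unname(one["gB", ]), c(7, 7))
  # unmapped probes dropped with a message
  expect_message(collapse_probes(m, map[1:2]), "unmapped")
  # brute-force policy check on a random fixture
  set.seed(31)
  pm <- matrix(rnorm(40, 8), 10, 4,
               dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  pmap <- setNames(rep(c("g1", "g2", "g3"), c(4, 3, 3)), rownames(pm))
  out2 <- collapse_probes(pm, pmap)
  for (g in unique(pmap)) {
    probes <- names(pmap)[pmap == g]
    best <- probes[which.max(rowMeans(pm[probes, , drop = FALSE]))]
    expect_equal(out2[g, ], pm[best, ])
  }
})

test_that("planted DEGs are recovered with matching consensus direction", {
  cfg <- tiny_config(seed = 37L, effect_fold = 3,
                     cases_per_dataset = 10L, controls_per_dataset = 10L)
  sim <- simulate_study(cfg)
  res <- consensus_de(sim$datasets)
  cons <- res$consensus
  up <- cons$gene[cons$class == "Up"]
  down <- cons$gene[cons$class == "Down"]
  tp <- sum(up %in% sim$truth$planted_up) + sum(down %in% sim$truth$planted_down)
  planted_n <- length(sim$truth$planted_up) + length(sim$truth$planted_down)
  expect_gte(tp / (length(up) + length(down)), 0.9)  # precision
  expect_gte(tp / planted_n, 0.9)                    # recall
  # per-dataset calling of planted effects
  calls <- de_call_variant(sim$datasets$DS1$A)
  planted_calls <- calls[calls$gene %in% sim$truth$planted_up, ]
  expect_gte(mean(planted_calls$direction == "up"), 0.9)
})
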