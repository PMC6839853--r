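# Per-dataset differential-expression calling under two normalization
# variants, the dual-normalization agreement rule, and the cross-dataset
# consensus classification (Up / Down / Mixed / NotDE).
#
# Conventions: fold changes are case/control mean ratios on the LINEAR
# intensity scale (log2-scale matrices are exponentiated first, so the
# "> 1.5" cut means the same under both normalizations); t-tests are run
# on the log2 scale, where microarray intensities are approximately
# normal. p-values are deliberately NOT multiplicity-corrected at this
# stage — the cross-dataset consensus and downstream network integration
# act as the false-positive control.

#' Linear-scale group fold change
#'
#' Ratio of the case mean to the control mean on the linear intensity
#' scale. Log2-scale inputs are exponentiated before averaging.
#'
#' @param case_values,control_values numeric vectors.
#' @param scale `"linear"` or `"log2"`.
#' @return linear fold change (case / control).
#' @export
group_fold_change <- function(case_values, control_values,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (length(case_values) == 0L || length(control_values) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  if (scale == "log2") {
    case_values <- 2^case_values
    control_values <- 2^control_values
  }
  if (any(case_values <= 0) || any(control_values <= 0))
    stop("linear-scale intensities must be positive", call. = FALSE)
  m_ctrl <- mean(control_values)
  if (m_ctrl == 0) stop("control mean is zero", call. = FALSE)
  mean(case_values) / m_ctrl
}

#' Two-sample independent t-test p-value
#'
#' Two-sided p-value from the classical pooled-variance t-test
#' (`var_equal = TRUE`, the default) or Welch's unequal-variance test.
#' When both groups are constant, the p-value is 1 if the group means are
#' equal (t = 0 convention) and 0 otherwise.
#'
#' @param case_values,control_values numeric vectors, at least 2 values
#'   each.
#' @param var_equal pooled variance if TRUE (default), Welch otherwise.
#' @return two-sided p-value in \[0, 1\].
#' @export
two_sample_t <- function(case_values, control_values, var_equal = TRUE) {
  if (length(case_values) < 2L || length(control_values) < 2L)
    stop("need at least 2 values per group", call. = FALSE)
  if (stats::var(case_values) == 0 && stats::var(control_values) == 0) {
    return(if (mean(case_values) == mean(control_values)) 1 else 0)
  }
  stats::t.test(case_values, control_values, var.equal = var_equal)$p.value
}

call_direction <- function(fold_change, p_value,
                           fc_threshold = 1.5, p_threshold = 0.05) {
  ifelse(p_value < p_threshold & fold_change > fc_threshold, "up",
         ifelse(p_value < p_threshold & fold_change < 1 / fc_threshold, "down",
                "none"))
}

#' Call differential expression for one dataset variant
#'
#' Per gene: linear fold change, two-sided t-test p (on the log2 scale),
#' and a direction call at the fold-change and p-value cut-offs.
#'
#' @param ds a `mitonet_expr` object.
#' @param fc_threshold linear fold-change threshold (applied as
#'   `> fc_threshold` for up and `< 1/fc_threshold` for down).
#' @param p_threshold p-value threshold.
#' @param var_equal pooled-variance t-test if TRUE (default).
#' @return data.frame with columns `gene`, `dataset`, `variant`,
#'   `fold_change`, `p_value`, `direction`.
#' @export
de_call_variant <- function(ds, fc_threshold = 1.5, p_threshold = 0.05,
                            var_equal = TRUE) {
  lin <- linear_matrix(ds)
  lg <- log2_matrix(ds)
  cs <- case_samples(ds)
  ks <- control_samples(ds)
  fc <- rowMeans(lin[, cs, drop = FALSE]) / rowMeans(lin[, ks, drop = FALSE])
  p <- vapply(seq_len(nrow(lg)), function(i) {
    two_sample_t(lg[i, cs], lg[i, ks], var_equal = var_equal)
  }, 0)
  data.frame(gene = rownames(lin), dataset = ds$id, variant = ds$variant,
             fold_change = unname(fc), p_value = p,
             direction = call_direction(fc, p, fc_threshold, p_threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dual-normalization agreement for one dataset
#'
#' A gene is selected within a dataset only when both normalization
#' variants call it in the same direction. Single-variant calls are
#' retained (status `A_only` / `B_only`) because the cross-dataset
#' complementary rule needs them; opposite-direction calls are flagged
#' `conflict` and never selected. Genes measured in only one variant are
#' dropped to the variants' intersection.
#'
#' @param calls_a,calls_b [de_call_variant()] outputs for variants A and B
#'   of the same dataset.
#' @return data.frame `gene`, `dataset`, `dir_A`, `dir_B`, `status`
#'   (`both`, `A_only`, `B_only`, `conflict`, `none`), `direction` (the
#'   agreed direction for `both`, else `"none"`).
#' @export
dataset_selection <- function(calls_a, calls_b) {
  common <- intersect(calls_a$gene, calls_b$gene)
  if (length(common) < length(union(calls_a$gene, calls_b$gene)))
    message(length(union(calls_a$gene, calls_b$gene)) - length(common),
            " genes present in only one variant dropped to the intersection")
  a <- calls_a[match(common, calls_a$gene), ]
  b <- calls_b[match(common, calls_b$gene), ]
  status <- ifelse(a$direction != "none" & a$direction == b$direction, "both",
            ifelse(a$direction != "none" & b$direction == "none", "A_only",
            ifelse(a$direction == "none" & b$direction != "none", "B_only",
            ifelse(a$direction != "none" & b$direction != "none", "conflict",
                   "none"))))
  n_conflict <- sum(status == "conflict")
  if (n_conflict > 0L)
    message(n_conflict, " genes with opposite-direction variant calls in ",
            a$dataset[1])
  data.frame(gene = common, dataset = a$dataset,
             dir_A = a$direction, dir_B = b$direction, status = status,
             direction = ifelse(status == "both", a$direction,
                                ifelse(status == "A_only", a$direction,
                                       ifelse(status == "B_only", b$direction,
                                              "none"))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-dataset study-wide gene selection
#'
#' A gene is a study-wide DEG if (a) both normalization variants agree on
#' its direction in at least one dataset, or (b) it is called by variant A
#' only in one dataset and by variant B only in a different dataset, in
#' the same direction ("complementary normalization methods in at least
#' two datasets"). For a qualifying gene, a dataset counts toward the
#' up (down) tally when the both-variant agreement holds there with
#' direction up (down), or when the complementary rule is satisfied for
#' that direction and the dataset contributes a single-variant call of
#' that direction.
#'
#' @param selections list of [dataset_selection()] outputs, one per
#'   dataset.
#' @return data.frame `gene`, `n_up`, `n_down`, `n_selected`, `qualifies`.
#' @export
cross_dataset_selection <- function(selections) {
  stopifnot(length(selections) >= 1L)
  sel <- do.call(rbind, selections)
  genes <- sort(unique(sel$gene))
  per_gene <- split(sel, sel$gene)
  res <- lapply(genes, function(g) {
    s <- per_gene[[g]]
    count_dir <- function(dir) {
      both <- s$status == "both" & s$direction == dir
      a_only <- s$status == "A_only" & s$direction == dir
      b_only <- s$status == "B_only" & s$direction == dir
      # complementary: an A-only call and a B-only call in different datasets
      comp <- any(a_only) && any(b_only) &&
        length(unique(s$dataset[a_only | b_only])) >= 2L
      sum(both | (if (comp) a_only | b_only else FALSE))
    }
    n_up <- count_dir("up")
    n_down <- count_dir("down")
    data.frame(gene = g, n_up = n_up, n_down = n_down,
               n_selected = n_up + n_down,
               qualifies = (n_up + n_down) > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Consensus regulation class from direction counts
#'
#' Up: up-regulated in at least one dataset and down in none; Down: the
#' mirror; Mixed: both directions observed; NotDE otherwise.
#'
#' @param n_up,n_down integer vectors of per-gene dataset counts.
#' @return character vector of classes (`"Up"`, `"Down"`, `"Mixed"`,
#'   `"NotDE"`).
#' @export
classify_regulation <- function(n_up, n_down) {
  if (any(n_up < 0) || any(n_down < 0))
    stop("direction counts must be non-negative", call. = FALSE)
  ifelse(n_up >= 1 & n_down == 0, "Up",
         ifelse(n_down >= 1 & n_up == 0, "Down",
                ifelse(n_up >= 1 & n_down >= 1, "Mixed", "NotDE")))
}

#' Truncated log2 of a linear fold change
#'
#' Reporting convention for fold-change tables: the log2 value is
#' truncated toward zero at two decimals (e.g. linear 7.94 prints as
#' 2.98, not 2.99). Full precision is retained internally; this is only
#' the display transform.
#'
#' @param fc linear fold change(s).
#' @return log2 fold change truncated toward zero at 2 decimals.
#' @export
fc_log2_trunc <- function(fc) {
  x <- log2(fc)
  trunc(x * 100 + sign(x) * 1e-9) / 100
}

#' Maximum fold change across passing calls
#'
#' The fold change of largest magnitude deviation from 1 (largest
#' |log2 FC|) across all datasets/variants where the gene passed the
#' per-variant cut-offs.
#'
#' @param gene gene symbol.
#' @param calls combined [de_call_variant()] rows for all datasets and
#'   variants.
#' @return list with `linear` and `log2` (truncated) values, or `NULL`
#'   when the gene has no passing call.
#' @export
max_fold_change <- function(gene, calls) {
  rows <- calls[calls$gene == gene & calls$direction != "none", , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  best <- rows$fold_change[which.max(abs(log2(rows$fold_change)))]
  list(linear = best, log2 = fc_log2_trunc(best))
}

#' Cross-dataset consensus differential-expression table
#'
#' Runs per-variant calling, the dual-normalization agreement rule and
#' the cross-dataset selection over all datasets, then classifies each
#' qualifying gene and reports its maximum fold change.
#'
#' @param datasets list as returned by [generate_expression_datasets()]
#'   (each element holding `A` and `B` `mitonet_expr` objects).
#' @param fc_threshold,p_threshold per-variant cut-offs.
#' @param var_equal pooled-variance t-test if TRUE.
#' @return list with `consensus` (data.frame `gene`, `n_up`, `n_down`,
#'   `n_selected`, `class`, `max_fc_linear`, `max_fc_log2`; qualifying
#'   genes only), `calls` (all per-variant calls) and `selections`
#'   (per-dataset agreement tables).
#' @export
consensus_de <- function(datasets, fc_threshold = 1.5, p_threshold = 0.05,
                         var_equal = TRUE) {
  calls <- list()
  selections <- list()
  for (d in datasets) {
    ca <- de_call_variant(d$A, fc_threshold, p_threshold, var_equal)
    cb <- de_call_variant(d$B, fc_threshold, p_threshold, var_equal)
    calls[[length(calls) + 1L]] <- ca
    calls[[length(calls) + 1L]] <- cb
    selections[[d$id]] <- dataset_selection(ca, cb)
  }
  calls <- do.call(rbind, calls)
  cross <- cross_dataset_selection(selections)
  deg <- cross[cross$qualifies, , drop = FALSE]
  if (nrow(deg) > 0L) {
    deg$class <- classify_regulation(deg$n_up, deg$n_down)
    mf <- lapply(deg$gene, max_fold_change, calls = calls)
    deg$max_fc_linear <- vapply(mf, function(x) if (is.null(x)) NA_real_ else x$linear, 0)
    deg$max_fc_log2 <- vapply(mf, function(x) if (is.null(x)) NA_real_ else x$log2, 0)
  } else {
    deg$class <- character(0)
    deg$max_fc_linear <- numeric(0)
    deg$max_fc_log2 <- numeric(0)
  }
  deg$qualifies <- NULL
  rownames(deg) <- NULL
  list(consensus = deg, calls = calls, selections = selections)
}
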