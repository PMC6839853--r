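# mitonet

Tissue-specific mitochondrial protein–protein interaction (PPI) network
analysis in R.

Chronic inflammatory diseases such as rheumatoid arthritis (RA) involve
mitochondrial dysfunction in the affected tissue, driven largely by
nuclear-DNA-encoded proteins that translocate to the organelle. Generic
PPI databases describe interactions anywhere in any cell; to study one
organelle in one tissue, the interactome must be cut down twice — to the
organelle's proteome, and to protein pairs that are actually
co-expressed in the diseased tissue. `mitonet` implements that
construction, the surrounding differential-expression consensus across
multiple case/control expression datasets, the topology analysis of the
resulting network, and gene-set over-representation testing, together
with a seeded synthetic-data generator that plants ground truth so every
stage can be validated end to end.

## The method

**Reliability filtering and integration.** Candidate interactions come
from several source databases with heterogeneous evidence. Score-bearing
sources keep interactions with confidence *s* > median(*s*) of that
source's score distribution; a curation-flag source keeps its core
subset; literature-based sources keep interactions with ≥ 2 publication
evidences. Filtered tables are merged into one simple undirected graph
(unordered pairs, self-loops dropped, provenance kept) and restricted to
edges with **both** endpoints in the organelle gene catalog.

**Co-expression (tissue) filter.** For each surviving edge (a, b) and
each expression dataset, the Pearson correlation ρ(a, b) is computed
across the *disease* samples only. An edge is kept when ρ > 0.7 in at
least one dataset; its *support* is the number of datasets agreeing.

**Consensus differential expression.** Each dataset is analysed under
two normalization variants. Per variant, gene-level calls use a linear
fold change FC > 1.5 (up) or FC < 1/1.5 (down) together with a two-sided
pooled-variance t-test p < 0.05, deliberately uncorrected. A gene enters
the study-wide consensus when both variants agree on direction in ≥ 1
dataset, or complementary variants call it (same direction) in ≥ 2
datasets; per-gene direction counts (n_up, n_down) over qualifying
datasets classify it **Up** (n_up ≥ 1, n_down = 0), **Down** (mirror),
or **Mixed** (both). Maximum fold changes are reported linear and log2,
the latter truncated toward zero at two decimals.

**Topology.** The tissue network's degree distribution P(k) is fitted
with P(k) ∝ k^−α (log-log least squares by default, discrete MLE as
alternative). Hubs are ranked by degree with tallies of consensus
classes among their immediate neighbours; *key hubs* have ≥ 27
neighbours including ≥ 7 differentially expressed ones.

**Enrichment.** Term over-representation uses the upper-tail
hypergeometric test P(X ≥ k) for an overlap of k query genes with a
K-gene term in an N-gene background, with Benjamini–Hochberg FDR and
significance at FDR < 0.01.

**Robustness to therapy effects.** Samples are hierarchically clustered
(average linkage, Euclidean distance on per-gene z-scores) on the panel
of broadly selected DEGs; case samples falling in the control-majority
cluster are removed and the consensus analysis repeated, reporting genes
gained and lost.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated study (seed 1) whose structure mirrors the intended use case:
six case/control datasets with unequal sample sizes and partial gene
coverage, an 1158-gene organelle catalog, seven interaction sources.
Running them in order prints, among other things:

```
$ Rscript analysis/02_integrate_ppi.R
Integration stages:
  source records in:         58184
  after reliability filters: 31342
  merged unique edges:       12888
  both endpoints in catalog: 10437

$ Rscript analysis/03_differential_expression.R
Consensus differential expression:
  study-wide DEGs: 197
Down   Up
 116   81
  planted-direction precision 1.000, recall 1.000

$ Rscript analysis/04_coexpression_network.R
  co-expressed edges kept: 6553
  support histogram (datasets -> edges):
   1    2    3    4    5    6
2267 2486 1362  384   53    1

$ Rscript analysis/05_network_topology.R
Tissue network: 1158 nodes, 6553 edges
  key hubs (>=27 neighbours, >=7 DEG neighbours): 33

$ Rscript analysis/06_enrichment.R
  significant at FDR < 0.01: 3
```

Reading: the reliability filters keep roughly half of the raw source
records; the co-expression filter then removes ~37% of catalog edges.
All 197 planted differentially expressed genes are recovered with their
planted directions and no false consensus calls, and exactly the three
annotation terms built enriched in planted DEGs reach FDR < 0.01 — the
pipeline finds what was planted and nothing else. Equivalent
functionality is available programmatically via `run_demo()` /
`run_pipeline()`.

## The methods vignette

`vignettes/mitonet-methods.Rmd` documents the statistical model behind
the synthetic-data generator, every tunable threshold with its default
and rationale, numerical conventions (tie handling, degenerate inputs,
truncation rules), and known limitations.
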