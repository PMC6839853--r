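Reference tables of reported consensus differential-expression results in
rheumatoid-arthritis synovium, used to validate the consensus
classification and fold-change reporting conventions:

reference_consensus_degs.tsv
  23 mitochondrial genes differentially expressed in at least three of six
  synovial microarray datasets: per-gene counts of datasets with up- and
  down-regulation, the reported consensus class, and the maximum fold
  change (linear and log2 as printed).

reference_oxphos_degs.tsv
  11 oxidative-phosphorylation (respiratory chain complex) subunit genes
  with per-direction dataset counts and complex membership.
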