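# Example configuration for the dyneqtl command-line front end.
# Paths are relative to the working directory of the invocation.
genotype: genotypes.tsv
expression:
  S: expression_S.tsv
  P: expression_P.tsv
  E: expression_E.tsv
  M: expression_M.tsv
gene_loci: gene_loci.tsv
conditions: [S, P, E, M]
transitions:
  - [S, P]
  - [P, E]
  - [P, M]
rf:
  n_trees: 1000
  mtry: null          # ceiling(p/3)
  min_node_size: 5
  seed: 1
perm:
  n: 10
  policy: within_condition
thresholds:
  mapping_fdr: 0.1
  interaction_fdr: 0.1
  contrast_alpha: 0.05
cis_window_bp: 1000000
region_min_pairs: 20
merge_markers: true
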