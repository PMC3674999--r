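# dyneqtl

Mapping and classification of **static**, **conditional** and **dynamic**
expression quantitative trait loci (eQTL) across multiple conditions or
cell types, for panels of homozygous recombinant inbred lines (RIL) such
as the mouse BXD strains.

Regulatory variation measured in several cell types falls into three
classes: a *static* eQTL affects its target gene identically in every
cell type; a *conditional* eQTL acts only in some cell types (or with
changing effect size); a *dynamic* eQTL drives the change in expression
between two cell types and is invisible to level-based mapping. `dyneqtl`
is aimed at quantitative geneticists who want all three classes from one
analysis of a multi-condition expression panel plus a diallelic genotype
matrix.

## Method

1. **Simultaneous mapping.** For each gene, expression vectors from all
   conditions are stacked into one trait vector `Y`; the genotype matrix
   is replicated per condition and one 0/1 cell-type indicator column is
   appended per condition. A regression Random Forest is fit and each
   marker's **selection frequency** `SF(m) = (splits using m) / (total
   splits)` measures its importance. Because trees can split on an
   indicator first and a marker second, markers predictive in only one
   condition are discoverable in the same run.
2. **Significance.** The trait is permuted (within condition blocks) a
   small number of times per gene; null SFs of each marker are pooled
   over *all genes and permutations*, giving a marker-specific null. An
   exponential tail fitted to the top 1% of the pooled null (threshold
   `s0` = 99th percentile, scale `lambda` = mean exceedance) refines
   p-values far beyond permutation resolution:
   `p = 0.01 * exp(-(SF - s0)/lambda)` for `SF > s0`, the add-one
   empirical fraction otherwise. FDR is Benjamini–Hochberg over all
   (gene, marker) pairs; pairs with `q <= 0.1` are reported.
3. **Classification.** Each significant pair is tested for a
   marker-by-condition interaction (full vs reduced ANOVA,
   `y ~ x*c` vs `y ~ x + c`); interaction FDR `<= 0.1` labels the pair
   conditional, otherwise static. Post-hoc Wald contrasts on the
   per-condition effects (Bonferroni within the eQTL) identify the
   active cell types.
4. **Dynamic mapping.** For a condition transition, the per-strain
   difference trait (a log fold-change) is mapped with the same
   machinery on genotypes only. Equal (static) effects cancel exactly in
   the difference; sign-swapping effects gain power.

A synthetic RIL generator (`make_fixture()`) plants eQTL of all three
classes with a machine-readable truth set, so the entire pipeline is
testable without any external data.

## Worked example

```r
library(dyneqtl)

fx   <- make_fixture("default", seed = 101) # 24 strains, 4 conditions, 120 genes
geno <- merge_identical_markers(fx$geno)    # 100 -> 93 distinct markers
run  <- run_simultaneous(fx$panels, geno, forest_config(seed = 101))

table(run$significant$class)
#> conditional      static
#>           5          22

head(run$significant[, c("gene_id", "marker_id", "sf", "p", "q", "class")], 5)
#>   gene_id marker_id     sf        p        q  class
#> 1 gene001 chr1_m003 0.0211 3.70e-06 0.003309 static
#> 2 gene002 chr1_m005 0.0214 4.15e-06 0.003309 static
#> 3 gene003 chr1_m007 0.0191 1.55e-04 0.069178 static
#> 4 gene004 chr1_m009 0.0264 2.22e-07 0.000354 static
#> 5 gene005 chr1_m011 0.0236 1.17e-06 0.001309 static
```

Each row is one significant gene-marker pair at FDR 0.1: `sf` is the
marker's selection frequency for the gene's stacked trait, `p` the hybrid
permutation p-value, `q` the genome-wide BH FDR, and `class` the
interaction-test verdict; conditional pairs additionally carry their
active conditions and per-condition Wald contrast p-values. Dynamic
mapping on the three default transitions and the class overlap complete
the picture:

```r
dyn <- run_dynamic(fx$panels, geno, cfg = forest_config(seed = 101))
summarize_overlap(run$significant, dyn$significant)
#>                          set n_pairs
#> 1                     static      22
#> 2                conditional       5
#> 3                    dynamic       9
#> 4         static&conditional       0
#> 5             static&dynamic       0
#> 6        conditional&dynamic       2
#> 7 static&conditional&dynamic       0
```

Static and conditional labels are exclusive by construction, static and
dynamic discoveries do not overlap (equal allelic effects cancel in a
difference trait), while a conditional eQTL can legitimately reappear as
dynamic: an effect present in one condition of a transition *is* a
genotype-dependent expression change.

A thin command-line front end over the same functions ships in
`inst/cli/dyneqtl` (`simulate`, `map-simultaneous`, `map-dynamic`,
`annotate-cis-trans`, `analyze-regions`, `summarize`), driven by a YAML
config in which every analysis threshold is an explicit key.

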