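---
title: "Classifying static, conditional and dynamic eQTL with dyneqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying static, conditional and dynamic eQTL with dyneqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Expression quantitative trait loci (eQTL) are genomic regions whose
genotype associates with a gene's mRNA level. When expression is measured
in several conditions — here, cell types along a differentiation
hierarchy, profiled across a panel of homozygous recombinant inbred
strains — regulatory variation falls into three qualitatively different
classes:

* a **static** eQTL affects its target in every condition, with the same
  allelic effect;
* a **conditional** eQTL affects its target only in a subset of
  conditions, or with condition-dependent effect size or sign
  (a significant marker-by-condition interaction);
* a **dynamic** eQTL drives the *change* in expression between two
  conditions: its natural trait is the per-strain log fold-change of a
  transition, not the expression level in either condition.

`dyneqtl` implements a single pipeline that maps and discriminates all
three classes, together with a synthetic recombinant-inbred-line (RIL)
generator that plants effects of every class so the whole pipeline can be
validated end-to-end against a known truth.

## Simultaneous mapping on the stacked design

Rather than mapping each condition separately (which needs both a
significance and an awkward "insignificance" threshold to compare
conditions), all conditions are mapped at once. For each gene, the
per-condition expression vectors are concatenated into one trait vector
$Y$; the genotype matrix is replicated per condition (subset to the
strains measured in that condition) and one 0/1 indicator column per
condition is appended. `build_stacked_design()` constructs this object.

The mapping engine is a regression Random Forest (`ranger`). The
importance measure is the **selection frequency** (SF): the number of
internal split nodes that use a predictor, divided by the total number of
internal splits in the forest. SFs sum to one over predictors, which is
what makes null SFs poolable across genes. A marker used more often than
expected by chance is an eQTL of the gene. Because the condition
indicators are ordinary predictors, a tree can first split samples by
condition and then use a marker that is predictive only within one
condition — this is what makes conditional eQTL visible to a single
mapping. Indicators are excluded from eQTL reporting but keep their SF
mass.

Forest defaults (`forest_config()`): 1000 trees, `mtry = ceiling(p/3)`
(the standard regression-forest choice), minimum node size 5, unlimited
depth, and an explicit seed — forests are exactly reproducible, and
per-gene seeds are derived from the run seed and the gene index so
gene-level work units can be executed in any order.

## From selection frequencies to p-values

Raw SFs are not comparable between markers: allele frequencies and local
linkage bias the SF of some markers even under the null. The null is
therefore estimated *per marker* by permutation: the trait is permuted
(by default within each condition block, which preserves condition means
so the null targets the genotype association; a global policy is also
available), the forest is refit, and the SFs of each marker are pooled
over **all genes and all permutations**. Under the null hypothesis the SF
distribution of a marker is the same for every gene, so a run with $G$
genes and $B$ permutations yields $G \times B$ null draws per marker from
only $B$ forest refits per gene (default $B = 10$).

Permutation resolution alone would floor p-values at $1/(GB+1)$. The
interesting eQTL live far beyond that, so the top 1% of each marker's
pooled null is replaced by a fitted exponential tail: the threshold $s_0$
is the empirical 99th percentile (type-7, linear-interpolation quantile —
documented so the threshold is reproducible), and the scale $\lambda$ is
the maximum-likelihood estimate for exceedances, their mean over $s_0$.
The hybrid p-value is

$$
p(s) =
\begin{cases}
\dfrac{1 + \#\{s^{null} \ge s\}}{1 + GB}, & s \le s_0
  \text{ or tail disabled},\\[1ex]
0.01 \, e^{-(s - s_0)/\lambda}, & s > s_0,
\end{cases}
$$

continuous at $s_0$ up to discreteness. The add-one empirical estimator
never returns zero (required for valid Benjamini–Hochberg adjustment) and
counts ties conservatively with $\ge$. With fewer than two distinct
exceedances the tail is disabled and the empirical branch is used
everywhere. False discovery rates are BH q-values over all
(gene, marker) pairs of a run, and pairs with $q \le 0.1$ are reported —
the genome-wide FDR convention used throughout.

## Static versus conditional

Every significant pair is then tested for a marker-by-condition
interaction: a full least-squares model
`y ~ genotype * condition` against the reduced `y ~ genotype + condition`,
compared by the standard F statistic. Interaction p-values are
BH-adjusted over exactly the significant set, and a pair is labelled
**conditional** iff its interaction q-value is at most 0.1, **static**
otherwise — the two labels are exhaustive and exclusive by construction.
Two degenerate cases are handled deliberately: a zero-residual full fit
reports $p = 1$ (conditionality cannot be claimed without residual
variance), and a marker constant within every condition has no testable
interaction and is labelled static with a flag.

For conditional pairs, the active conditions are identified by post-hoc
Wald contrasts: the per-condition genotype effect $\beta_t$ (main effect
plus the interaction coefficient of condition $t$, with its standard
error from the full-model covariance) is tested against zero with a
two-sided normal test, Bonferroni-corrected within the eQTL (the family
is the set of testable conditions of that eQTL, not the genome), and
conditions with adjusted $p \le 0.05$ are reported active. Treatment
coding is used for the condition factor; F and Wald contrasts are
invariant to any full-rank coding. A conditional pair with an empty
active set is kept and flagged rather than dropped. Both alpha and the
interaction FDR are configuration parameters, defaulting to 0.05 and 0.1.

## Dynamic mapping on difference traits

For a transition between two conditions, `build_difference_trait()` forms
the per-strain difference (to − from) over the strains measured in both —
a log fold-change, since inputs are log2 scale. `map_dynamic()` then runs
the same RF/SF/permutation/tail/FDR machinery on a genotype-only design
(no indicators; permutations are global because there is a single block),
with pooled nulls built per transition since sample sizes differ.
Transitions are directed and explicit (default S→P, P→E, P→M for the
four-cell-type layout).

Two algebraic facts shape the results. First, a static effect cancels
exactly in the difference: equal betas leave the diffs independent of
genotype, so static eQTL cannot leak into dynamic discoveries (in the
noiseless limit the difference trait is constant and the gene is
skipped). Second, differences inherit the independent errors of both
conditions, so $\mathrm{var}(\mathrm{diff}) = 2\sigma^2$ — the documented
reason dynamic mapping has fewer discoveries than level mapping. Its
advantage appears for sign-swapping effects (+β in one condition, −β in
the other): per-condition effects are halved relative to the difference
signal, and pooled analyses cancel entirely, while the difference trait
carries the full 2β gap.

## Post-analysis

`classify_cis_trans()` labels a pair cis when the target gene's locus
overlaps the marker interval extended by a window (default 1 Mb on either
side) on the same chromosome, trans otherwise. The window default is a
convention, not a derived quantity, and published cis/trans fractions are
sensitive to it — it is deliberately a prominent parameter.

`analyze_regions()` takes eQTL-rich markers (those with at least
`min_pairs` = 20 significant target pairs — the qualitative "locus with
many targets" notion made explicit) and applies a Friedman rank test
across conditions to the matrix of per-condition Wald-contrast p-values
of the region's targets. The test uses midranks with the standard tie
correction and a chi-square reference with $k-1$ degrees of freedom —
adequate at the block counts involved (tens of targets); being
rank-based, it is invariant to monotone transforms within rows, so
applying it to p-values is sound.

## The synthetic RIL generator

`simulate_ril_genotypes()` draws each strain's chromosome as a two-state
Markov chain: first marker Bernoulli(0.5), each subsequent marker
flipping with probability `recomb_prob`. This is not an explicit meiosis
model, but it produces the two features that matter downstream: linkage
blocks (so signal spreads over neighboring markers, as in real panels)
and occasional identical adjacent marker columns (so marker merging is
exercised). Only homozygous diallelic genotypes are simulated.

`simulate_expression_panels()` implements
$y_{gst} = \mathrm{baseline}_{gt} + \beta_{gt}\,x_{s} + \varepsilon$,
with i.i.d. Gaussian noise. The default fixture
(`make_fixture("default")`) emulates the target data class: 24 strains,
4 conditions with 22–24 strains measured each, 100 markers on 5
chromosomes with `recomb_prob = 0.1` (high local linkage, as in a small
RIL panel typed at sub-megabase density), and 120 genes — 20 static
(β = 1.5 in noise-SD units), 20 single-condition conditional (β = 2), 10
sign-swapping dynamic (β = ±1 on the P/M pair), 70 null. Each gene
additionally receives per-condition baselines drawn N(0, 1): distinct
cell types differ in expression level for most genes even after joint
normalization, and this between-condition structure is what the
indicator predictors absorb. What the generator deliberately does *not*
model: probe-level microarray structure, batch effects, heteroskedastic
or heavy-tailed noise, epistasis, and polygenic trans backgrounds —
passing tests on these fixtures demonstrate the machinery is correct and
calibrated, not that real data will be as kind.

## Validation studies and their observed outcomes

`eval_planted_recovery()`, `eval_null_calibration()` and
`eval_swap_power()` run the full pipeline on generated fixtures and score
it against the planted truth; the test suite and
`scripts/acceptance.R` both call them. Study sizes were chosen once as a
balance between Monte-Carlo error and a desk-scale compute envelope:
1000-tree forests with 10 permutations for the single recovery run,
150–250 trees for the repeated null and power replicates, 10 null seeds,
and 25 power datasets with 2 planted swap genes each.

Two honest limitations of the method at this sample size emerge from the
studies and are worth stating plainly:

* **Single-condition conditional eQTL are hard for the SF statistic.**
  A marker whose effect (2 noise-SDs) lives in only ~22 of ~92 stacked
  rows attains a selection frequency only marginally above the pooled
  null's 99th percentile, and its hybrid p-value (median ~10⁻²·⁵)
  rarely clears a genome-wide BH bar near 3×10⁻⁴. Static loci at
  β = 1.5 recover essentially completely, and the loci that *are*
  detected are classified and localized to the correct active condition
  with high accuracy — but conditional *recall* is low (~10–40%). An
  interaction ANOVA on the same data detects these effects at p ~ 10⁻⁶,
  so the ceiling belongs to the RF-SF mapping statistic at n = 22–24
  strains per condition and a 10-permutation null, not to the data or
  the classification stage. Depth-capped trees, larger or smaller
  `mtry`, and a per-tree-presence SF variant were all benchmarked and
  none changes this materially.
* **Sign-swapping effects strong enough for dynamic detection are also
  visible to simultaneous mapping.** At the power study's
  effect-to-noise ratio (β = ±1, σ = 0.3, 24 strains), dynamic mapping
  recovers roughly three quarters of swap loci while the stacked
  mapping plus interaction test recovers even more of them; at the
  default fixture's weaker β = ±1σ, both arms recover almost none. At
  this panel size the difference trait's robust advantage is therefore
  the *exact exclusion* of static effects (and the cleaner trait
  definition), not a large power separation; with weaker or purely
  change-associated effects and more strains, the balance shifts toward
  dynamic mapping.
* **Realized FDR at desk scale is approximate.** The exponential tail is
  fitted to only ~12 exceedances when 120 genes and 10 permutations are
  pooled, so far-tail p-values are an extrapolation; in planted-effect
  runs the realized false-discovery proportion among q ≤ 0.1 discoveries
  fluctuates around 0.1–0.25 rather than sitting tightly at the nominal
  0.1. Larger gene panels (the intended regime, with thousands of genes
  pooled) stabilize the tail in proportion.

## Numerical conventions and edge cases

* Genotypes are coded B→0, D→1; heterozygous/unknown input calls are
  rejected by default (a lenient mode drops the affected markers).
* Coordinates are 1-based inclusive bp; merged markers span
  `[min start, max end]` of their run and keep the first member's id.
* The SD filter uses the sample (n−1) standard deviation.
* Quantiles are type-7 throughout.
* Constant traits yield an all-zero, flagged SF profile; designs with
  fewer than `2 * min_node_size` rows are an error.
* BH is computed by `stats::p.adjust`; the Friedman statistic is
  computed by the package's own tie-corrected implementation and is
  tested against `stats::friedman.test` to 10⁻¹⁰.
* All randomness flows through explicit seeds; identical seeds give
  byte-identical output files.
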