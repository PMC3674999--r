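Package: dyneqtl
Title: Static, Conditional and Dynamic eQTL Mapping by Simultaneous
    Random-Forest Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps and classifies expression quantitative trait loci (eQTL)
    across multiple conditions or cell types from recombinant-inbred-line
    panels. Gene expression from all conditions is stacked into one trait
    vector and mapped simultaneously with Random Forests; the selection
    frequency of each marker across the forest is converted into p-values
    via per-marker pooled permutation null distributions with an
    exponential upper tail, and significant eQTL are discriminated into
    static and conditional classes by a marker-by-condition interaction
    ANOVA with post-hoc Wald contrasts. Dynamic eQTL, which drive
    expression changes between paired conditions, are mapped on per-strain
    log fold-change traits with the same machinery. Includes readers for
    GeneNetwork-style genotype and expression tables, marker merging and
    variance filtering, cis/trans annotation, Friedman tests for
    condition-biased eQTL-rich regions, and a synthetic
    recombinant-inbred-line data generator with planted eQTL of all three
    classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
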