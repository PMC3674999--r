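# Dynamic eQTL mapping on per-strain expression differences.
#
# A dynamic eQTL drives the *change* in expression between two conditions.
# Because inputs are log2-scale, the per-strain difference is a log
# fold-change, and mapping it directly has more power than per-condition
# mapping when allelic effects swap sign between the conditions (the
# per-condition effects can cancel in pooled analyses while the difference
# trait carries twice the effect). The price is noise inflation: under
# independent errors var(diff) = 2 sigma^2.

#' Build a per-strain difference (transition) trait for one gene
#'
#' diffs = value(to) - value(from) over the strains measured in both
#' conditions, in shared-strain order.
#'
#' @param panel_from,panel_to `expression_panel` objects of the transition.
#' @param gene_id gene to difference.
#' @return object of class `transition_trait`: `gene_id`, `condition_pair`
#'   (from, to), `strains`, `diffs`.
#' @export
build_difference_trait <- function(panel_from, panel_to, gene_id) {
  stopifnot(inherits(panel_from, "expression_panel"),
            inherits(panel_to, "expression_panel"))
  if (!gene_id %in% panel_from$genes || !gene_id %in% panel_to$genes) {
    stop("gene absent from one of the panels: ", gene_id)
  }
  shared <- intersect(panel_from$strains, panel_to$strains)
  if (length(shared) < 4) {
    stop("insufficient paired samples: ", length(shared), " shared strains")
  }
  diffs <- panel_to$values[gene_id, shared] - panel_from$values[gene_id, shared]
  structure(list(gene_id = gene_id,
                 condition_pair = c(from = panel_from$condition,
                                    to = panel_to$condition),
                 strains = shared, diffs = unname(diffs)),
            class = "transition_trait")
}

#' Map dynamic eQTL for one condition transition
#'
#' For each gene shared by the two panels, builds the difference trait and
#' runs the same RF selection-frequency machinery as simultaneous mapping
#' — genotype predictors only (no condition indicators), global
#' permutations (a single trait block), per-transition pooled nulls with
#' exponential tails, and BH FDR over all (gene, marker) pairs of the
#' transition. Genes with zero-variance differences are skipped (logged).
#'
#' @param panel_from,panel_to `expression_panel` objects of the transition.
#' @param geno a `genotype_panel`.
#' @param cfg a `forest_config`.
#' @param n_perm permutations per gene (default 10).
#' @param genes optional subset of genes to map; default all shared genes.
#' @return data.frame: transition, gene_id, marker_id, sf, p, q, branch.
#' @export
map_dynamic <- function(panel_from, panel_to, geno, cfg = forest_config(),
                        n_perm = 10, genes = NULL) {
  if (is.null(genes)) genes <- intersect(panel_from$genes, panel_to$genes)
  transition <- paste0(panel_from$condition, "-", panel_to$condition)
  observed <- list()
  permuted <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    trait <- build_difference_trait(panel_from, panel_to, g)
    strains <- intersect(trait$strains, geno$strains)
    y <- trait$diffs[match(strains, trait$strains)]
    if (length(unique(y)) < 2) {
      log_event("skip_gene", "gene '", g, "': zero-variance difference trait in ",
                transition)
      next
    }
    design <- build_trait_design(y, strains, geno, g, condition = transition)
    res <- map_gene(design, cfg, n_perm, policy = "global", gene_index = i)
    observed[[length(observed) + 1]] <- res$observed
    permuted[[length(permuted) + 1]] <- res$permuted
  }
  if (length(observed) == 0) {
    return(data.frame(transition = character(0), gene_id = character(0),
                      marker_id = character(0), sf = numeric(0),
                      p = numeric(0), q = numeric(0), branch = character(0),
                      stringsAsFactors = FALSE))
  }
  nulls <- pool_null(permuted)
  res <- eqtl_test(observed, nulls)
  cbind(transition = transition, res, stringsAsFactors = FALSE)
}
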