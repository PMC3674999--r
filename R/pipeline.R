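# End-to-end pipelines: simultaneous mapping + classification, dynamic
# mapping per transition, and overlap summaries.

#' Run the simultaneous multi-condition eQTL mapping pipeline
#'
#' For every gene: build the stacked design, fit the observed forest and
#' `n_perm` permuted forests, pool per-marker nulls over all genes, convert
#' SFs to hybrid p-values, BH-adjust over all (gene, marker) pairs, then
#' discriminate static vs conditional eQTL among the significant pairs by
#' interaction ANOVA and post-hoc Wald contrasts.
#'
#' Per-gene seeds are derived from `cfg$seed` and the gene's index, so
#' gene-level work units are independent and order-insensitive.
#'
#' @param panels list of `expression_panel` objects (condition order).
#' @param geno a `genotype_panel` (markers already merged as desired).
#' @param cfg a `forest_config`.
#' @param n_perm permutations per gene (default 10).
#' @param policy permutation policy (default "within_condition").
#' @param mapping_fdr FDR threshold for calling a pair significant.
#' @param interaction_fdr FDR threshold for calling a significant pair
#'   conditional.
#' @param contrast_alpha level for the post-hoc Wald contrasts.
#' @param genes optional gene subset; default union over panels.
#' @return list with `results` (all pairs: gene_id, marker_id, sf, p, q,
#'   branch), `significant` (classified pairs with class, q_interaction,
#'   active_conditions, contrast columns), `nulls` (per-marker
#'   `marker_null`s).
#' @export
run_simultaneous <- function(panels, geno, cfg = forest_config(),
                             n_perm = 10, policy = "within_condition",
                             mapping_fdr = 0.1, interaction_fdr = 0.1,
                             contrast_alpha = 0.05, genes = NULL) {
  stopifnot(length(panels) >= 1)
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(panels, function(p) p$genes)))
  }
  observed <- list(); permuted <- list()
  for (i in seq_along(genes)) {
    design <- build_stacked_design(panels, geno, genes[i])
    res <- map_gene(design, cfg, n_perm, policy, gene_index = i)
    observed[[i]] <- res$observed
    permuted[[i]] <- res$permuted
  }
  nulls <- pool_null(permuted)
  results <- eqtl_test(observed, nulls)
  sig <- results[results$q <= mapping_fdr, , drop = FALSE]
  rownames(sig) <- NULL
  if (nrow(sig) > 0 && length(panels) >= 2) {
    sig <- classify_static_conditional(sig, panels, geno,
                                       fdr_threshold = interaction_fdr,
                                       alpha = contrast_alpha)
  }
  list(results = results, significant = sig, nulls = nulls)
}

#' Run dynamic eQTL mapping over configured transitions
#'
#' One difference-trait mapping per (from, to) condition pair, each with
#' its own pooled null and its own BH family (sample sizes differ between
#' transitions).
#'
#' @param panels named list of `expression_panel` objects.
#' @param geno a `genotype_panel`.
#' @param transitions list of c(from, to) label pairs, e.g.
#'   `list(c("S","P"), c("P","E"), c("P","M"))`.
#' @param cfg a `forest_config`.
#' @param n_perm permutations per gene.
#' @param mapping_fdr FDR threshold for the `significant` subset.
#' @return list with `results` (all transitions stacked) and `significant`.
#' @export
run_dynamic <- function(panels, geno,
                        transitions = list(c("S", "P"), c("P", "E"),
                                           c("P", "M")),
                        cfg = forest_config(), n_perm = 10,
                        mapping_fdr = 0.1) {
  cond <- vapply(panels, function(p) p$condition, character(1))
  names(panels) <- cond
  parts <- lapply(transitions, function(tr) {
    if (!all(tr %in% cond)) {
      stop("transition ", tr[1], "->", tr[2], ": condition panel missing")
    }
    map_dynamic(panels[[tr[1]]], panels[[tr[2]]], geno, cfg, n_perm)
  })
  results <- do.call(rbind, parts)
  rownames(results) <- NULL
  sig <- results[results$q <= mapping_fdr, , drop = FALSE]
  rownames(sig) <- NULL
  list(results = results, significant = sig)
}

#' Summarize overlap between eQTL classes
#'
#' Pairs are matched on (gene_id, marker_id): "overlapping" means the same
#' locus-target link found by different analyses. Returns the counts
#' needed for a three-class Venn summary of static, conditional and
#' dynamic eQTL.
#'
#' @param significant classified simultaneous pairs (needs `class`).
#' @param dynamic_significant significant dynamic pairs.
#' @return data.frame with columns `set` and `n_pairs` covering each class
#'   and each intersection.
#' @export
summarize_overlap <- function(significant, dynamic_significant) {
  key <- function(df) if (nrow(df) == 0) character(0) else
    paste(df$gene_id, df$marker_id, sep = "\r")
  st <- key(significant[significant$class == "static", , drop = FALSE])
  co <- key(significant[significant$class == "conditional", , drop = FALSE])
  dy <- unique(key(dynamic_significant))
  data.frame(
    set = c("static", "conditional", "dynamic",
            "static&conditional", "static&dynamic", "conditional&dynamic",
            "static&conditional&dynamic"),
    n_pairs = c(length(st), length(co), length(dy),
                length(intersect(st, co)),
                length(intersect(st, dy)),
                length(intersect(co, dy)),
                length(intersect(intersect(st, co), dy))),
    stringsAsFactors = FALSE
  )
}

#' Write a results data.frame as headered TSV
#'
#' List columns are comma-joined; numeric formatting is left to R's
#' defaults so that identical runs produce byte-identical files.
#'
#' @param results data.frame.
#' @param path output path.
#' @export
write_results_tsv <- function(results, path) {
  out <- results
  for (j in seq_along(out)) {
    if (is.list(out[[j]])) {
      out[[j]] <- vapply(out[[j]], paste, character(1), collapse = ",")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
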