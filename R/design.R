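# Stacked (simultaneous) design construction.

#' Build the stacked multi-condition design for one gene
#'
#' Concatenates the gene's expression across all conditions into one trait
#' vector Y and builds the matching predictor matrix X: the genotype matrix
#' is replicated per condition (subset to the strains with expression in
#' that condition) and one 0/1 indicator column is appended per condition.
#' The indicators let a tree learner split samples by condition and then
#' pick markers predictive within a condition, which is what makes
#' conditional eQTL discoverable in a single mapping.
#'
#' Row order is conditions in the order of `panels`, strains in panel order
#' within a condition; X column order is markers in map order, then
#' indicators in condition order (named `ct_<condition>`).
#'
#' @param panels list of `expression_panel` objects (declared condition
#'   order).
#' @param geno a `genotype_panel`.
#' @param gene_id gene to stack.
#' @return an object of class `stacked_design` with elements `gene_id`, `Y`,
#'   `X`, `row_meta` (data.frame strain/condition), `marker_ids`,
#'   `conditions`.
#' @export
build_stacked_design <- function(panels, geno, gene_id) {
  stopifnot(inherits(geno, "genotype_panel"), length(panels) >= 1)
  conditions <- vapply(panels, function(p) p$condition, character(1))
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  have <- vapply(panels, function(p) gene_id %in% p$genes, logical(1))
  if (!any(have)) stop("gene absent from all panels: ", gene_id)

  y_parts <- list(); meta_parts <- list(); x_parts <- list()
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    if (!have[i]) next
    strains <- intersect(p$strains, geno$strains)
    if (length(strains) == 0) next
    y_parts[[i]] <- p$values[gene_id, strains]
    meta_parts[[i]] <- data.frame(strain = strains, condition = p$condition,
                                  stringsAsFactors = FALSE)
    x_parts[[i]] <- geno$calls[strains, , drop = FALSE]
  }
  Y <- unname(unlist(y_parts))
  row_meta <- do.call(rbind, meta_parts)
  rownames(row_meta) <- NULL
  G <- do.call(rbind, x_parts)
  ind <- matrix(0L, nrow(G), length(conditions),
                dimnames = list(NULL, indicator_name(conditions)))
  for (i in seq_along(conditions)) {
    ind[row_meta$condition == conditions[i], i] <- 1L
  }
  X <- cbind(G, ind)
  rownames(X) <- NULL
  structure(list(gene_id = gene_id, Y = Y, X = X, row_meta = row_meta,
                 marker_ids = colnames(geno$calls), conditions = conditions),
            class = "stacked_design")
}

#' Build a single-block design without condition indicators
#'
#' Used for difference-trait (dynamic) mapping, where there is only one
#' trait block and condition indicators would be constant.
#'
#' @param y numeric trait vector, one entry per strain.
#' @param strains strain ids aligned with `y`.
#' @param geno a `genotype_panel` containing all `strains`.
#' @param gene_id gene label carried through to results.
#' @param condition label recorded in `row_meta` (e.g. "P-M").
#' @return a `stacked_design` with zero indicator columns.
#' @export
build_trait_design <- function(y, strains, geno, gene_id, condition = "diff") {
  stopifnot(length(y) == length(strains), all(strains %in% geno$strains))
  X <- geno$calls[strains, , drop = FALSE]
  rownames(X) <- NULL
  structure(list(gene_id = gene_id, Y = unname(y), X = X,
                 row_meta = data.frame(strain = strains,
                                       condition = condition,
                                       stringsAsFactors = FALSE),
                 marker_ids = colnames(geno$calls), conditions = condition),
            class = "stacked_design")
}
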