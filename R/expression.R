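# Expression panels: construction, I/O, probe summarization, variance filter.

#' Construct an expression panel
#'
#' One panel per condition/cell type: a genes x strains matrix of
#' normalized, log2-scale expression values. Inputs are assumed already
#' normalized (e.g. log2 + quantile normalization upstream).
#'
#' @param values numeric matrix, genes x strains, finite; rownames are gene
#'   ids, colnames strain ids.
#' @param condition single condition label, e.g. "S", "P", "E", "M".
#' @return an object of class `expression_panel`.
#' @export
expression_panel <- function(values, condition) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)),
            is.character(condition), length(condition) == 1)
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  structure(
    list(condition = condition, genes = rownames(values),
         strains = colnames(values), values = values),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel '%s': %d genes x %d strains\n",
              x$condition, length(x$genes), length(x$strains)))
  invisible(x)
}

#' Read a per-condition expression table
#'
#' TSV dialect: first column is the gene (or probe) id, remaining columns
#' are strain ids.
#'
#' @param path TSV file path.
#' @param condition condition label for the panel.
#' @return an `expression_panel`.
#' @export
read_expression_table <- function(path, condition) {
  tab <- utils::read.delim(path, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  expression_panel(values, condition)
}

#' Write an expression panel as TSV
#'
#' @param panel an `expression_panel`.
#' @param path output path.
#' @export
write_expression_table <- function(panel, path) {
  out <- data.frame(gene_id = panel$genes, panel$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' TSV with columns `probe_id`, `gene_id`; each probe maps to exactly one
#' gene (many probes per gene allowed).
#'
#' @param path TSV file path.
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path) {
  map <- utils::read.delim(path, colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(map))) {
    stop("probe map must have columns probe_id, gene_id")
  }
  if (anyDuplicated(map$probe_id)) stop("probe mapped to more than one gene")
  map
}

#' Summarize probe-level expression to gene level by the median
#'
#' Each gene's expression profile is the per-strain median over all its
#' probes. Probes without a gene mapping are dropped (logged with a count).
#'
#' @param probe_values numeric matrix, probes x strains, rownames probe ids.
#' @param map data.frame with columns `probe_id`, `gene_id`.
#' @param condition condition label for the returned panel.
#' @return an `expression_panel` with one row per gene.
#' @export
median_summarize_probes <- function(probe_values, map, condition = "X") {
  stopifnot(is.matrix(probe_values), !is.null(rownames(probe_values)))
  gene <- map$gene_id[match(rownames(probe_values), map$probe_id)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    log_event("drop_probe", sum(unmapped), " probe(s) without gene mapping dropped")
    probe_values <- probe_values[!unmapped, , drop = FALSE]
    gene <- gene[!unmapped]
  }
  if (nrow(probe_values) == 0) stop("no mapped probes")
  genes <- unique(gene)
  values <- matrix(NA_real_, length(genes), ncol(probe_values),
                   dimnames = list(genes, colnames(probe_values)))
  for (g in genes) {
    rows <- probe_values[gene == g, , drop = FALSE]
    values[g, ] <- apply(rows, 2, stats::median)
  }
  expression_panel(values, condition)
}

#' Filter genes with low expression variance in every condition
#'
#' A gene is retained iff its per-condition sample standard deviation is at
#' least `sd_min` in at least one condition; the same gene set is removed
#' from every panel. A gene absent from a panel contributes no SD there;
#' a condition with fewer than 2 strains is skipped for the test (logged).
#'
#' @param panels list of `expression_panel` objects (shared gene universe,
#'   outer join allowed).
#' @param sd_min minimum sample (n-1 denominator) standard deviation.
#' @return list of filtered `expression_panel` objects.
#' @export
filter_low_variance_genes <- function(panels, sd_min = 0.1) {
  stopifnot(length(panels) >= 1)
  all_genes <- unique(unlist(lapply(panels, function(p) p$genes)))
  keep <- setNames(rep(FALSE, length(all_genes)), all_genes)
  for (p in panels) {
    if (length(p$strains) < 2) {
      log_event("skip_condition", "condition '", p$condition,
                "' has < 2 strains; SD undefined, skipped in variance filter")
      next
    }
    sds <- apply(p$values, 1, stats::sd)
    keep[p$genes] <- keep[p$genes] | sds >= sd_min
  }
  dropped <- sum(!keep)
  if (dropped > 0) {
    log_event("drop_gene", dropped, " gene(s) below SD ", sd_min,
              " in every condition")
  }
  lapply(panels, function(p) {
    sel <- keep[p$genes]
    expression_panel(p$values[sel, , drop = FALSE], p$condition)
  })
}
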