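# cis/trans annotation and eQTL-rich-region conditionality testing.

#' Read gene coordinates from a BED-like TSV
#'
#' Columns: chromosome, start, end, gene_id (header required); coordinates
#' are 1-based inclusive bp. Column order is free as long as the names
#' match (`start_bp`/`end_bp` accepted as aliases of `start`/`end`).
#'
#' @param path TSV file path.
#' @return data.frame with columns gene_id, chromosome, start_bp, end_bp.
#' @export
read_gene_loci <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  names(tab)[names(tab) == "start"] <- "start_bp"
  names(tab)[names(tab) == "end"] <- "end_bp"
  need <- c("gene_id", "chromosome", "start_bp", "end_bp")
  if (!all(need %in% names(tab))) {
    stop("gene loci table must have columns ", paste(need, collapse = ", "))
  }
  if (any(tab$start_bp > tab$end_bp)) stop("start_bp > end_bp in gene loci")
  tab[, need]
}

#' Annotate eQTL records as cis or trans
#'
#' A pair is cis iff the target gene's locus overlaps the marker interval
#' extended by `window_bp` on both sides, on the same chromosome;
#' otherwise trans. Genes without coordinates get NA (logged). The window
#' default of 1 Mb is a conventional cis distance for mouse crosses and is
#' deliberately exposed: published cis/trans fractions are sensitive to it.
#'
#' @param results data.frame with gene_id and marker_id columns.
#' @param loci data.frame from [read_gene_loci()].
#' @param markers marker map (`genotype_panel$markers`).
#' @param window_bp cis window in bp on either side of the marker interval.
#' @return `results` with an added `cis_trans` column ("cis"/"trans"/NA).
#' @export
classify_cis_trans <- function(results, loci, markers, window_bp = 1e6) {
  gi <- match(results$gene_id, loci$gene_id)
  mi <- match(results$marker_id, markers$marker_id)
  if (anyNA(mi)) stop("marker not in map: ",
                      results$marker_id[which(is.na(mi))[1]])
  lab <- rep(NA_character_, nrow(results))
  known <- !is.na(gi)
  if (any(!known)) {
    log_event("no_coordinates", sum(!known),
              " record(s) with unannotated genes; cis_trans = NA")
  }
  same_chr <- known &
    loci$chromosome[gi] == markers$chromosome[mi]
  lo <- markers$interval_start_bp[mi] - window_bp
  hi <- markers$interval_end_bp[mi] + window_bp
  overlap <- same_chr & loci$end_bp[gi] >= lo & loci$start_bp[gi] <= hi
  lab[known] <- ifelse(overlap[known], "cis", "trans")
  results$cis_trans <- lab
  results
}

#' Friedman rank test across conditions
#'
#' Nonparametric test for systematic differences between conditions over a
#' set of target pairs (blocks): each row of the matrix is ranked
#' (midranks for ties) and the tie-corrected Friedman statistic is
#' referred to a chi-square distribution with k-1 degrees of freedom.
#' Being rank-based, the test is invariant to monotone transforms within
#' rows, so it can be applied directly to contrast p-values. Rows with NA
#' are dropped (logged).
#'
#' @param mat numeric matrix, targets (blocks) x conditions (treatments);
#'   >= 3 complete rows and >= 2 columns required.
#' @return list with `statistic`, `df`, `p_value`, `n_blocks`.
#' @export
friedman_region_test <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  complete <- stats::complete.cases(mat)
  if (any(!complete)) {
    log_event("drop_block", sum(!complete),
              " row(s) with NA dropped from Friedman test")
    mat <- mat[complete, , drop = FALSE]
  }
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 3) stop("need >= 3 complete target rows for the Friedman test")
  r <- t(apply(mat, 1, rank))  # midranks for ties
  col_sums <- colSums(r)
  # tie-corrected statistic: 12 * sum (R_j - n(k+1)/2)^2 over
  # [n k (k+1) - (1/(k-1)) * sum_i sum_groups (t^3 - t)]
  tie_term <- sum(apply(r, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) {  # all rows completely tied
    return(list(statistic = 0, df = k - 1, p_value = 1, n_blocks = n))
  }
  stat <- 12 * sum((col_sums - n * (k + 1) / 2)^2) / denom
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
       n_blocks = n)
}

#' Find eQTL-rich markers
#'
#' Markers carrying at least `min_pairs` significant target pairs; the
#' qualitative "locus with many targets" notion made explicit.
#'
#' @param significant data.frame of significant pairs.
#' @param min_pairs minimum number of target pairs (default 20).
#' @return character vector of marker ids.
#' @export
find_rich_regions <- function(significant, min_pairs = 20) {
  counts <- table(significant$marker_id)
  names(counts)[counts >= min_pairs]
}

#' Test eQTL-rich regions for condition-biased contrast p-values
#'
#' For each rich marker, collects the per-condition Bonferroni-adjusted
#' contrast p-values of its target pairs into a targets x conditions
#' matrix and applies [friedman_region_test()]: a small p-value means the
#' locus's effect profile is systematically biased toward some conditions.
#'
#' @param classified data.frame from [classify_static_conditional()] (needs
#'   the `contrast_p_*` columns).
#' @param markers marker map (`genotype_panel$markers`).
#' @param region_markers marker ids to test, e.g. from
#'   [find_rich_regions()].
#' @return data.frame: marker_id, chromosome, start_bp, end_bp, n_targets,
#'   friedman_stat, friedman_p.
#' @export
analyze_regions <- function(classified, markers, region_markers) {
  pcols <- grep("^contrast_p_", names(classified), value = TRUE)
  if (length(pcols) < 2) stop("need contrast p-value columns for >= 2 conditions")
  if (length(region_markers) == 0) {
    return(data.frame(marker_id = character(0), chromosome = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_targets = integer(0), friedman_stat = numeric(0),
                      friedman_p = numeric(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(region_markers, function(m) {
    sub <- classified[classified$marker_id == m, pcols, drop = FALSE]
    mat <- as.matrix(sub)
    ft <- tryCatch(friedman_region_test(mat), error = function(e) NULL)
    mi <- match(m, markers$marker_id)
    data.frame(marker_id = m, chromosome = markers$chromosome[mi],
               start_bp = markers$interval_start_bp[mi],
               end_bp = markers$interval_end_bp[mi],
               n_targets = nrow(sub),
               friedman_stat = if (is.null(ft)) NA_real_ else ft$statistic,
               friedman_p = if (is.null(ft)) NA_real_ else ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
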