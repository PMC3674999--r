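# Genotype panels: construction, file I/O and marker merging.

#' Construct a genotype panel
#'
#' A genotype panel holds homozygous diallelic marker calls for a set of
#' inbred strains, together with genomic interval metadata per marker.
#' Calls are coded 0 (the "B" allele of a B-by-D cross) and 1 (the "D"
#' allele); this 0/1 coding matches the split semantics of tree learners.
#'
#' @param calls integer/numeric matrix, strains x markers, values in {0, 1};
#'   rownames are strain ids, colnames marker ids.
#' @param markers data.frame with columns `marker_id`, `chromosome`,
#'   `interval_start_bp`, `interval_end_bp`, `member_ids` (list column of
#'   character vectors naming the original markers merged into each row).
#'   Intervals are 1-based inclusive base pairs.
#' @return an object of class `genotype_panel` with elements `strains`,
#'   `markers` and `calls`.
#' @export
genotype_panel <- function(calls, markers) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)), !is.null(colnames(calls)))
  if (!all(calls %in% c(0, 1))) {
    stop("genotype calls must be 0 or 1 (homozygous diallelic)")
  }
  required <- c("marker_id", "chromosome", "interval_start_bp", "interval_end_bp")
  if (!all(required %in% names(markers))) {
    stop("markers must have columns ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(markers$marker_id)) stop("duplicate marker ids")
  if (!identical(colnames(calls), as.character(markers$marker_id))) {
    stop("colnames(calls) must equal markers$marker_id in order")
  }
  if (any(markers$interval_start_bp > markers$interval_end_bp)) {
    stop("marker interval_start_bp must be <= interval_end_bp")
  }
  if (is.null(markers$member_ids)) {
    markers$member_ids <- as.list(as.character(markers$marker_id))
  }
  structure(
    list(strains = rownames(calls), markers = markers, calls = calls),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d strains x %d markers on %d chromosome(s)\n",
    length(x$strains), nrow(x$markers), length(unique(x$markers$chromosome))
  ))
  invisible(x)
}

#' Read a GeneNetwork-style genotype table
#'
#' Expected dialect: a header line with columns `Chr`, `Locus`, `Position`
#' followed by one column per strain; calls are single allele symbols
#' (default `B`/`D`, plus `H` for heterozygous and `U` for unknown).
#' Comment lines starting with `#` or `@` are skipped. Positions may be in
#' base pairs or megabases (`position_unit`); they are stored as 1-based
#' inclusive bp intervals (point markers get start == end).
#'
#' Heterozygous or unknown calls are incompatible with the homozygous 0/1
#' coding. With `policy = "reject"` (default) the reader stops and names the
#' offending cell; with `policy = "drop"` every marker containing such a
#' call is dropped (logged), keeping the call matrix complete without
#' imputation.
#'
#' Non-monotone positions within a chromosome trigger a warning and a
#' stable re-sort by (chromosome, position).
#'
#' @param path TSV file path.
#' @param alleles length-2 character vector: symbols coded as 0 and 1.
#' @param het,unknown symbols treated as heterozygous / missing.
#' @param policy `"reject"` or `"drop"` for het/unknown calls.
#' @param position_unit `"bp"` or `"Mb"`.
#' @return a `genotype_panel`.
#' @export
read_genotype_table <- function(path, alleles = c("B", "D"), het = "H",
                                unknown = "U", policy = c("reject", "drop"),
                                position_unit = c("bp", "Mb")) {
  policy <- match.arg(policy)
  position_unit <- match.arg(position_unit)
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  required <- c("Chr", "Locus", "Position")
  if (!all(required %in% names(tab))) {
    stop("genotype table must have columns Chr, Locus, Position")
  }
  strain_cols <- setdiff(names(tab), required)
  if (length(strain_cols) == 0) stop("no strain columns found")
  if (anyDuplicated(tab$Locus)) {
    stop("duplicate marker id: ", tab$Locus[duplicated(tab$Locus)][1])
  }
  pos <- as.numeric(tab$Position)
  if (anyNA(pos)) stop("non-numeric Position values")
  if (position_unit == "Mb") pos <- pos * 1e6
  pos <- as.integer(round(pos))

  raw <- as.matrix(tab[, strain_cols, drop = FALSE])
  bad <- !(raw %in% c(alleles, het, unknown))
  dim(bad) <- dim(raw)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown allele symbol '%s' at marker '%s', strain '%s'",
                 raw[idx[1], idx[2]], tab$Locus[idx[1]], strain_cols[idx[2]]))
  }
  hu <- raw %in% c(het, unknown)
  dim(hu) <- dim(raw)
  if (any(hu)) {
    if (policy == "reject") {
      idx <- which(hu, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "heterozygous/unknown call '%s' at marker '%s', strain '%s' (policy = reject)",
        raw[idx[1], idx[2]], tab$Locus[idx[1]], strain_cols[idx[2]]))
    }
    drop_rows <- rowSums(hu) > 0
    log_event("drop_marker", sum(drop_rows),
              " marker(s) dropped for heterozygous/unknown calls")
    tab <- tab[!drop_rows, , drop = FALSE]
    raw <- raw[!drop_rows, , drop = FALSE]
    pos <- pos[!drop_rows]
  }

  markers <- data.frame(
    marker_id = tab$Locus, chromosome = tab$Chr,
    interval_start_bp = pos, interval_end_bp = pos,
    stringsAsFactors = FALSE
  )
  # stable sort by (chromosome in order of first appearance, position)
  chr_order <- match(markers$chromosome, unique(markers$chromosome))
  ord <- order(chr_order, markers$interval_start_bp)
  if (!identical(ord, seq_len(nrow(markers)))) {
    warning("non-monotone marker positions within a chromosome; re-sorting")
    markers <- markers[ord, , drop = FALSE]
    raw <- raw[ord, , drop = FALSE]
    rownames(markers) <- NULL
  }
  calls <- t(matrix(as.integer(raw == alleles[2]), nrow = nrow(raw)))
  dimnames(calls) <- list(strain_cols, markers$marker_id)
  markers$member_ids <- as.list(markers$marker_id)
  genotype_panel(calls, markers)
}

#' Write a genotype panel in the GeneNetwork-style dialect
#'
#' Merged markers are written with their representative id and interval
#' start position; `read_genotype_table` round-trips unmerged panels.
#'
#' @param panel a `genotype_panel`.
#' @param path output TSV path.
#' @param alleles symbols written for codes 0 and 1.
#' @export
write_genotype_table <- function(panel, path, alleles = c("B", "D")) {
  sym <- matrix(alleles[panel$calls + 1L], nrow = nrow(panel$calls))
  out <- data.frame(
    Chr = panel$markers$chromosome,
    Locus = panel$markers$marker_id,
    Position = panel$markers$interval_start_bp,
    t(sym),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out)[-(1:3)] <- panel$strains
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge adjacent markers with identical genotype profiles
#'
#' With a small strain panel, neighboring markers often carry identical
#' call columns and cannot be distinguished by any association analysis.
#' Maximal runs of adjacent same-chromosome markers with identical calls
#' across all strains are collapsed into one marker whose interval spans
#' the run (`[min start, max end]`); `member_ids` records the constituents
#' and the run's first marker id is kept as the representative id. The
#' operation is idempotent.
#'
#' @param panel a `genotype_panel` sorted by chromosome and position.
#' @return a `genotype_panel` with merged markers.
#' @export
merge_identical_markers <- function(panel) {
  m <- nrow(panel$markers)
  if (m <= 1) return(panel)
  same <- logical(m)
  for (j in 2:m) {
    same[j] <- panel$markers$chromosome[j] == panel$markers$chromosome[j - 1] &&
      all(panel$calls[, j] == panel$calls[, j - 1])
  }
  run_id <- cumsum(!same)
  keep <- which(!same)
  markers <- panel$markers[keep, , drop = FALSE]
  rownames(markers) <- NULL
  member_groups <- split(panel$markers$marker_id, run_id)
  markers$member_ids <- unname(lapply(
    member_groups[as.character(seq_along(keep))],
    function(ids) unname(unlist(panel$markers$member_ids[
      match(ids, panel$markers$marker_id)]))))
  grp <- split(seq_len(m), run_id)
  markers$interval_start_bp <- vapply(grp, function(i)
    min(panel$markers$interval_start_bp[i]), numeric(1))
  markers$interval_end_bp <- vapply(grp, function(i)
    max(panel$markers$interval_end_bp[i]), numeric(1))
  calls <- panel$calls[, keep, drop = FALSE]
  colnames(calls) <- markers$marker_id
  genotype_panel(calls, markers)
}
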