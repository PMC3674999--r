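# Minimal eQTL-map visualization.

#' eQTL map scatter: marker position vs target gene position
#'
#' Each significant pair is drawn at (marker genome position, gene genome
#' position), with genome coordinates obtained by laying chromosomes end
#' to end. cis bands appear on the diagonal; vertical stripes are
#' trans-acting hotspots. Points are colored by class when a `class`
#' column is present.
#'
#' @param significant data.frame with gene_id and marker_id.
#' @param markers marker map (`genotype_panel$markers`).
#' @param loci gene coordinates as from [read_gene_loci()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data.frame.
#' @export
plot_eqtl_map <- function(significant, markers, loci, ...) {
  chroms <- unique(c(markers$chromosome, loci$chromosome))
  chr_len <- vapply(chroms, function(ch) {
    max(c(markers$interval_end_bp[markers$chromosome == ch],
          loci$end_bp[loci$chromosome == ch], 0))
  }, numeric(1))
  offset <- setNames(cumsum(c(0, chr_len[-length(chr_len)])), chroms)
  mi <- match(significant$marker_id, markers$marker_id)
  gi <- match(significant$gene_id, loci$gene_id)
  x <- offset[markers$chromosome[mi]] + markers$interval_start_bp[mi]
  y <- offset[loci$chromosome[gi]] + loci$start_bp[gi]
  keep <- !is.na(x) & !is.na(y)
  cls <- if ("class" %in% names(significant)) significant$class else
    rep("eQTL", nrow(significant))
  col <- c(static = "grey30", conditional = "firebrick",
           dynamic = "dodgerblue", eQTL = "grey30")[cls]
  graphics::plot(x[keep], y[keep], col = col[keep], pch = 19, cex = 0.6,
                 xlab = "eQTL position (genome, bp)",
                 ylab = "target gene position (genome, bp)", ...)
  graphics::abline(v = cumsum(chr_len), h = cumsum(chr_len),
                   col = "grey85", lty = 3)
  invisible(data.frame(x = x, y = y, class = cls)[keep, ])
}
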