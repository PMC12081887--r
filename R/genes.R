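#' Build gene models from a TSV table
#'
#' Expects columns `gene`, `chrom`, `start`, `end`, `strand` (0-based
#' half-open). The TSS is `start` for `+` genes and `end - 1` for `-` genes.
#'
#' @param x data.frame or path to a TSV with a header row.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
gene_models <- function(x) {
  if (is.character(x)) x <- utils::read.table(x, header = TRUE, sep = "\t",
                                              stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in% names(x)))
  if (!all(x$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  x$tss <- ifelse(x$strand == "+", x$start, x$end - 1)
  x
}

#' Promoter intervals for gene models
#'
#' The promoter is the TSS plus a symmetric flank (default +/- 2 kb),
#' clipped at position 0.
#'
#' @param genes Output of [gene_models()].
#' @param flank_bp Flank on each side of the TSS in bp.
#' @return Interval data.frame (`chrom,start,end,name,score,strand`).
#' @export
promoters <- function(genes, flank_bp = 2000) {
  data.frame(chrom = genes$chrom,
             start = pmax(0, genes$tss - flank_bp),
             end = genes$tss + flank_bp + 1,
             name = genes$gene, score = NA_real_, strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Promoter bin index per gene
#'
#' The bin containing the TSS at the working resolution.
#'
#' @param genes Output of [gene_models()].
#' @param bt A [bin_table()].
#' @return Integer vector of 0-based bins, `NA` for other chromosomes.
#' @export
promoter_bins <- function(genes, bt) {
  out <- rep(NA_integer_, nrow(genes))
  on_chrom <- genes$chrom == bt$chrom & genes$tss >= 0 &
    genes$tss < bt$chrom_length
  out[on_chrom] <- bin_index(bt, genes$tss[on_chrom])
  out
}

#' Expression table container
#'
#' Wraps a genes x samples FPKM matrix with per-sample metadata.
#'
#' @param fpkm Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param samples data.frame with rownames (or column `sample`) matching
#'   `colnames(fpkm)` and columns `region` and `stage` (ordered factor or
#'   sortable labels).
#' @return Object of class `expression_table`.
#' @export
expression_table <- function(fpkm, samples) {
  stopifnot(is.matrix(fpkm), all(fpkm >= 0, na.rm = TRUE))
  if (!is.null(samples$sample)) rownames(samples) <- samples$sample
  stopifnot(all(colnames(fpkm) %in% rownames(samples)),
            all(c("region", "stage") %in% names(samples)))
  samples <- samples[colnames(fpkm), , drop = FALSE]
  structure(list(fpkm = fpkm, samples = samples), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d samples (%d stages, %d regions)\n",
              nrow(x$fpkm), ncol(x$fpkm),
              length(unique(x$samples$stage)),
              length(unique(x$samples$region))))
  invisible(x)
}

#' Per-gene mean FPKM by stage
#' @param et An [expression_table()].
#' @return genes x stages matrix of mean FPKM, stages in sorted order.
#' @export
stage_means <- function(et) {
  stages <- sort(unique(et$samples$stage))
  out <- sapply(stages, function(s)
    rowMeans(et$fpkm[, et$samples$stage == s, drop = FALSE]))
  colnames(out) <- as.character(stages)
  out
}
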