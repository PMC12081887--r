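#' Fixed-width genomic bin table
#'
#' A `bin_table` tiles one chromosome with fixed-width bins in 0-based
#' half-open coordinates. The last bin may be shorter than `resolution`.
#' Bin indices are 0-based so that `bin_index(pos) == floor(pos / resolution)`.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param resolution Bin width in bp.
#' @return An object of class `bin_table` with fields `chrom`, `chrom_length`,
#'   `resolution`, `n_bins`, `start`, `end` (per-bin coordinate vectors).
#' @examples
#' bt <- bin_table("chrS", 1e6, 4e4)
#' bt$n_bins
#' @export
bin_table <- function(chrom, chrom_length, resolution) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            chrom_length > 0, resolution > 0)
  chrom_length <- as.numeric(chrom_length)
  resolution <- as.numeric(resolution)
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  start <- (seq_len(n_bins) - 1L) * resolution
  end <- pmin(start + resolution, chrom_length)
  structure(
    list(chrom = chrom, chrom_length = chrom_length,
         resolution = resolution, n_bins = n_bins,
         start = start, end = end),
    class = "bin_table")
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("<bin_table> %s: %s bp, %d bins at %s bp\n",
              x$chrom, format(x$chrom_length, big.mark = ","),
              x$n_bins, format(x$resolution, big.mark = ",")))
  invisible(x)
}

#' Map genomic positions to bin indices
#'
#' @param bt A [bin_table()].
#' @param pos Positions in bp (0-based).
#' @return 0-based bin indices, `floor(pos / resolution)`.
#' @export
bin_index <- function(bt, pos) {
  stopifnot(inherits(bt, "bin_table"))
  if (any(pos < 0 | pos >= bt$chrom_length))
    stop("position outside chromosome [0, ", bt$chrom_length, ")")
  as.integer(floor(pos / bt$resolution))
}

#' Bin intervals of a bin table as a data frame
#'
#' @param bt A [bin_table()].
#' @return data.frame with columns `chrom`, `start`, `end`, `bin` (0-based).
#' @export
bins_as_intervals <- function(bt) {
  data.frame(chrom = bt$chrom, start = bt$start, end = bt$end,
             bin = seq_len(bt$n_bins) - 1L)
}
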