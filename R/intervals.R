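#' Read genomic intervals from BED or anchor pairs from BEDPE
#'
#' Coordinates are kept 0-based half-open (BED native). Records with
#' `start >= end` are rejected with a warning.
#'
#' @param path Path to a BED3+/BED6 or BEDPE file.
#' @param format `"BED"` or `"BEDPE"`.
#' @return For BED: a data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand` (an interval set). For BEDPE: a data.frame
#'   with `chrom1,start1,end1,chrom2,start2,end2,name,score`.
#' @export
read_intervals <- function(path, format = c("BED", "BEDPE")) {
  format <- match.arg(format)
  dat <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(dat) || nrow(dat) == 0L) {
    return(if (format == "BED") empty_intervals() else empty_bedpe())
  }
  if (format == "BED") {
    if (ncol(dat) < 3L) stop("BED needs >= 3 columns")
    out <- data.frame(
      chrom = as.character(dat[[1]]),
      start = as.numeric(dat[[2]]),
      end = as.numeric(dat[[3]]),
      name = if (ncol(dat) >= 4) as.character(dat[[4]]) else ".",
      score = if (ncol(dat) >= 5) suppressWarnings(as.numeric(dat[[5]])) else NA_real_,
      strand = if (ncol(dat) >= 6) as.character(dat[[6]]) else ".",
      stringsAsFactors = FALSE)
    bad <- out$start >= out$end
    if (any(bad)) {
      warning(sum(bad), " record(s) with start >= end rejected")
      out <- out[!bad, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
  } else {
    if (ncol(dat) < 6L) stop("BEDPE needs >= 6 columns")
    out <- data.frame(
      chrom1 = as.character(dat[[1]]), start1 = as.numeric(dat[[2]]),
      end1 = as.numeric(dat[[3]]),
      chrom2 = as.character(dat[[4]]), start2 = as.numeric(dat[[5]]),
      end2 = as.numeric(dat[[6]]),
      name = if (ncol(dat) >= 7) as.character(dat[[7]]) else ".",
      score = if (ncol(dat) >= 8) suppressWarnings(as.numeric(dat[[8]])) else NA_real_,
      stringsAsFactors = FALSE)
    bad <- out$start1 >= out$end1 | out$start2 >= out$end2
    if (any(bad)) {
      warning(sum(bad), " record(s) with start >= end rejected")
      out <- out[!bad, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
  }
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

empty_bedpe <- function() {
  data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
             chrom2 = character(), start2 = numeric(), end2 = numeric(),
             name = character(), score = numeric(), stringsAsFactors = FALSE)
}

#' Write an interval set as BED6
#' @param x Interval data.frame (`chrom,start,end[,name,score,strand]`).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(
    chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0,
    strand = if ("strand" %in% names(x)) x$strand else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Aggregate intervals or point values into a binned signal track
#'
#' `count` counts overlapping records per bin (presence in a bin counts once
#' per record); `sum` distributes each record's score over the bins it
#' overlaps, weighted by overlap fraction; `mean` divides the summed score by
#' the number of contributing records per bin. Bins with no record are `NA`
#' when `missing_as_na` (explicit missing), else 0.
#'
#' @param x Interval data.frame (`chrom,start,end[,score]`). Point features
#'   (e.g. TSS) are represented as 1-bp intervals `[p, p+1)`.
#' @param bt A [bin_table()].
#' @param reducer `"count"`, `"sum"` or `"mean"`.
#' @param missing_as_na Encode empty bins as `NA` (default `FALSE`: zeros).
#' @return Numeric per-bin vector of length `bt$n_bins` (a signal track).
#' @export
bin_signal <- function(x, bt, reducer = c("count", "sum", "mean"),
                       missing_as_na = FALSE) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(bt, "bin_table"))
  x <- x[x$chrom == bt$chrom, , drop = FALSE]
  n <- bt$n_bins
  track <- numeric(n)
  hits <- numeric(n)
  if (nrow(x)) {
    score <- if ("score" %in% names(x) && !all(is.na(x$score)))
      ifelse(is.na(x$score), 0, x$score) else (x$end - x$start)
    for (r in seq_len(nrow(x))) {
      s <- max(0, x$start[r]); e <- min(bt$chrom_length, x$end[r])
      if (s >= e) next
      b0 <- bin_index(bt, s)
      b1 <- bin_index(bt, e - 1)
      for (b in b0:b1) {
        ov <- min(e, bt$end[b + 1L]) - max(s, bt$start[b + 1L])
        frac <- ov / (e - s)
        track[b + 1L] <- track[b + 1L] +
          switch(reducer, count = 1, sum = score[r] * frac, mean = score[r] * frac)
        hits[b + 1L] <- hits[b + 1L] + 1
      }
    }
  }
  if (reducer == "mean") track <- ifelse(hits > 0, track / hits, 0)
  if (missing_as_na) track[hits == 0] <- NA_real_
  track
}

#' Write a per-bin track as bedGraph
#' @param track Numeric per-bin vector.
#' @param bt A [bin_table()].
#' @param path Output path. `NA` bins are skipped.
#' @export
write_bedgraph <- function(track, bt, path) {
  stopifnot(length(track) == bt$n_bins)
  keep <- !is.na(track)
  out <- data.frame(chrom = bt$chrom,
                    start = format(bt$start[keep], scientific = FALSE, trim = TRUE),
                    end = format(bt$end[keep], scientific = FALSE, trim = TRUE),
                    value = track[keep])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph into a per-bin track
#' @param path bedGraph path.
#' @param bt A [bin_table()]; records must align to its bins.
#' @param missing_as_na Bins absent from the file become `NA` (default) or 0.
#' @return Numeric per-bin vector.
#' @export
read_bedgraph <- function(path, bt, missing_as_na = TRUE) {
  dat <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  track <- rep(if (missing_as_na) NA_real_ else 0, bt$n_bins)
  dat <- dat[dat[[1]] == bt$chrom, , drop = FALSE]
  if (nrow(dat)) {
    b <- bin_index(bt, as.numeric(dat[[2]]))
    track[b + 1L] <- as.numeric(dat[[4]])
  }
  track
}

#' Reciprocal overlap fraction between two intervals
#'
#' @param s1,e1,s2,e2 Interval coordinates (vectors recycle).
#' @return `min(overlap/len1, overlap/len2)`, 0 when disjoint.
#' @export
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}
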