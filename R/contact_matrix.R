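#' Sparse symmetric Hi-C contact matrix
#'
#' Stores one chromosome's binned contacts as upper-triangle triples
#' `(i, j, value)` with `i <= j` (0-based bin indices). Lower-triangle input
#' is folded onto the upper triangle and duplicate pixels are summed, so the
#' matrix is symmetric by construction. Bins can be masked (excluded from all
#' computation); balancing weights are attached by [ice_balance()].
#'
#' Absent pixels between unmasked bins are implicit zeros: the matrix is a
#' complete symmetric array stored sparsely, not a list of observations.
#'
#' @param bt A [bin_table()].
#' @param i,j 0-based bin indices (any order; folded to `i <= j`).
#' @param value Contact values; must be `>= 0` in raw/balanced state.
#' @param state One of `"raw"`, `"balanced"`, `"oe"`.
#' @param mask Logical per-bin vector, `TRUE` = bin is valid. Default all valid.
#' @param weights Per-bin balancing weights (bias estimates), or `NULL`.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(bt, i, j, value, state = "raw",
                           mask = NULL, weights = NULL) {
  stopifnot(inherits(bt, "bin_table"),
            length(i) == length(j), length(j) == length(value))
  state <- match.arg(state, c("raw", "balanced", "oe"))
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) && (min(i, j) < 0L || max(i, j) >= bt$n_bins))
    stop("bin index out of range for bin table with ", bt$n_bins, " bins")
  if (state != "oe" && length(value) && any(value < 0, na.rm = TRUE))
    stop("negative contact value in ", state, " matrix")
  # fold to upper triangle, then sum duplicates
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  if (length(i)) {
    key <- i * as.numeric(bt$n_bins) + j
    if (anyDuplicated(key)) {
      value <- as.numeric(rowsum(value, key, reorder = TRUE))
      ui <- !duplicated(key)
      ord <- order(key[ui])
      i <- (i[ui])[ord]; j <- (j[ui])[ord]
    } else {
      ord <- order(key)
      i <- i[ord]; j <- j[ord]; value <- value[ord]
    }
  }
  if (is.null(mask)) mask <- rep(TRUE, bt$n_bins)
  stopifnot(length(mask) == bt$n_bins)
  structure(
    list(bin_table = bt, i = i, j = j, value = as.numeric(value),
         mask = mask, weights = weights, state = state),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins (%d masked), %d stored pixels, state=%s\n",
              x$bin_table$chrom, x$bin_table$n_bins, sum(!x$mask),
              length(x$i), x$state))
  invisible(x)
}

#' Read a contact matrix from a sparse triple file
#'
#' The canonical interchange format is a 3-column whitespace-separated text
#' file `bin_i bin_j count` (0-based indices). Lines starting with `#` and an
#' optional header row are skipped. Lower-triangle entries are folded and
#' duplicates summed.
#'
#' @param path Path to the triple file.
#' @param bt The [bin_table()] the indices refer to.
#' @return A raw-state [contact_matrix()].
#' @export
read_contact_matrix <- function(path, bt) {
  dat <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(dat) < 3L) stop("triple file needs 3 columns: i, j, count")
  # tolerate a header row
  if (nrow(dat) && is.na(suppressWarnings(as.numeric(dat[1, 1]))))
    dat <- dat[-1, , drop = FALSE]
  i <- suppressWarnings(as.numeric(dat[[1]]))
  j <- suppressWarnings(as.numeric(dat[[2]]))
  v <- suppressWarnings(as.numeric(dat[[3]]))
  if (anyNA(i) || anyNA(j) || anyNA(v))
    stop("non-numeric entries in triple file ", path)
  if (any(i != floor(i)) || any(j != floor(j)))
    stop("non-integer bin indices in ", path)
  if (any(v < 0)) stop("negative count in ", path)
  if (length(i) && (min(i, j) < 0 || max(i, j) >= bt$n_bins))
    stop("bin index out of range in ", path)
  contact_matrix(bt, i, j, v, state = "raw")
}

#' Write a contact matrix as sparse triples
#'
#' @param cm A [contact_matrix()].
#' @param path Output path.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  utils::write.table(data.frame(i = cm$i, j = cm$j, value = cm$value),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Dense symmetric view of a contact matrix
#'
#' Implicit zeros are materialized; rows/columns of masked bins are `NA`.
#'
#' @param cm A [contact_matrix()].
#' @return A dense `n_bins x n_bins` symmetric matrix.
#' @export
cm_dense <- function(cm) {
  n <- cm$bin_table$n_bins
  m <- matrix(0, n, n)
  idx1 <- cbind(cm$i + 1L, cm$j + 1L)
  m[idx1] <- cm$value
  m[idx1[, c(2, 1), drop = FALSE]] <- cm$value
  m[!cm$mask, ] <- NA_real_
  m[, !cm$mask] <- NA_real_
  m
}

#' Extract a square on-diagonal window as a dense matrix
#'
#' @param cm A [contact_matrix()].
#' @param from_bin,to_bin Inclusive 0-based bin range.
#' @return Dense symmetric submatrix with `NA` at masked bins.
#' @export
cm_window <- function(cm, from_bin, to_bin) {
  n <- cm$bin_table$n_bins
  stopifnot(from_bin >= 0, to_bin < n, from_bin <= to_bin)
  keep <- cm$i >= from_bin & cm$i <= to_bin & cm$j >= from_bin & cm$j <= to_bin
  w <- to_bin - from_bin + 1L
  m <- matrix(0, w, w)
  ii <- cm$i[keep] - from_bin + 1L
  jj <- cm$j[keep] - from_bin + 1L
  m[cbind(ii, jj)] <- cm$value[keep]
  m[cbind(jj, ii)] <- cm$value[keep]
  bad <- which(!cm$mask[(from_bin:to_bin) + 1L])
  if (length(bad)) { m[bad, ] <- NA_real_; m[, bad] <- NA_real_ }
  m
}

#' Per-bin marginal totals
#'
#' Row sums of the symmetric matrix: off-diagonal pixels contribute to both
#' bins, the diagonal once. Masked bins get `NA`.
#'
#' @param cm A [contact_matrix()].
#' @return Numeric vector of length `n_bins`.
#' @export
cm_marginals <- function(cm) {
  n <- cm$bin_table$n_bins
  s <- numeric(n)
  if (length(cm$i)) {
    off <- cm$i != cm$j
    s <- s + tabulate2(cm$i + 1L, cm$value, n)
    s <- s + tabulate2(cm$j[off] + 1L, cm$value[off], n)
  }
  s[!cm$mask] <- NA_real_
  s
}

# weighted tabulate: sum of w by integer bin 1..n
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Total symmetric-matrix mass (off-diagonals counted twice)
#' @param cm A [contact_matrix()].
#' @return Scalar total.
#' @export
cm_total <- function(cm) {
  keep <- cm$mask[cm$i + 1L] & cm$mask[cm$j + 1L]
  sum(cm$value[keep] * ifelse(cm$i[keep] == cm$j[keep], 1, 2))
}
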