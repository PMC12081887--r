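#' Mask bins with zero or low marginal counts
#'
#' Bins whose marginal total is zero, or below the `min_quantile` quantile of
#' the nonzero marginals, are masked; stored pixels touching a masked bin are
#' dropped. Low-count rows and columns in raw Hi-C matrices are dominated by
#' repetitive or unmappable sequence and would destabilize balancing.
#'
#' @param cm Raw-state [contact_matrix()].
#' @param min_quantile Quantile of nonzero marginals below which bins are
#'   masked (default 0.02).
#' @return The matrix with an updated mask.
#' @export
mask_low_coverage <- function(cm, min_quantile = 0.02) {
  stopifnot(inherits(cm, "contact_matrix"), cm$state == "raw")
  marg <- cm_marginals(cm)
  marg[is.na(marg)] <- 0
  nz <- marg[marg > 0]
  thr <- if (length(nz) && min_quantile > 0)
    stats::quantile(nz, min_quantile, names = FALSE) else 0
  mask <- cm$mask & marg > 0 & marg >= thr
  if (!any(mask)) stop("all bins masked at min_quantile = ", min_quantile)
  keep <- mask[cm$i + 1L] & mask[cm$j + 1L]
  contact_matrix(cm$bin_table, cm$i[keep], cm$j[keep], cm$value[keep],
                 state = "raw", mask = mask)
}

#' ICE matrix balancing (iterative correction)
#'
#' Symmetric iterative correction on the sparse upper-triangle
#' representation: per-bin multiplicative biases are estimated so that the
#' marginals of the corrected matrix are equal over unmasked bins
#' (coefficient of variation below `tol`). The returned weights are the bias
#' estimates, normalized to mean 1 over unmasked bins; the balanced value is
#' `raw_ij / (w_i * w_j)`.
#'
#' @param cm Masked raw-state [contact_matrix()].
#' @param tol Convergence tolerance on the marginal CV (default 1e-5).
#' @param max_iter Maximum iterations (default 200).
#' @return Balanced-state [contact_matrix()] with `weights`.
#' @export
ice_balance <- function(cm, tol = 1e-5, max_iter = 200) {
  stopifnot(inherits(cm, "contact_matrix"), cm$state == "raw")
  un <- which(cm$mask)
  if (!length(un)) stop("no unmasked bins to balance")
  n <- cm$bin_table$n_bins
  v <- cm$value
  b <- rep(1, n)
  cur <- cm
  cv <- Inf
  for (it in seq_len(max_iter)) {
    marg <- cm_marginals(cur)
    m_un <- marg[un]
    mu <- mean(m_un)
    if (mu == 0) stop("zero total counts on unmasked bins")
    cv <- stats::sd(m_un) / mu
    if (cv < tol) break
    s <- rep(1, n)
    s[un] <- m_un / mu
    s[s == 0] <- 1
    v <- v / (s[cur$i + 1L] * s[cur$j + 1L])
    b <- b * s
    cur <- contact_matrix(cm$bin_table, cm$i, cm$j, v,
                          state = "raw", mask = cm$mask)
  }
  if (cv >= tol)
    stop(sprintf("ICE did not converge in %d iterations (marginal CV = %.3g)",
                 max_iter, cv))
  # normalize weights to mean 1 over unmasked bins; rescale matrix to match
  scale <- mean(b[un])
  b <- b / scale
  v <- cm$value / (b[cm$i + 1L] * b[cm$j + 1L])
  b[-un] <- NA_real_
  out <- contact_matrix(cm$bin_table, cm$i, cm$j, v,
                        state = "balanced", mask = cm$mask)
  out$weights <- b
  out
}

#' Expected contact value per genomic distance
#'
#' `expected(d)` is the mean over all unmasked pixel positions at bin
#' distance `d`, counting absent (implicitly zero) pixels between unmasked
#' bins as zeros. Distances with no unmasked pixel position are `NA`.
#'
#' @param cm Balanced (or raw) [contact_matrix()].
#' @return Numeric vector of length `n_bins`; element `d + 1` is expected(d).
#' @export
expected_by_distance <- function(cm) {
  n <- cm$bin_table$n_bins
  un <- cm$mask
  # denominators: number of unmasked (i, i+d) positions per distance
  denom <- numeric(n)
  pos <- which(un) - 1L
  for (d in 0:(n - 1L)) {
    if (length(pos) == 0) break
    ok <- pos + d <= n - 1L
    if (!any(ok)) break
    denom[d + 1L] <- sum(un[pos[ok] + d + 1L])
  }
  keep <- un[cm$i + 1L] & un[cm$j + 1L]
  d <- cm$j[keep] - cm$i[keep]
  sums <- numeric(n)
  if (length(d)) sums <- tabulate2(d + 1L, cm$value[keep], n)
  out <- ifelse(denom > 0, sums / denom, NA_real_)
  out
}

#' Observed-over-expected normalization
#'
#' Divides every pixel by the expected value at its distance, removing the
#' distance decay. Pixels at distances with zero or undefined expected value
#' are dropped (missing).
#'
#' @param cm Balanced [contact_matrix()].
#' @param expected Optional precomputed [expected_by_distance()] vector.
#' @return O/E-state [contact_matrix()].
#' @export
observed_over_expected <- function(cm, expected = NULL) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (is.null(expected)) expected <- expected_by_distance(cm)
  e <- expected[cm$j - cm$i + 1L]
  ok <- !is.na(e) & e > 0
  out <- contact_matrix(cm$bin_table, cm$i[ok], cm$j[ok], cm$value[ok] / e[ok],
                        state = "oe", mask = cm$mask)
  out$weights <- cm$weights
  out$expected <- expected
  out
}

#' Pearson correlation matrix of O/E rows
#'
#' The plaid compartment pattern appears as a checkerboard of positive and
#' negative correlations between bin rows of the O/E matrix.
#'
#' @param cm_oe O/E-state [contact_matrix()].
#' @return Dense `n x n` correlation matrix; masked bins are `NA`; the
#'   diagonal of unmasked bins is 1.
#' @export
correlation_matrix <- function(cm_oe) {
  stopifnot(inherits(cm_oe, "contact_matrix"), cm_oe$state == "oe")
  dm <- cm_dense(cm_oe)
  un <- which(cm_oe$mask)
  cc <- matrix(NA_real_, nrow(dm), ncol(dm))
  if (length(un) >= 3) {
    sub <- dm[un, un, drop = FALSE]
    cs <- suppressWarnings(stats::cor(t(sub)))
    cs[is.na(cs)] <- 0
    diag(cs) <- 1
    cc[un, un] <- cs
  }
  cc
}
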