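#' Structural similarity (SSIM) between two equal-size matrices
#'
#' `S = l^alpha * c^beta * s^gamma` with brightness
#' `l = (2 mu_R mu_Q + C1) / (mu_R^2 + mu_Q^2 + C1)`, contrast
#' `c = (2 sd_R sd_Q + C2) / (sd_R^2 + sd_Q^2 + C2)` and structure
#' `s = (cov_RQ + C3) / (sd_R sd_Q + C3)`. The stabilizing constants follow
#' the image-analysis convention `C1 = (0.01 D)^2`, `C2 = (0.03 D)^2`,
#' `C3 = C2 / 2`, with `D` the dynamic range of the two windows; they keep
#' all-constant windows finite. S is 1 for identical windows and lies in
#' `[-1, 1]`.
#'
#' @param R,Q Equal-size numeric matrices (O/E windows). `NA` pixels must be
#'   imputed beforehand (see [sliding_similarity()]).
#' @param weights Component exponents `c(alpha, beta, gamma)` (default all 1).
#' @param constants Optional `c(C1, C2, C3)`; derived from the dynamic range
#'   when NULL.
#' @return list(`S`, `brightness`, `contrast`, `structure`).
#' @export
ssim <- function(R, Q, weights = c(1, 1, 1), constants = NULL) {
  if (!all(dim(R) == dim(Q))) stop("window size mismatch")
  r <- as.numeric(R); q <- as.numeric(Q)
  if (anyNA(r) || anyNA(q)) stop("NA pixels: impute before calling ssim")
  if (is.null(constants)) {
    D <- max(r, q) - min(r, q)
    if (D == 0) D <- 1
    constants <- c((0.01 * D)^2, (0.03 * D)^2, (0.03 * D)^2 / 2)
  }
  C1 <- constants[1]; C2 <- constants[2]; C3 <- constants[3]
  n <- length(r)
  mu_r <- mean(r); mu_q <- mean(q)
  ## population (biased) moments, the image-analysis convention
  var_r <- sum((r - mu_r)^2) / n
  var_q <- sum((q - mu_q)^2) / n
  cov_rq <- sum((r - mu_r) * (q - mu_q)) / n
  sd_r <- sqrt(var_r); sd_q <- sqrt(var_q)
  l <- (2 * mu_r * mu_q + C1) / (mu_r^2 + mu_q^2 + C1)
  c_ <- (2 * sd_r * sd_q + C2) / (var_r + var_q + C2)
  s_ <- (cov_rq + C3) / (sd_r * sd_q + C3)
  S <- sign(l)^weights[1] * abs(l)^weights[1] *
    c_^weights[2] * sign(s_) * abs(s_)^weights[3]
  list(S = S, brightness = l, contrast = c_, structure = s_)
}

#' Bilinear rescaling of a matrix to a target size
#'
#' Used to bring two windows of unequal bin counts onto a common grid
#' before SSIM.
#'
#' @param m Numeric matrix.
#' @param nrow_out,ncol_out Target dimensions.
#' @return Rescaled matrix.
#' @export
rescale_bilinear <- function(m, nrow_out, ncol_out) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr == nrow_out && nc == ncol_out) return(m)
  rx <- if (nrow_out == 1) 1 else seq(1, nr, length.out = nrow_out)
  cx <- if (ncol_out == 1) 1 else seq(1, nc, length.out = ncol_out)
  r0 <- pmin(floor(rx), nr - 1L); c0 <- pmin(floor(cx), nc - 1L)
  fr <- rx - r0; fc <- cx - c0
  out <- matrix(0, nrow_out, ncol_out)
  for (a in seq_len(nrow_out)) {
    m1 <- m[r0[a], ] * (1 - fr[a]) + m[r0[a] + 1L, ] * fr[a]
    out[a, ] <- m1[c0] * (1 - fc) + m1[c0 + 1L] * fc
  }
  out
}

#' Sliding-window SSIM comparison of two contact maps
#'
#' Tiles the chromosome with windows of `window_bp` every `step_bp`,
#' extracts the O/E submatrix of each matrix, imputes masked pixels at the
#' O/E expectation (1), skips windows with more than `max_masked_frac`
#' masked pixels, and scores each window pair with [ssim()]. The z-score is
#' against the mean/sd of all window scores and the empirical p is the
#' left-tail rank probability among all windows (suppressed with a warning
#' below 10 windows).
#'
#' @param cm_a,cm_b O/E-state [contact_matrix()]s on the same bin table
#'   (balanced input is O/E-normalized on the fly).
#' @param window_bp,step_bp Window and step in bp (defaults 2 Mb / 500 kb).
#' @param max_masked_frac Window skip threshold (default 0.3).
#' @return data.frame `start,end,S,brightness,contrast,structure,z,p`.
#' @export
sliding_similarity <- function(cm_a, cm_b, window_bp = 2e6, step_bp = 5e5,
                               max_masked_frac = 0.3) {
  if (cm_a$state != "oe") cm_a <- observed_over_expected(cm_a)
  if (cm_b$state != "oe") cm_b <- observed_over_expected(cm_b)
  bt <- cm_a$bin_table
  stopifnot(bt$n_bins == cm_b$bin_table$n_bins)
  wb <- as.integer(round(window_bp / bt$resolution))
  sb <- as.integer(round(step_bp / bt$resolution))
  if (wb < 2 || sb < 1) stop("window/step too small for this resolution")
  starts <- seq(0L, bt$n_bins - wb, by = sb)
  rows <- lapply(starts, function(s0) {
    wa <- cm_window(cm_a, s0, s0 + wb - 1L)
    wbm <- cm_window(cm_b, s0, s0 + wb - 1L)
    masked <- mean(is.na(wa) | is.na(wbm))
    if (masked > max_masked_frac) return(NULL)
    wa[is.na(wa)] <- 1; wbm[is.na(wbm)] <- 1    # O/E expectation
    sc <- ssim(wa, wbm)
    data.frame(start = bt$start[s0 + 1L],
               end = bt$end[min(s0 + wb, bt$n_bins)],
               S = sc$S, brightness = sc$brightness,
               contrast = sc$contrast, structure = sc$structure)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no scorable windows")
  sdv <- stats::sd(out$S)
  out$z <- if (is.na(sdv) || sdv == 0) 0 else (out$S - mean(out$S)) / sdv
  if (nrow(out) >= 10) {
    out$p <- vapply(out$S, function(v) mean(out$S <= v), numeric(1))
  } else {
    warning("fewer than 10 windows: empirical p suppressed")
    out$p <- NA_real_
  }
  out
}

#' Merge dissimilar windows into regions
#'
#' Windows with `z <= -z_threshold` are merged when they overlap.
#'
#' @param windows Output of [sliding_similarity()].
#' @param z_threshold Dissimilarity threshold on the z-score (default 2).
#' @return data.frame `start,end,n_windows,min_z`.
#' @export
dissimilar_regions <- function(windows, z_threshold = 2) {
  hit <- windows[windows$z <= -abs(z_threshold), , drop = FALSE]
  out <- data.frame(start = numeric(), end = numeric(),
                    n_windows = integer(), min_z = numeric())
  if (!nrow(hit)) return(out)
  hit <- hit[order(hit$start), , drop = FALSE]
  cs <- hit$start[1]; ce <- hit$end[1]; nw <- 1L; mz <- hit$z[1]
  flush <- function() out[nrow(out) + 1L, ] <<- list(cs, ce, nw, mz)
  for (r in seq_len(nrow(hit))[-1]) {
    if (hit$start[r] < ce) {
      ce <- max(ce, hit$end[r]); nw <- nw + 1L; mz <- min(mz, hit$z[r])
    } else {
      flush()
      cs <- hit$start[r]; ce <- hit$end[r]; nw <- 1L; mz <- hit$z[r]
    }
  }
  flush()
  out
}
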