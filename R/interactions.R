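#' Enumerate unmasked pixels of a matrix in a distance range
#'
#' Includes implicit zeros between unmasked bins, since the background
#' models are fitted to the complete pixel population.
#'
#' @param cm A [contact_matrix()].
#' @param min_dist,max_dist Bin-distance range (inclusive).
#' @return data.frame `i`, `j`, `d`, `value`.
#' @keywords internal
cm_pixels <- function(cm, min_dist, max_dist) {
  n <- cm$bin_table$n_bins
  max_dist <- min(max_dist, n - 1L)
  ds <- min_dist:max_dist
  i <- unlist(lapply(ds, function(d) 0:(n - 1L - d)), use.names = FALSE)
  d <- rep.int(ds, n - ds)
  j <- i + d
  ok <- cm$mask[i + 1L] & cm$mask[j + 1L]
  i <- i[ok]; j <- j[ok]; d <- d[ok]
  v <- numeric(length(i))
  sel <- cm$j - cm$i >= min_dist & cm$j - cm$i <= max_dist &
    cm$mask[cm$i + 1L] & cm$mask[cm$j + 1L]
  m <- match(cm$i[sel] * as.numeric(n) + cm$j[sel], i * as.numeric(n) + j)
  v[m[!is.na(m)]] <- cm$value[sel][!is.na(m)]
  data.frame(i = i, j = j, d = d, value = v)
}

#' Fit a negative binomial by moments with an MLE polish
#'
#' Method-of-moments start (`size = m^2 / (v - m)`), followed by a
#' Newton-free `optimize` polish of the NB size parameter at fixed mean.
#' Dispersion is floored at the Poisson limit.
#'
#' @param x Non-negative counts (or continuous values; rounded for the
#'   likelihood polish).
#' @return list(`mu`, `size`).
#' @keywords internal
fit_nb <- function(x) {
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(m) || m <= 0) return(list(mu = m, size = Inf))
  size0 <- if (v > m) m^2 / (v - m) else 1e8
  xi <- round(x)
  nll <- function(s) -sum(stats::dnbinom(xi, size = s, mu = m, log = TRUE))
  opt <- tryCatch(
    stats::optimize(nll, lower = size0 / 10, upper = size0 * 10)$minimum,
    error = function(e) size0)
  list(mu = m, size = max(opt, 1e-8))
}

#' Negative binomial candidate loop pixels
#'
#' For each genomic distance an NB background is fitted to all unmasked
#' pixel values (zeros included); a pixel is a candidate when its upper-tail
#' probability `P(X >= obs)` is below `alpha`. Distance strata with fewer
#' than `min_points` pixels are pooled with neighboring distances into
#' log-spaced bands.
#'
#' @param cm Balanced [contact_matrix()] (10-kb resolution typical).
#' @param alpha Candidate p-value threshold (default 0.05).
#' @param min_dist,max_dist Bin-distance range (defaults 2 and 200).
#' @param min_points Minimum pixels per stratum before pooling (default 200).
#' @return data.frame of candidates: `i,j,d,value,expected,p`.
#' @export
nb_candidates <- function(cm, alpha = 0.05, min_dist = 2L, max_dist = 200L,
                          min_points = 200L) {
  stopifnot(inherits(cm, "contact_matrix"))
  px <- cm_pixels(cm, min_dist, max_dist)
  if (!nrow(px)) return(px[0, ])
  px$band <- pool_distances(px$d, min_points)
  out <- vector("list", length(unique(px$band)))
  bi <- 0L
  for (b in unique(px$band)) {
    sel <- px$band == b
    x <- px$value[sel]
    if (all(x == 0)) next
    fit <- fit_nb(x)
    obs <- px$value[sel]
    p <- stats::pnbinom(pmax(ceiling(obs) - 1, 0), size = fit$size,
                        mu = fit$mu, lower.tail = FALSE)
    hit <- p < alpha & obs > 0
    if (any(hit)) {
      bi <- bi + 1L
      out[[bi]] <- data.frame(i = px$i[sel][hit], j = px$j[sel][hit],
                              d = px$d[sel][hit], value = obs[hit],
                              expected = fit$mu, p = p[hit])
    }
  }
  res <- if (bi) do.call(rbind, out[seq_len(bi)]) else
    data.frame(i = integer(), j = integer(), d = integer(),
               value = numeric(), expected = numeric(), p = numeric())
  res[order(res$p), , drop = FALSE]
}

## pool sparse distance strata into log-spaced bands
pool_distances <- function(d, min_points) {
  cnt <- table(d)
  if (all(cnt >= min_points)) return(d)
  ## log-spaced band edges; grow until every band has enough points
  for (nb in c(64, 32, 16, 8, 4, 2, 1)) {
    edges <- unique(round(exp(seq(log(max(min(d), 1)),
                                  log(max(d) + 1), length.out = nb + 1))))
    band <- findInterval(d, edges, rightmost.closed = TRUE)
    if (all(table(band) >= min_points) || nb == 1) return(band + max(d) + 1L)
  }
  rep(1L, length(d))
}

#' Keep only the strongest candidate per neighborhood
#'
#' Among candidates within the same `(2*window+1)^2` pixel neighborhood,
#' only the one with the maximal observed value survives; ties go to the
#' smaller `(i, j)`. The result is an antichain: no two surviving loops lie
#' within one window of each other.
#'
#' Optionally (when `cm` is given) each candidate is also tested against its
#' *local* background -- the mean of the neighborhood ring (the window
#' excluding the 3x3 peak core): the candidate must exceed
#' `min_local_enrichment` times the ring mean, and (when the matrix carries
#' balancing weights) its raw read support `value * w_i * w_j` must be
#' Poisson-improbable, at level `local_alpha`, under the ring-mean
#' expectation scaled by the same weights. The distance-stratified NB
#' background is genome-global, so without a local test pixels inside
#' strong domains at sparsely populated distances, or scaled-up count noise
#' between two low-coverage bins, pass on global grounds alone.
#'
#' @param candidates Output of [nb_candidates()].
#' @param window_bins Neighborhood half-width in bins (default 5).
#' @param cm The [contact_matrix()] the candidates came from (only needed
#'   for the local criteria).
#' @param min_local_enrichment Required ratio of the candidate value to its
#'   neighborhood-ring mean; `NULL` (default) disables the ratio test.
#' @param local_alpha Level of the raw-support Poisson test against the
#'   local expectation; `NULL` (default) disables it.
#' @return Filtered candidate data.frame (a loop set).
#' @export
neighborhood_filter <- function(candidates, window_bins = 5L, cm = NULL,
                                min_local_enrichment = NULL,
                                local_alpha = NULL) {
  if (!nrow(candidates)) return(candidates)
  if (!is.null(cm) && (!is.null(min_local_enrichment) || !is.null(local_alpha))) {
    dm <- cm_dense(cm)
    n <- nrow(dm)
    w <- window_bins
    bg <- vapply(seq_len(nrow(candidates)), function(r) {
      ci <- candidates$i[r] + 1L; cj <- candidates$j[r] + 1L
      ri <- max(1L, ci - w):min(n, ci + w)
      rj <- max(1L, cj - w):min(n, cj + w)
      ring <- dm[ri, rj]
      ring[ri >= ci - 1L & ri <= ci + 1L, rj >= cj - 1L & rj <= cj + 1L] <- NA
      mean(ring, na.rm = TRUE)
    }, numeric(1))
    ok <- is.finite(bg)
    if (!is.null(min_local_enrichment))
      ok <- ok & candidates$value >= min_local_enrichment * bg
    if (!is.null(local_alpha) && !is.null(cm$weights)) {
      wp <- cm$weights[candidates$i + 1L] * cm$weights[candidates$j + 1L]
      raw <- candidates$value * wp
      p_raw <- stats::ppois(pmax(ceiling(raw) - 1, 0), bg * wp,
                            lower.tail = FALSE)
      ok <- ok & !is.na(p_raw) & p_raw < local_alpha
    }
    candidates <- candidates[ok, , drop = FALSE]
    if (!nrow(candidates)) return(candidates)
  }
  ord <- order(-candidates$value, candidates$i, candidates$j)
  cand <- candidates[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  ki <- integer(0); kj <- integer(0)
  for (r in seq_len(nrow(cand))) {
    if (length(ki) &&
        any(pmax(abs(ki - cand$i[r]), abs(kj - cand$j[r])) <= window_bins))
      next
    keep[r] <- TRUE
    ki <- c(ki, cand$i[r]); kj <- c(kj, cand$j[r])
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$i, out$j), , drop = FALSE]
}

#' Loop calling with a parameter sweep and merge
#'
#' Runs [nb_candidates()] + [neighborhood_filter()] over a grid of
#' `(alpha, window)` settings and merges the union: calls whose anchors lie
#' within `merge_radius` bins are collapsed to the call with the smallest
#' p-value. The default grid is deliberately stricter than the per-setting
#' candidate threshold, because the plain NB + neighborhood pipeline (no
#' donut filtering) otherwise admits isolated noise pixels.
#'
#' @param cm Balanced [contact_matrix()].
#' @param alphas Candidate thresholds to sweep (default `c(1e-4, 1e-5)`).
#' @param windows Neighborhood half-widths to sweep (default `c(3, 5)`).
#' @param min_local_enrichment Local-background ratio required of surviving
#'   candidates (see [neighborhood_filter()]; default 2).
#' @param local_alpha Level of the raw-support local Poisson test (see
#'   [neighborhood_filter()]; default 1e-5).
#' @param merge_radius Anchor collapse radius in bins (default 2).
#' @param min_dist,max_dist Bin-distance range.
#' @return Loop set data.frame `i,j,d,value,expected,p,alpha,window`.
#' @export
sweep_and_merge <- function(cm, alphas = c(1e-4, 1e-5), windows = c(3L, 5L),
                            min_local_enrichment = 2, local_alpha = 1e-5,
                            merge_radius = 2L,
                            min_dist = 2L, max_dist = 200L) {
  sets <- list()
  for (a in alphas) {
    cand <- nb_candidates(cm, alpha = a, min_dist = min_dist,
                          max_dist = max_dist)
    for (w in windows) {
      s <- neighborhood_filter(cand, window_bins = w, cm = cm,
                               min_local_enrichment = min_local_enrichment,
                               local_alpha = local_alpha)
      if (nrow(s)) { s$alpha <- a; s$window <- w; sets[[length(sets) + 1L]] <- s }
    }
  }
  if (!length(sets))
    return(data.frame(i = integer(), j = integer(), d = integer(),
                      value = numeric(), expected = numeric(), p = numeric(),
                      alpha = numeric(), window = integer()))
  allc <- do.call(rbind, sets)
  allc <- allc[order(allc$p, allc$i, allc$j), , drop = FALSE]
  keep <- logical(nrow(allc))
  ki <- integer(0); kj <- integer(0)
  for (r in seq_len(nrow(allc))) {
    if (length(ki) &&
        any(pmax(abs(ki - allc$i[r]), abs(kj - allc$j[r])) <= merge_radius))
      next
    keep[r] <- TRUE
    ki <- c(ki, allc$i[r]); kj <- c(kj, allc$j[r])
  }
  out <- allc[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$i, out$j), , drop = FALSE]
}

#' Distance-stratified Weibull background fit
#'
#' Per distance stratum (pooled into log-spaced bands when sparse), zero
#' contacts are removed, values above the `fit_percentile` percentile of the
#' nonzero contacts are excluded so true interactions do not distort the
#' fit, and a Weibull distribution is fitted by maximum likelihood.
#'
#' @param cm Balanced [contact_matrix()].
#' @param fit_percentile Upper exclusion percentile (default 95).
#' @param min_dist,max_dist Bin-distance range.
#' @param min_points Minimum nonzero values per stratum before pooling
#'   (default 200).
#' @param discrete_shift Half-width subtracted from values before fitting
#'   and testing (default 0.5). Balanced Hi-C values live on a near-integer
#'   count lattice; shifting to interval midpoints is the usual continuity
#'   correction when modelling lattice data with a continuous distribution.
#'   Set 0 for genuinely continuous inputs.
#' @return Object of class `weibull_background`: data.frame `band`, `d_min`,
#'   `d_max`, `shape`, `scale`, `n`, `unfit`, plus the shift used.
#' @export
weibull_background <- function(cm, fit_percentile = 95, min_dist = 2L,
                               max_dist = 200L, min_points = 200L,
                               discrete_shift = 0.5) {
  stopifnot(inherits(cm, "contact_matrix"))
  px <- cm_pixels(cm, min_dist, max_dist)
  px <- px[px$value > 0, , drop = FALSE]
  if (!nrow(px)) stop("no nonzero pixels in distance range")
  px$band <- pool_distances(px$d, min_points)
  bands <- sort(unique(px$band))
  fit1 <- function(x) {
    cut <- stats::quantile(x, fit_percentile / 100, names = FALSE)
    x <- x[x <= cut]
    x <- pmax(x - discrete_shift, 1e-6)
    if (length(x) < 10 || stats::sd(x) == 0)
      return(list(shape = NA_real_, scale = NA_real_, n = length(x),
                  unfit = TRUE))
    f <- fit_weibull_mle(x, truncation = max(cut - discrete_shift, 1e-6))
    list(shape = f$shape, scale = f$scale, n = length(x), unfit = FALSE)
  }
  rows <- lapply(bands, function(b) {
    sel <- px$band == b
    f <- fit1(px$value[sel])
    data.frame(band = b, d_min = min(px$d[sel]), d_max = max(px$d[sel]),
               shape = f$shape, scale = f$scale, n = f$n, unfit = f$unfit)
  })
  out <- do.call(rbind, rows)
  structure(list(fits = out, min_dist = min_dist, max_dist = max_dist,
                 min_points = min_points, discrete_shift = discrete_shift),
            class = "weibull_background")
}

#' Maximum-likelihood Weibull fit, optionally right-truncated
#'
#' With `truncation = NULL` this wraps [MASS::fitdistr()] (moment-matched
#' fallback when the optimizer fails). With a truncation point `c` the fit
#' maximizes the right-truncated likelihood
#' `prod f(x) / F(c)` -- the correct MLE when values above `c` were removed
#' before fitting, as the percentile cut of [weibull_background()] does;
#' a plain MLE on truncated data systematically underestimates the tail.
#'
#' @param x Positive values.
#' @param truncation Right-truncation point, or `NULL` for a complete-data
#'   fit.
#' @return list(`shape`, `scale`).
#' @export
fit_weibull_mle <- function(x, truncation = NULL) {
  if (!is.null(truncation)) {
    start <- c(log(1.2), log(mean(x)))
    nll <- function(par) {
      k <- exp(par[1]); sc <- exp(par[2])
      -sum(stats::dweibull(x, k, sc, log = TRUE)) +
        length(x) * stats::pweibull(truncation, k, sc, log.p = TRUE)
    }
    o <- tryCatch(stats::optim(start, nll), error = function(e) NULL)
    if (!is.null(o) && all(is.finite(o$par)))
      return(list(shape = exp(o$par[1]), scale = exp(o$par[2])))
  }
  f <- tryCatch(
    MASS::fitdistr(x, "weibull", lower = c(1e-3, 1e-8)),
    error = function(e) NULL)
  if (!is.null(f))
    return(list(shape = unname(f$estimate["shape"]),
                scale = unname(f$estimate["scale"])))
  ## moment fallback: solve CV for the shape, then the scale from the mean
  cv <- stats::sd(x) / mean(x)
  g <- function(k) sqrt(gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1) - cv
  k <- tryCatch(stats::uniroot(g, c(0.05, 50))$root, error = function(e) 1)
  list(shape = k, scale = mean(x) / gamma(1 + 1 / k))
}

#' Weibull-background significant interactions
#'
#' The p-value of a pixel is the Weibull upper tail at its value, for the
#' fitted background of its distance band. Zero pixels are never tested.
#' With `anchor` given, only that bin's row is tested (virtual-4C mode).
#'
#' @param cm Balanced [contact_matrix()].
#' @param background A [weibull_background()] (fitted on `cm` if NULL).
#' @param alpha Significance threshold (default 1e-4, no multiplicity
#'   correction, per the fixed-threshold convention; BH q-values are still
#'   reported).
#' @param anchor Optional 0-based anchor bin (virtual 4C).
#' @param min_dist,max_dist Bin-distance range.
#' @return data.frame `i,j,d,value,p,q,significant` for all tested pixels
#'   with `value > 0`.
#' @export
significant_interactions <- function(cm, background = NULL, alpha = 1e-4,
                                     anchor = NULL, min_dist = 2L,
                                     max_dist = 200L) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (is.null(background))
    background <- weibull_background(cm, min_dist = min_dist,
                                     max_dist = max_dist)
  px <- cm_pixels(cm, min_dist, max_dist)
  px <- px[px$value > 0, , drop = FALSE]
  if (!is.null(anchor))
    px <- px[px$i == anchor | px$j == anchor, , drop = FALSE]
  if (!nrow(px))
    return(data.frame(i = integer(), j = integer(), d = integer(),
                      value = numeric(), p = numeric(), q = numeric(),
                      significant = logical()))
  fits <- background$fits
  band_of <- function(d) {
    hit <- which(fits$d_min <= d & fits$d_max >= d)
    if (length(hit)) hit[1] else NA_integer_
  }
  bidx <- vapply(px$d, band_of, integer(1))
  p <- rep(NA_real_, nrow(px))
  ok <- !is.na(bidx) & !fits$unfit[bidx]
  shift <- if (is.null(background$discrete_shift)) 0 else
    background$discrete_shift
  p[ok] <- stats::pweibull(pmax(px$value[ok] - shift, 1e-6),
                           shape = fits$shape[bidx[ok]],
                           scale = fits$scale[bidx[ok]], lower.tail = FALSE)
  px$p <- p
  px$q <- stats::p.adjust(p, method = "BH")
  px$significant <- !is.na(p) & p < alpha
  rownames(px) <- NULL
  px
}

#' Label loops specific to one group (region or stage)
#'
#' A loop called in group g is labeled specific to g when its mean O/E over
#' every other group is below `frac` of its O/E in g. This criterion is a
#' package convention (callers differ); the threshold is configurable.
#'
#' @param loop_sets Named list of loop sets (one per group).
#' @param oe_list Named list of O/E matrices, same names.
#' @param frac Cross-group O/E ratio threshold (default 0.5).
#' @return data.frame `group,i,j,oe_own,oe_other_mean,specific`.
#' @export
specificity_labels <- function(loop_sets, oe_list, frac = 0.5) {
  stopifnot(identical(sort(names(loop_sets)), sort(names(oe_list))))
  groups <- names(loop_sets)
  if (length(groups) == 1L)
    warning("single group: every loop is trivially specific")
  oe_at <- function(cm, i, j) {
    m <- match(i * as.numeric(cm$bin_table$n_bins) + j,
               cm$i * as.numeric(cm$bin_table$n_bins) + cm$j)
    v <- cm$value[m]
    v[is.na(v)] <- 0
    v
  }
  rows <- lapply(groups, function(g) {
    ls <- loop_sets[[g]]
    if (!nrow(ls)) return(NULL)
    own <- oe_at(oe_list[[g]], ls$i, ls$j)
    others <- setdiff(groups, g)
    other_mean <- if (length(others)) {
      rowMeans(matrix(vapply(others, function(h)
        oe_at(oe_list[[h]], ls$i, ls$j), numeric(nrow(ls))), nrow = nrow(ls)))
    } else rep(0, nrow(ls))
    data.frame(group = g, i = ls$i, j = ls$j, oe_own = own,
               oe_other_mean = other_mean,
               specific = length(others) == 0 | other_mean < frac * own,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate peak analysis around anchor pairs
#'
#' Averages O/E submatrices in aligned `(2*flank+1)^2` windows centered on
#' each anchor pair; central enrichment is the center pixel of the mean
#' window over the mean of its four corner pixels.
#'
#' @param cm_oe O/E-state [contact_matrix()].
#' @param pairs data.frame with columns `i`, `j` (0-based anchor bins).
#' @param flank_bins Window half-width (default 5).
#' @return list(`mean_window` matrix, `enrichment`, `n_pairs`).
#' @export
apa <- function(cm_oe, pairs, flank_bins = 5L) {
  stopifnot(inherits(cm_oe, "contact_matrix"))
  if (!nrow(pairs)) stop("empty anchor pair list")
  n <- cm_oe$bin_table$n_bins
  w <- 2L * flank_bins + 1L
  acc <- matrix(0, w, w); cnt <- matrix(0, w, w)
  used <- 0L
  f <- flank_bins
  for (r in seq_len(nrow(pairs))) {
    ci <- min(pairs$i[r], pairs$j[r]); cj <- max(pairs$i[r], pairs$j[r])
    if (ci - f < 0 || cj + f >= n) next
    if (cj - ci <= 2L * f) next              # windows must not cross diagonal
    used <- used + 1L
    sel <- cm_oe$i >= ci - f & cm_oe$i <= ci + f &
      cm_oe$j >= cj - f & cm_oe$j <= cj + f
    sub <- matrix(0, w, w)
    if (any(sel))
      sub[cbind(cm_oe$i[sel] - ci + f + 1L, cm_oe$j[sel] - cj + f + 1L)] <-
        cm_oe$value[sel]
    mrow <- cm_oe$mask[(ci - f):(ci + f) + 1L]
    mcol <- cm_oe$mask[(cj - f):(cj + f) + 1L]
    okpx <- outer(mrow, mcol, "&")
    acc[okpx] <- acc[okpx] + sub[okpx]
    cnt <- cnt + okpx
  }
  if (used == 0L) stop("no anchor pair admits a full window")
  mw <- ifelse(cnt > 0, acc / cnt, NA_real_)
  corners <- c(mw[1, 1], mw[1, w], mw[w, 1], mw[w, w])
  center <- mw[flank_bins + 1L, flank_bins + 1L]
  list(mean_window = mw,
       enrichment = center / mean(corners, na.rm = TRUE), n_pairs = used)
}

#' Correlation between loop strength and linked-gene expression
#'
#' Pearson correlation, per loop-gene pair, between the loop's per-sample
#' O/E strength and the linked gene's log2 FPKM across samples, with BH
#' adjustment across pairs.
#'
#' @param strengths loops x samples matrix of O/E strengths (rownames = loop
#'   ids).
#' @param et An [expression_table()] whose columns match `colnames(strengths)`.
#' @param links data.frame `loop` (rowname in `strengths`), `gene`.
#' @return data.frame `loop,gene,r,p,q`.
#' @export
loop_expression_correlation <- function(strengths, et, links) {
  stopifnot(inherits(et, "expression_table"),
            all(colnames(strengths) %in% colnames(et$fpkm)))
  if (ncol(strengths) < 3) stop("need >= 3 samples to correlate")
  rows <- lapply(seq_len(nrow(links)), function(r) {
    lp <- as.character(links$loop[r]); g <- as.character(links$gene[r])
    if (!(lp %in% rownames(strengths)) || !(g %in% rownames(et$fpkm)))
      return(NULL)
    x <- strengths[lp, ]
    y <- log2(et$fpkm[g, colnames(strengths)] + 1)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
    ct <- stats::cor.test(x, y)
    data.frame(loop = lp, gene = g, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(loop = character(), gene = character(),
                                      r = numeric(), p = numeric(),
                                      q = numeric()))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
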