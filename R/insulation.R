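#' Insulation score along the matrix diagonal
#'
#' Slides a `window_bp x window_bp` square along the diagonal: for bin b the
#' square spans rows `b-w..b-1` and columns `b+1..b+w` (the diagonal bin
#' itself is excluded), with `w = window_bp / resolution`. The raw score is
#' the mean of the square's values lying within the interquartile range
#' (a 25-75% trimmed mean), or the plain mean when `trim = FALSE`. Bins
#' within `w` of a chromosome end, or whose square has no usable pixel, get
#' no score.
#'
#' @param cm A balanced or O/E-state [contact_matrix()] (40-kb resolution in
#'   the reference pipeline). O/E input is recommended and is what
#'   [run_pipeline()] uses: the trimmed IQR mean is only a meaningful robust
#'   statistic when the square's values are exchangeable, which requires
#'   removing the distance decay first; on decaying matrices the trim
#'   systematically discards near-diagonal pixels and flattens valleys.
#' @param window_bp Square side in bp; must be a multiple of the resolution
#'   (default 480 kb).
#' @param trim Use the IQR-trimmed mean (default `TRUE`).
#' @return Object of class `insulation_profile` with fields `raw`, `norm`
#'   (filled by [normalize_insulation()]), `bin_table`, `window_bins`.
#' @export
insulation_score <- function(cm, window_bp = 480000, trim = TRUE) {
  stopifnot(inherits(cm, "contact_matrix"))
  bt <- cm$bin_table
  w <- window_bp / bt$resolution
  if (w != round(w)) stop("window_bp must be an integer multiple of the resolution")
  w <- as.integer(w)
  if (w < 2L) stop("window must span at least 2 bins")
  n <- bt$n_bins
  dm <- cm_dense(cm)
  raw <- rep(NA_real_, n)
  for (b in seq(w, n - 1L - w)) {      # 0-based bin b
    sq <- dm[(b - w):(b - 1L) + 1L, (b + 1L):(b + w) + 1L]
    vals <- sq[!is.na(sq)]
    if (!length(vals)) next
    if (trim) {
      q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE)
      inr <- vals[vals >= q[1] & vals <= q[2]]
      raw[b + 1L] <- if (length(inr)) mean(inr) else mean(vals)
    } else raw[b + 1L] <- mean(vals)
  }
  raw[!cm$mask] <- NA_real_
  structure(list(bin_table = bt, window_bins = w, raw = raw,
                 norm = NULL, boundaries = NULL),
            class = "insulation_profile")
}

#' @export
print.insulation_profile <- function(x, ...) {
  cat(sprintf("<insulation_profile> %d bins, window %d bins, %d scored%s\n",
              x$bin_table$n_bins, x$window_bins, sum(!is.na(x$raw)),
              if (!is.null(x$boundaries))
                sprintf(", %d boundaries", nrow(x$boundaries)) else ""))
  invisible(x)
}

#' Normalize an insulation profile per chromosome
#'
#' `norm = log2(raw / mean(raw over scored bins))`; defined only where
#' `raw > 0`. By construction the mean of `2^norm` over scored bins is 1 and
#' the result is invariant to global rescaling of the matrix.
#'
#' @param profile An [insulation_score()] profile.
#' @return The profile with `norm` filled in.
#' @export
normalize_insulation <- function(profile) {
  stopifnot(inherits(profile, "insulation_profile"))
  ok <- !is.na(profile$raw)
  m <- mean(profile$raw[ok])
  if (!is.finite(m) || m <= 0) stop("no positive insulation scores to normalize")
  norm <- rep(NA_real_, length(profile$raw))
  pos <- ok & profile$raw > 0
  norm[pos] <- log2(profile$raw[pos] / m)
  profile$norm <- norm
  profile
}

#' Detect insulation valleys (TAD boundaries)
#'
#' Boundaries are local minima of the normalized insulation score whose
#' strength -- the mean of the two nearest flanking local maxima minus the
#' minimum value -- is at least `delta`. Plateaus of equal minima yield a
#' single boundary at their leftmost bin.
#'
#' @param profile Normalized [insulation_score()] profile.
#' @param delta Minimum boundary strength (default 0.1).
#' @return The profile with `boundaries`: a data.frame
#'   (`chrom,start,end,bin,strength,norm_is`).
#' @export
detect_boundaries <- function(profile, delta = 0.1) {
  stopifnot(inherits(profile, "insulation_profile"))
  if (is.null(profile$norm)) profile <- normalize_insulation(profile)
  x <- profile$norm
  bt <- profile$bin_table
  idx <- which(!is.na(x))
  v <- x[idx]
  nn <- length(v)
  res <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    bin = integer(), strength = numeric(), norm_is = numeric(),
                    stringsAsFactors = FALSE)
  if (nn >= 3) {
    is_min <- logical(nn); is_max <- logical(nn)
    for (k in 2:(nn - 1)) {
      ## plateau-aware extrema: compare to nearest differing neighbors
      l <- k - 1; while (l >= 1 && v[l] == v[k]) l <- l - 1
      r <- k + 1; while (r <= nn && v[r] == v[k]) r <- r + 1
      if (l >= 1 && r <= nn) {
        if (v[l] > v[k] && v[r] > v[k] && (k == 1 || v[k - 1] != v[k]))
          is_min[k] <- TRUE    # leftmost bin of an equal-minimum plateau
        if (v[l] < v[k] && v[r] < v[k] && (k == 1 || v[k - 1] != v[k]))
          is_max[k] <- TRUE
      }
    }
    mins <- which(is_min); maxs <- which(is_max)
    for (k in mins) {
      lmax <- maxs[maxs < k]; rmax <- maxs[maxs > k]
      ## with no interior flanking maximum (e.g. flat shoulders), fall back
      ## to the highest value on that side of the valley
      lv <- if (length(lmax)) v[max(lmax)] else max(v[seq_len(k - 1)])
      rv <- if (length(rmax)) v[min(rmax)] else max(v[(k + 1):nn])
      flank <- c(lv, rv)
      strength <- mean(flank) - v[k]
      if (strength >= delta) {
        b <- idx[k] - 1L
        res[nrow(res) + 1L, ] <- list(bt$chrom, bt$start[b + 1L],
                                      bt$end[b + 1L], b, strength, v[k])
      }
    }
  }
  profile$boundaries <- res
  profile
}

#' Derive TADs from boundary calls
#'
#' Consecutive boundary bin midpoints delimit TADs; the scored span's ends
#' close the first and last domain. Domains shorter than `min_size_bp` are
#' merged into their smaller-insulation neighbor.
#'
#' @param profile A [detect_boundaries()] profile.
#' @param min_size_bp Minimum TAD size (default 400 kb).
#' @return Interval data.frame of TADs (`chrom,start,end,name`).
#' @export
tads_from_boundaries <- function(profile, min_size_bp = 400000) {
  stopifnot(inherits(profile, "insulation_profile"),
            !is.null(profile$boundaries))
  bt <- profile$bin_table
  scored <- which(!is.na(profile$raw)) - 1L
  if (!length(scored)) stop("profile has no scored bins")
  span <- c(bt$start[min(scored) + 1L], bt$end[max(scored) + 1L])
  cuts <- sort((profile$boundaries$start + profile$boundaries$end) / 2)
  edges <- c(span[1], cuts, span[2])
  tads <- data.frame(chrom = bt$chrom, start = edges[-length(edges)],
                     end = edges[-1], stringsAsFactors = FALSE)
  ## enforce minimum size by merging short domains rightward
  k <- 1L
  while (k <= nrow(tads)) {
    if (tads$end[k] - tads$start[k] < min_size_bp && nrow(tads) > 1L) {
      if (k < nrow(tads)) {
        tads$start[k + 1L] <- tads$start[k]
        tads <- tads[-k, , drop = FALSE]
      } else {
        tads$end[k - 1L] <- tads$end[k]
        tads <- tads[-k, , drop = FALSE]
        k <- k - 1L
      }
    } else k <- k + 1L
  }
  rownames(tads) <- NULL
  tads$name <- sprintf("TAD_%d", seq_len(nrow(tads)))
  tads
}

#' Regions of differential insulation between two profiles
#'
#' Maximal runs of at least `min_run` consecutive bins where the absolute
#' difference of normalized insulation meets `min_abs_diff`.
#'
#' @param profile_a,profile_b Normalized profiles on the same bin table.
#' @param min_abs_diff Per-bin absolute difference threshold (default 0.5).
#' @param min_run Minimum run length in bins (default 2).
#' @return Interval data.frame (`chrom,start,end,mean_diff,n_bins`).
#' @export
differential_insulation <- function(profile_a, profile_b,
                                    min_abs_diff = 0.5, min_run = 2) {
  stopifnot(inherits(profile_a, "insulation_profile"),
            inherits(profile_b, "insulation_profile"),
            profile_a$bin_table$n_bins == profile_b$bin_table$n_bins)
  if (is.null(profile_a$norm)) profile_a <- normalize_insulation(profile_a)
  if (is.null(profile_b$norm)) profile_b <- normalize_insulation(profile_b)
  d <- profile_a$norm - profile_b$norm
  hit <- !is.na(d) & abs(d) >= min_abs_diff
  bt <- profile_a$bin_table
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    mean_diff = numeric(), n_bins = integer(),
                    stringsAsFactors = FALSE)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= min_run)) {
    b0 <- starts[k]; b1 <- ends[k]
    out[nrow(out) + 1L, ] <- list(bt$chrom, bt$start[b0], bt$end[b1],
                                  mean(d[b0:b1]), b1 - b0 + 1L)
  }
  out
}

#' Average signal profile around a set of anchors
#'
#' Bins a fixed flank around each anchor midpoint and averages the per-bin
#' count of overlapping peaks (or the mean of a supplied per-bin track)
#' across anchors. Used for CTCF meta-profiles at TAD boundaries.
#'
#' @param anchors Interval data.frame (e.g. boundaries).
#' @param peaks Interval data.frame of peaks, or a numeric per-bin track on
#'   `bt`.
#' @param bt A [bin_table()]; required when `peaks` is a track.
#' @param flank_bp Flank on each side of the anchor midpoint (default 400 kb).
#' @param bin_bp Profile bin width (default 40 kb).
#' @return data.frame (`offset_bp`, `signal`) with `2*flank/bin + 1` rows.
#' @export
meta_profile <- function(anchors, peaks, bt = NULL,
                         flank_bp = 400000, bin_bp = 40000) {
  if (nrow(anchors) == 0L) stop("empty anchor set")
  nb <- as.integer(flank_bp / bin_bp)
  offs <- (-nb:nb) * bin_bp
  acc <- numeric(length(offs)); nobs <- numeric(length(offs))
  mids <- (anchors$start + anchors$end) / 2
  peak_track <- is.numeric(peaks)
  for (m in mids) {
    for (k in seq_along(offs)) {
      s <- m + offs[k] - bin_bp / 2; e <- s + bin_bp
      if (peak_track) {
        stopifnot(!is.null(bt))
        if (s < 0 || e > bt$chrom_length) next
        b <- bin_index(bt, (s + e) / 2)
        if (!is.na(peaks[b + 1L])) {
          acc[k] <- acc[k] + peaks[b + 1L]; nobs[k] <- nobs[k] + 1
        }
      } else {
        acc[k] <- acc[k] + sum(peaks$start < e & peaks$end > s)
        nobs[k] <- nobs[k] + 1
      }
    }
  }
  data.frame(offset_bp = offs,
             signal = ifelse(nobs > 0, acc / nobs, NA_real_))
}
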