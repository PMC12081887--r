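#' Stitch enhancer peaks into candidate regions
#'
#' ROSE-style stitching: peaks fully contained in a TSS exclusion zone
#' (TSS +/- `tss_flank_bp`) are removed, the remaining peaks are merged
#' transitively whenever the gap between consecutive peaks is at most
#' `gap_bp`, and stitched regions must have more than 2 constituents to be
#' valid.
#'
#' @param peaks Interval data.frame (`chrom,start,end[,score]`), one
#'   chromosome.
#' @param gap_bp Maximum stitching gap (default 12500).
#' @param tss Optional vector of TSS positions for promoter exclusion.
#' @param tss_flank_bp Exclusion flank around each TSS (default 2500).
#' @param min_constituents Minimum constituent count for a region to be kept
#'   (default 3, i.e. more than 2 constituents).
#' @return data.frame `chrom,start,end,n_constituents,signal` of valid
#'   stitched regions (signal = summed peak scores).
#' @export
stitch <- function(peaks, gap_bp = 12500, tss = NULL, tss_flank_bp = 2500,
                   min_constituents = 3L) {
  if (!nrow(peaks))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_constituents = integer(), signal = numeric(),
                      stringsAsFactors = FALSE))
  ## promoter exclusion: drop peaks fully inside any TSS window
  if (!is.null(tss) && length(tss)) {
    excl <- vapply(seq_len(nrow(peaks)), function(r)
      any(peaks$start[r] >= tss - tss_flank_bp &
            peaks$end[r] <= tss + tss_flank_bp + 1), logical(1))
    peaks <- peaks[!excl, , drop = FALSE]
  }
  if (!nrow(peaks))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_constituents = integer(), signal = numeric(),
                      stringsAsFactors = FALSE))
  score <- if ("score" %in% names(peaks) && !all(is.na(peaks$score)))
    ifelse(is.na(peaks$score), 0, peaks$score) else (peaks$end - peaks$start)
  ord <- order(peaks$start, peaks$end)
  s <- peaks$start[ord]; e <- peaks$end[ord]; sc <- score[ord]
  grp <- integer(length(s)); grp[1] <- 1L
  hi <- e[1]
  for (r in seq_along(s)[-1]) {
    grp[r] <- if (s[r] - hi <= gap_bp) grp[r - 1L] else grp[r - 1L] + 1L
    hi <- max(hi, e[r])
  }
  out <- data.frame(
    chrom = peaks$chrom[ord][!duplicated(grp)],
    start = tapply(s, grp, min)[as.character(unique(grp))],
    end = tapply(e, grp, max)[as.character(unique(grp))],
    n_constituents = as.integer(table(grp)[as.character(unique(grp))]),
    signal = tapply(sc, grp, sum)[as.character(unique(grp))],
    stringsAsFactors = FALSE)
  out <- out[out$n_constituents >= min_constituents, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank stitched regions and split super-enhancers from typical enhancers
#'
#' The ROSE tangent cutoff: regions are ranked ascending by total signal,
#' rank and signal are rescaled to the unit square, and the cutoff is the
#' signal at the point where the slope of the rescaled curve reaches 1.
#' Regions with signal above the cutoff are super-enhancers (SE), the rest
#' typical enhancers (TE).
#'
#' @param regions Output of [stitch()] (or any data.frame with `signal`).
#' @return The regions with `rank` (ascending signal) and `class`
#'   (`"SE"`/`"TE"`), ordered by rank.
#' @export
rank_and_split <- function(regions) {
  n <- nrow(regions)
  regions$rank <- rank(regions$signal, ties.method = "first")
  regions <- regions[order(regions$rank), , drop = FALSE]
  regions$class <- "TE"
  if (n >= 2 && stats::sd(regions$signal) > 0) {
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (regions$signal - min(regions$signal)) /
      (max(regions$signal) - min(regions$signal))
    ## first index whose forward slope on the rescaled curve exceeds 1
    slope <- c(diff(y) / diff(x), Inf)
    cut_idx <- which(slope > 1)
    if (length(cut_idx)) {
      cutoff <- regions$signal[min(cut_idx)]
      regions$class[regions$signal > cutoff] <- "SE"
    }
  }
  rownames(regions) <- NULL
  regions
}

#' Region-specific super-enhancers by reciprocal overlap
#'
#' An SE of region r is specific when its best reciprocal overlap with the
#' SEs of every other region stays below `min_overlap_frac`.
#'
#' @param se_sets Named list of SE interval data.frames (one per region).
#' @param min_overlap_frac Reciprocal overlap threshold (default 0.3).
#' @return data.frame `region,start,end,max_overlap,specific`.
#' @export
se_specificity <- function(se_sets, min_overlap_frac = 0.3) {
  regions <- names(se_sets)
  rows <- lapply(regions, function(r) {
    se <- se_sets[[r]]
    if (!nrow(se)) return(NULL)
    others <- setdiff(regions, r)
    mo <- vapply(seq_len(nrow(se)), function(k) {
      best <- 0
      for (h in others) {
        o <- se_sets[[h]]
        if (nrow(o))
          best <- max(best, max(reciprocal_overlap(se$start[k], se$end[k],
                                                   o$start, o$end)))
      }
      best
    }, numeric(1))
    data.frame(region = r, start = se$start, end = se$end, max_overlap = mo,
               specific = mo < min_overlap_frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Link super-enhancers to genes via significant interactions
#'
#' A pair (SE, gene) is emitted when any bin overlapping the SE has a
#' significant interaction with the gene's promoter bin. Multiple genes at
#' one promoter bin all get linked, flagged ambiguous.
#'
#' @param ses SE interval data.frame.
#' @param sig Significant-interaction table from
#'   [significant_interactions()] (only rows with `significant` are used).
#' @param genes [gene_models()] output.
#' @param bt The [bin_table()] of the interaction calls.
#' @param min_dist_bins Minimum SE-bin-to-promoter-bin separation (default
#'   5 bins): promoter-proximal pairs sit where the distance-stratified
#'   background is least reliable and are not counted as interaction links.
#' @return data.frame `se_start,se_end,gene,se_bin,promoter_bin,p,ambiguous`.
#' @export
link_se_to_genes <- function(ses, sig, genes, bt, min_dist_bins = 5L) {
  sig <- sig[sig$significant, , drop = FALSE]
  out <- data.frame(se_start = numeric(), se_end = numeric(),
                    gene = character(), se_bin = integer(),
                    promoter_bin = integer(), p = numeric(),
                    ambiguous = logical(), stringsAsFactors = FALSE)
  if (!nrow(ses) || !nrow(sig)) return(out)
  pb <- promoter_bins(genes, bt)
  bin_genes <- split(genes$gene, pb)
  for (r in seq_len(nrow(ses))) {
    b0 <- bin_index(bt, ses$start[r])
    b1 <- bin_index(bt, min(ses$end[r], bt$chrom_length) - 1)
    se_bins <- b0:b1
    hits <- sig[sig$i %in% se_bins | sig$j %in% se_bins, , drop = FALSE]
    if (!nrow(hits)) next
    for (h in seq_len(nrow(hits))) {
      sb <- if (hits$i[h] %in% se_bins) hits$i[h] else hits$j[h]
      ob <- if (hits$i[h] %in% se_bins) hits$j[h] else hits$i[h]
      if (abs(ob - sb) < min_dist_bins) next
      gs <- bin_genes[[as.character(ob)]]
      for (g in gs)
        out[nrow(out) + 1L, ] <- list(ses$start[r], ses$end[r], g, sb, ob,
                                      hits$p[h], length(gs) > 1)
    }
  }
  unique(out)
}

#' Expression of SE-linked vs TE-linked genes
#'
#' One-sided Wilcoxon rank-sum on log2 mean FPKM, alternative: SE-linked
#' genes higher.
#'
#' @param se_genes,te_genes Character vectors of gene ids.
#' @param et An [expression_table()].
#' @return list(`n_se`, `n_te`, `shift` median log2 difference, `p`), or
#'   NULL with a warning when a class is empty.
#' @export
se_vs_te_expression <- function(se_genes, te_genes, et) {
  se_genes <- intersect(unique(se_genes), rownames(et$fpkm))
  te_genes <- setdiff(intersect(unique(te_genes), rownames(et$fpkm)), se_genes)
  if (!length(se_genes) || !length(te_genes)) {
    warning("empty SE- or TE-linked gene class; test skipped")
    return(NULL)
  }
  a <- log2(rowMeans(et$fpkm[se_genes, , drop = FALSE]) + 1)
  b <- log2(rowMeans(et$fpkm[te_genes, , drop = FALSE]) + 1)
  wt <- stats::wilcox.test(a, b, alternative = "greater", exact = FALSE)
  list(n_se = length(se_genes), n_te = length(te_genes),
       shift = stats::median(a) - stats::median(b), p = wt$p.value)
}

#' Cis and trans SE-SE interaction enrichment
#'
#' Cis: per-pair O/E between SE bins, against a distance-matched sample of
#' TE-pair O/E values. Trans: observed inter-chromosomal SE-bin contact rate
#' over the uniform expectation. A one-sided Wilcoxon compares the cis SE-SE
#' enrichment distribution against the trans SE-SE enrichment distribution.
#'
#' @param se_bins,te_bins 0-based bins of SE and TE elements on the cis
#'   chromosome.
#' @param cm_oe O/E-state cis [contact_matrix()].
#' @param trans_mat Dense trans count matrix (rows = this chromosome's bins).
#' @param max_dist Maximum cis pair distance in bins (default 200).
#' @return list(`cis_se` O/E values, `cis_te` matched TE values, `trans_se`
#'   per-pair enrichment, `cis_over_te` ratio of medians, `trans_enrichment`
#'   mean, `p_cis_gt_trans`).
#' @export
se_interaction_enrichment <- function(se_bins, te_bins, cm_oe, trans_mat,
                                      max_dist = 200L) {
  n <- cm_oe$bin_table$n_bins
  key <- cm_oe$i * as.numeric(n) + cm_oe$j
  oe_at <- function(i, j) {
    a <- pmin(i, j); b <- pmax(i, j)
    v <- cm_oe$value[match(a * as.numeric(n) + b, key)]
    v[is.na(v)] <- 0
    v
  }
  pair_up <- function(bins) {
    if (length(bins) < 2) return(NULL)
    pr <- t(utils::combn(sort(bins), 2))
    d <- pr[, 2] - pr[, 1]
    ok <- d >= 2 & d <= max_dist
    if (!any(ok)) return(NULL)
    cbind(pr[ok, , drop = FALSE], d[ok])
  }
  se_pr <- pair_up(se_bins)
  if (is.null(se_pr)) stop("no SE pairs within the cis distance range")
  cis_se <- oe_at(se_pr[, 1], se_pr[, 2])
  ## distance-matched TE background
  te_pr <- pair_up(te_bins)
  cis_te <- numeric(0)
  if (!is.null(te_pr)) {
    for (k in seq_len(nrow(se_pr))) {
      dd <- abs(te_pr[, 3] - se_pr[k, 3])
      near <- which(dd <= stats::quantile(dd, 0.25))
      cis_te <- c(cis_te, oe_at(te_pr[near, 1], te_pr[near, 2]))
    }
  }
  ## trans: SE rows of the trans matrix vs the uniform expectation
  mu <- mean(trans_mat)
  trans_se <- as.numeric(trans_mat[se_bins + 1L, , drop = FALSE]) / mu
  wt <- stats::wilcox.test(cis_se, trans_se, alternative = "greater",
                           exact = FALSE)
  list(cis_se = cis_se, cis_te = cis_te, trans_se = trans_se,
       cis_over_te = stats::median(cis_se) /
         max(stats::median(cis_te), .Machine$double.eps),
       trans_enrichment = mean(trans_se),
       p_cis_gt_trans = wt$p.value)
}
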