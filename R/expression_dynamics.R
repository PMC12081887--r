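#' Filter unexpressed genes
#'
#' Removes genes whose FPKM stays below `min_fpkm` in every stage (stage
#' values are per-stage means over samples).
#'
#' @param et An [expression_table()].
#' @param min_fpkm Expression floor (default 0.5).
#' @return Filtered [expression_table()]; empty results are allowed, with a
#'   warning.
#' @export
filter_expressed <- function(et, min_fpkm = 0.5) {
  stopifnot(inherits(et, "expression_table"))
  sm <- stage_means(et)
  keep <- apply(sm, 1, function(v) any(v >= min_fpkm))
  if (!any(keep)) warning("no gene passes the expression filter")
  expression_table(et$fpkm[keep, , drop = FALSE], et$samples)
}

#' Fuzzy c-means soft clustering of stage trajectories
#'
#' Per-gene stage profiles (mean FPKM per stage, log2) are standardized
#' (z-score over stages) and clustered with fuzzy c-means (membership
#' exponent `m`), following the convention of time-course soft-clustering
#' packages. Memberships are in `[0, 1]` and sum to 1 per gene.
#'
#' @param et A filtered [expression_table()].
#' @param c Number of clusters.
#' @param m Fuzzifier (default 2).
#' @param seed Seed for the centroid initialization.
#' @param max_iter,tol Convergence controls.
#' @return Object of class `soft_clustering`: `membership` (genes x c),
#'   `centroids` (c x stages), `cluster` (argmax assignment),
#'   `max_membership`, `m`, `c`.
#' @export
soft_cluster <- function(et, c, m = 2, seed = 1L, max_iter = 200,
                         tol = 1e-6) {
  stopifnot(inherits(et, "expression_table"), c >= 2)
  prof <- log2(stage_means(et) + 1)
  if (c >= nrow(prof)) stop("c must be smaller than the number of genes")
  z <- t(apply(prof, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  set.seed(seed)
  fit <- e1071::cmeans(z, centers = c, m = m, iter.max = max_iter,
                       dist = "euclidean", method = "cmeans")
  memb <- fit$membership
  rownames(memb) <- rownames(prof)
  structure(list(membership = memb, centroids = fit$centers,
                 cluster = apply(memb, 1, which.max),
                 max_membership = apply(memb, 1, max),
                 m = m, c = c, stages = colnames(prof)),
            class = "soft_clustering")
}

#' @export
print.soft_clustering <- function(x, ...) {
  cat(sprintf("<soft_clustering> %d genes x %d clusters (fuzzifier %.1f); %d confident members\n",
              nrow(x$membership), x$c, x$m, sum(x$max_membership > 0.5)))
  invisible(x)
}

#' Confidently assigned genes per cluster
#'
#' Genes whose maximal membership strictly exceeds `min_membership`;
#' all others stay unassigned.
#'
#' @param clustering A [soft_cluster()] result.
#' @param min_membership Strict membership threshold (default 0.5).
#' @return Named list of gene-id vectors, one per cluster.
#' @export
confident_members <- function(clustering, min_membership = 0.5) {
  stopifnot(inherits(clustering, "soft_clustering"))
  ok <- clustering$max_membership > min_membership
  split(rownames(clustering$membership)[ok],
        factor(clustering$cluster[ok], levels = seq_len(clustering$c)))
}

#' Screen the cluster count by minimum centroid distance
#'
#' Fits [soft_cluster()] over a range of c and reports the minimum pairwise
#' centroid distance for each; an elbow (sharp drop) marks where clusters
#' start splitting real shapes.
#'
#' @param et A filtered [expression_table()].
#' @param c_range Candidate cluster counts (default 2:12).
#' @param seed Seed passed to each fit.
#' @return data.frame `c`, `min_centroid_dist`.
#' @export
screen_cluster_count <- function(et, c_range = 2:12, seed = 1L) {
  c_range <- c_range[c_range < nrow(et$fpkm)]
  rows <- lapply(c_range, function(cc) {
    cl <- soft_cluster(et, c = cc, seed = seed)
    dd <- stats::dist(cl$centroids)
    data.frame(c = cc, min_centroid_dist = min(dd))
  })
  do.call(rbind, rows)
}
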