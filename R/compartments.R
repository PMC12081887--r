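#' Principal components of the contact correlation matrix
#'
#' Top-k eigenvectors of the mean-centered Pearson correlation matrix of O/E
#' rows, computed over unmasked bins and ordered by eigenvalue. The plaid
#' compartment pattern dominates one of the leading components; which one is
#' decided later against gene density.
#'
#' @param cc Dense correlation matrix from [correlation_matrix()].
#' @param k Number of components (default 3).
#' @return `n x k` matrix of eigenvectors (`NA` rows at masked bins), with
#'   attribute `eigenvalues`.
#' @export
compute_pcs <- function(cc, k = 3) {
  n <- nrow(cc)
  un <- which(!is.na(diag(cc)))
  if (length(un) < k + 1) stop("degenerate correlation matrix")
  sub <- cc[un, un, drop = FALSE]
  sub <- sweep(sub, 2, colMeans(sub))       # mean-center
  sub <- (sub + t(sub)) / 2                 # keep exactly symmetric
  eg <- eigen(sub, symmetric = TRUE)
  if (all(abs(eg$values) < 1e-12)) stop("rank-zero correlation matrix")
  pcs <- matrix(NA_real_, n, k)
  pcs[un, ] <- eg$vectors[, seq_len(k)]
  colnames(pcs) <- paste0("PC", seq_len(k))
  attr(pcs, "eigenvalues") <- eg$values[seq_len(k)]
  pcs
}

#' Select the compartment-tracking PC and orient it by gene density
#'
#' The compartment component is the PC with the largest absolute Pearson
#' correlation against the gene-density track (ties broken by lower PC
#' index); its sign is flipped if that correlation is negative, so that
#' positive values mean the gene-dense active (A) compartment. If no PC
#' reaches `min_cor` the profile is flagged unresolved and carries no labels.
#'
#' @param pcs Output of [compute_pcs()].
#' @param gene_density Per-bin gene-count track.
#' @param bt The [bin_table()] of the profile.
#' @param min_cor Correlation floor below which selection fails (default 0.1).
#' @return Object of class `compartment_profile`: fields `pc` (oriented
#'   values), `label` ("A"/"B"/NA), `selected_pc`, `cor_with_density`,
#'   `unresolved`, `pcs`, `bin_table`.
#' @export
select_and_orient <- function(pcs, gene_density, bt, min_cor = 0.1) {
  stopifnot(nrow(pcs) == length(gene_density), nrow(pcs) == bt$n_bins)
  ok <- !is.na(pcs[, 1]) & !is.na(gene_density)
  cors <- apply(pcs, 2, function(v)
    suppressWarnings(stats::cor(v[ok], gene_density[ok])))
  cors[is.na(cors)] <- 0
  best <- which.max(abs(cors))          # ties: which.max takes the first
  unresolved <- abs(cors[best]) < min_cor
  pc <- pcs[, best]
  if (!unresolved && cors[best] < 0) pc <- -pc
  label <- rep(NA_character_, length(pc))
  if (!unresolved) label[!is.na(pc)] <- ifelse(pc[!is.na(pc)] > 0, "A", "B")
  structure(list(bin_table = bt, pc = if (unresolved) pcs[, best] else pc,
                 label = label, selected_pc = unname(best),
                 cor_with_density = cors, unresolved = unresolved, pcs = pcs),
            class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, ...) {
  if (x$unresolved) {
    cat("<compartment_profile> unresolved: no PC tracks gene density\n")
  } else {
    cat(sprintf("<compartment_profile> PC%d selected (|r|=%.2f with gene density): %d A / %d B bins\n",
                x$selected_pc, abs(x$cor_with_density[x$selected_pc]),
                sum(x$label == "A", na.rm = TRUE),
                sum(x$label == "B", na.rm = TRUE)))
  }
  invisible(x)
}

#' Full compartment call from a balanced matrix
#'
#' Convenience wrapper: O/E, correlation matrix, PCs, selection/orientation.
#'
#' @param cm Balanced [contact_matrix()] (100-kb resolution typical).
#' @param gene_density Per-bin gene-count track.
#' @param k Number of PCs to consider (default 3).
#' @param min_cor Selection floor, see [select_and_orient()].
#' @return A `compartment_profile`.
#' @export
call_compartments <- function(cm, gene_density, k = 3, min_cor = 0.1) {
  oe <- if (cm$state == "oe") cm else observed_over_expected(cm)
  cc <- correlation_matrix(oe)
  pcs <- compute_pcs(cc, k = k)
  select_and_orient(pcs, gene_density, cm$bin_table, min_cor = min_cor)
}

#' Classify per-bin compartment switches between two profiles
#'
#' @param profile_ref,profile_query Two `compartment_profile`s on the same
#'   bin table.
#' @return Character vector per bin: `"A->A"`, `"A->B"`, `"B->A"`, `"B->B"`,
#'   or `NA` where either profile is unlabeled.
#' @export
classify_switches <- function(profile_ref, profile_query) {
  stopifnot(inherits(profile_ref, "compartment_profile"),
            inherits(profile_query, "compartment_profile"),
            profile_ref$bin_table$n_bins == profile_query$bin_table$n_bins)
  a <- profile_ref$label; b <- profile_query$label
  out <- rep(NA_character_, length(a))
  ok <- !is.na(a) & !is.na(b)
  out[ok] <- paste0(a[ok], "->", b[ok])
  out
}

#' Per-bin compartment dynamics across stages (one-way ANOVA)
#'
#' Tests, per bin, whether the oriented PC value varies across developmental
#' stages, with the supplied samples (replicates, or regions treated as
#' replicates) as observations. P-values are BH-adjusted genome-wide; bins
#' with `q < fdr` are flagged dynamic.
#'
#' @param pc_matrix bins x samples matrix of oriented PC values.
#' @param stages Stage label per sample (length = ncol).
#' @param fdr BH threshold for the dynamic flag (default 0.05).
#' @param var_equal Pool variances across stages (classical ANOVA F,
#'   default TRUE); `FALSE` gives Welch's correction.
#' @return data.frame per bin: `F`, `p`, `q`, `dynamic`.
#' @export
compartment_dynamics <- function(pc_matrix, stages, fdr = 0.05,
                                 var_equal = TRUE) {
  stopifnot(is.matrix(pc_matrix), ncol(pc_matrix) == length(stages))
  stages <- factor(stages)
  if (nlevels(stages) < 2) stop("need at least 2 stages")
  if (min(table(stages)) < 2)
    stop("each stage needs >= 2 samples (replicates or regions)")
  n <- nrow(pc_matrix)
  Fv <- rep(NA_real_, n); pv <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    y <- pc_matrix[b, ]
    if (anyNA(y)) next
    if (stats::var(y) == 0) { Fv[b] <- 0; pv[b] <- 1; next }
    ft <- tryCatch(stats::oneway.test(y ~ stages, var.equal = var_equal),
                   error = function(e) NULL)
    if (!is.null(ft)) { Fv[b] <- unname(ft$statistic); pv[b] <- ft$p.value }
  }
  q <- rep(NA_real_, n)
  ok <- !is.na(pv)
  q[ok] <- stats::p.adjust(pv[ok], method = "BH")
  data.frame(F = Fv, p = pv, q = q, dynamic = !is.na(q) & q < fdr)
}

#' Compartment strength via a saddle decomposition
#'
#' Unmasked bins are ranked by PC value into `n_quantiles` groups; the
#' saddle grid is the mean O/E per group pair. Strength is
#' `(mean AA corner + mean BB corner) / (2 * mean AB corner)`, with corners
#' the outermost quantile groups. Shuffled labels give strength ~ 1.
#'
#' @param cm_oe O/E-state [contact_matrix()].
#' @param profile A `compartment_profile` (or numeric PC vector).
#' @param n_quantiles Number of PC rank groups (default 5).
#' @param min_dist_bins Pixels closer than this are excluded so the diagonal
#'   does not dominate (default 2).
#' @return list(`strength`, `saddle` matrix, `n_quantiles`).
#' @export
compartment_strength <- function(cm_oe, profile, n_quantiles = 5,
                                 min_dist_bins = 2) {
  stopifnot(inherits(cm_oe, "contact_matrix"), cm_oe$state == "oe")
  pc <- if (inherits(profile, "compartment_profile")) profile$pc else profile
  stopifnot(length(pc) == cm_oe$bin_table$n_bins)
  ok_bin <- !is.na(pc) & cm_oe$mask
  grp <- rep(NA_integer_, length(pc))
  rk <- rank(pc[ok_bin], ties.method = "first")
  grp[ok_bin] <- as.integer(cut(rk, breaks = n_quantiles, labels = FALSE))
  keep <- !is.na(grp[cm_oe$i + 1L]) & !is.na(grp[cm_oe$j + 1L]) &
    (cm_oe$j - cm_oe$i) >= min_dist_bins
  gi <- grp[cm_oe$i[keep] + 1L]; gj <- grp[cm_oe$j[keep] + 1L]
  v <- cm_oe$value[keep]
  saddle <- matrix(NA_real_, n_quantiles, n_quantiles)
  for (a in seq_len(n_quantiles)) for (b in a:n_quantiles) {
    sel <- (gi == a & gj == b) | (gi == b & gj == a)
    if (any(sel)) saddle[a, b] <- saddle[b, a] <- mean(v[sel])
  }
  bb <- saddle[1, 1]; aa <- saddle[n_quantiles, n_quantiles]
  ab <- saddle[1, n_quantiles]
  strength <- if (is.na(ab) || ab == 0) NA_real_ else (aa + bb) / (2 * ab)
  list(strength = strength, saddle = saddle, n_quantiles = n_quantiles)
}

#' Expression shift of compartment-switching genes
#'
#' Genes are assigned to bins by TSS; the log2 FPKM change between two
#' sample groups is compared between genes in a given switch class (default
#' B->A) and all genes, by a one-sided Wilcoxon rank-sum test in the
#' direction the class implies (B->A up, A->B down).
#'
#' @param switches Per-bin switch classes from [classify_switches()].
#' @param et An [expression_table()].
#' @param genes [gene_models()] output.
#' @param bt The [bin_table()] of the switch classes.
#' @param ref_samples,query_samples Column names of the two groups; the
#'   change is query minus ref.
#' @param class Switch class to test (default `"B->A"`).
#' @return list(`class`, `n_genes`, `shift` = median change difference,
#'   `p`, `alternative`), or NULL with a warning when the class is empty.
#' @export
switch_expression_test <- function(switches, et, genes, bt,
                                   ref_samples, query_samples,
                                   class = "B->A") {
  stopifnot(inherits(et, "expression_table"))
  gb <- promoter_bins(genes, bt)
  keep <- !is.na(gb) & genes$gene %in% rownames(et$fpkm)
  gb <- gb[keep]; gid <- genes$gene[keep]
  lfc <- log2(rowMeans(et$fpkm[gid, query_samples, drop = FALSE]) + 1) -
    log2(rowMeans(et$fpkm[gid, ref_samples, drop = FALSE]) + 1)
  in_class <- !is.na(switches[gb + 1L]) & switches[gb + 1L] == class
  if (!any(in_class)) {
    warning("no genes in switch class ", class)
    return(NULL)
  }
  alternative <- if (class == "B->A") "greater"
  else if (class == "A->B") "less" else "two.sided"
  wt <- stats::wilcox.test(lfc[in_class], lfc, alternative = alternative,
                           exact = FALSE)
  list(class = class, n_genes = sum(in_class),
       shift = stats::median(lfc[in_class]) - stats::median(lfc),
       p = wt$p.value, alternative = alternative)
}
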