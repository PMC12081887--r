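#' Specification for a synthetic Hi-C study
#'
#' Defines one synthetic chromosome and every planted feature the downstream
#' callers are validated against: power-law distance decay, plaid compartment
#' structure coupled to gene density, TAD blocks, focal loops with shoulders,
#' per-bin multiplicative biases, H3K27ac peak clusters forming
#' super-enhancers, stage/region expression coupled to compartment status and
#' loop strength, and intergenic SNPs looped to promoters.
#'
#' The expected intensity of pixel (i, j) at bin distance d = j - i is
#' `lambda_ij = L * (d+1)^(-alpha) * (1 + a * c_i * c_j) * T_ij * P_ij * b_i * b_j`
#' where `c` is the per-bin compartment sign, `T_ij = tau` when i and j share
#' a TAD, `P_ij = phi` at planted loop pixels (phi/2 on the 1-bin shoulder)
#' and `b` are per-bin biases; counts are Poisson(lambda).
#'
#' @param chrom_length Chromosome length in bp (default 20 Mb).
#' @param resolution Bin size in bp (default 40 kb).
#' @param library_size Expected total upper-triangle count mass; default
#'   `2000 * n_bins`.
#' @param alpha Distance-decay exponent (default 1).
#' @param plaid_amp Compartment plaid amplitude `a` in `[0, 1)` (default 0.4).
#' @param comp_block_range Compartment block lengths, bp (default 1-3 Mb).
#' @param switch_frac Fraction of compartment blocks that flip sign between
#'   the first and last developmental stage (default 0.15).
#' @param tad_len_range TAD lengths, bp (default 0.4-1.2 Mb).
#' @param tau Within-TAD contact enrichment (default 2.5).
#' @param n_loops Number of generic planted loops (default 30).
#' @param phi Loop fold enrichment (default 5).
#' @param loop_dist_range Loop anchor separation, bp (default 0.2-1 Mb).
#' @param frac_promoter_loops Fraction of generic loops re-anchored onto a
#'   gene promoter bin (default 0.5).
#' @param frac_loops_in_tad Fraction of planted loops (all types) whose
#'   anchors share a TAD (default 0.9; loops are overwhelmingly intra-domain
#'   in real genomes).
#' @param bias_range Per-bin biases drawn log-uniform over this range
#'   (default c(0.5, 2)); `c(1, 1)` disables biases.
#' @param n_dead_bins Bins zeroed out entirely, to exercise masking
#'   (default 2).
#' @param n_genes Number of genes (default 400).
#' @param gene_density_contrast Relative TSS density in A vs B bins
#'   (default 3).
#' @param n_se Number of super-enhancer loci (default 6).
#' @param n_te_clusters Number of typical-enhancer clusters of 3-4 weak
#'   constituents (default 15); these stitch into valid regions and form
#'   the TE class after the rank split.
#' @param n_te_peaks Number of isolated typical-enhancer peaks (default 60;
#'   these fail the constituent filter and exercise it).
#' @param se_signal,te_signal Per-constituent H3K27ac signal levels
#'   (arbitrary units; defaults 60 and 8).
#' @param phi_se Fold enrichment of SE-to-promoter and SE-to-SE loops
#'   (default 6).
#' @param n_se_pairs Number of planted cis SE-SE loops (default 4).
#' @param n_stages,n_regions Sample grid (defaults 5 stages x 3 regions).
#' @param beta_comp,beta_loop,beta_se Expression coupling coefficients on the
#'   log2-FPKM scale (defaults 1, 0.5, 2; super-enhancer targets are
#'   typically several-fold above typical-enhancer targets).
#' @param traj_frac Fraction of genes given a monotone stage trend, split
#'   evenly between rising and falling shapes (default 0.5).
#' @param trend_amp Peak-to-trough amplitude of stage trends, log2 units
#'   (default 3).
#' @param expr_noise_sd Gaussian noise on log2 FPKM (default 0.5).
#' @param n_index_snps Number of GWAS index SNPs passing the association
#'   threshold (default 30).
#' @param frac_linked_snps Fraction of index SNPs placed in distal loop
#'   anchors of gene promoters (default 0.5).
#' @param n_null_snps SNPs with association p above 1e-6, to exercise
#'   filtering (default 20).
#' @param max_dist_bins Only pixels with bin distance up to this are
#'   generated (NULL = full triangle).
#' @param seed Integer seed fixing every draw.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(chrom_length = 2e7, resolution = 4e4,
                           library_size = NULL, alpha = 1,
                           plaid_amp = 0.4, comp_block_range = c(1e6, 3e6),
                           switch_frac = 0.15,
                           tad_len_range = c(4e5, 1.2e6), tau = 2.5,
                           n_loops = 30, phi = 5,
                           loop_dist_range = c(2e5, 1e6),
                           frac_promoter_loops = 0.5,
                           frac_loops_in_tad = 0.9,
                           bias_range = c(0.5, 2), n_dead_bins = 2,
                           n_genes = 400, gene_density_contrast = 3,
                           n_se = 6, n_te_clusters = 15, n_te_peaks = 60,
                           se_signal = 60, te_signal = 8,
                           phi_se = 6, n_se_pairs = 4,
                           n_stages = 5, n_regions = 3,
                           beta_comp = 1, beta_loop = 0.5, beta_se = 2,
                           traj_frac = 0.5, trend_amp = 3,
                           expr_noise_sd = 0.5,
                           n_index_snps = 30, frac_linked_snps = 0.5,
                           n_null_snps = 20,
                           max_dist_bins = NULL, seed = 1L) {
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  if (is.null(library_size)) library_size <- 2000 * n_bins
  spec <- list(chrom = "chrS", chrom_length = chrom_length,
               resolution = resolution, n_bins = n_bins,
               library_size = library_size, alpha = alpha,
               plaid_amp = plaid_amp, comp_block_range = comp_block_range,
               switch_frac = switch_frac,
               tad_len_range = tad_len_range, tau = tau,
               n_loops = n_loops, phi = phi,
               loop_dist_range = loop_dist_range,
               frac_promoter_loops = frac_promoter_loops,
               frac_loops_in_tad = frac_loops_in_tad,
               bias_range = bias_range, n_dead_bins = n_dead_bins,
               n_genes = n_genes,
               gene_density_contrast = gene_density_contrast,
               n_se = n_se, n_te_clusters = n_te_clusters,
               n_te_peaks = n_te_peaks,
               se_signal = se_signal, te_signal = te_signal,
               phi_se = phi_se, n_se_pairs = n_se_pairs,
               n_stages = n_stages, n_regions = n_regions,
               beta_comp = beta_comp, beta_loop = beta_loop,
               beta_se = beta_se,
               traj_frac = traj_frac, trend_amp = trend_amp,
               expr_noise_sd = expr_noise_sd,
               n_index_snps = n_index_snps,
               frac_linked_snps = frac_linked_snps,
               n_null_snps = n_null_snps,
               max_dist_bins = max_dist_bins, seed = as.integer(seed))
  stopifnot(plaid_amp >= 0, plaid_amp < 1, tau >= 1, phi >= 0,
            all(unlist(spec$bias_range) > 0), alpha >= 0)
  class(spec) <- "synthetic_spec"
  spec
}

#' A structureless null version of a synthetic spec
#'
#' Pure distance decay: no plaid, no TADs, no loops, no biases, no dead
#' bins. Used for caller calibration.
#'
#' @param spec A [synthetic_spec()].
#' @return Modified spec.
#' @export
null_spec <- function(spec) {
  spec$plaid_amp <- 0; spec$tau <- 1; spec$n_loops <- 0
  spec$bias_range <- c(1, 1); spec$n_dead_bins <- 0
  spec$n_se <- 0; spec$n_se_pairs <- 0; spec$n_te_clusters <- 0
  spec$n_index_snps <- 0; spec$frac_linked_snps <- 0
  spec
}

#' Generate the planted ground truth layout for a synthetic spec
#'
#' Decides everything that is fixed before count sampling: compartment signs
#' per stage, TAD segmentation and boundary bins, gene models, SE loci and
#' constituents, TE peaks, SNP positions, the full planted loop list (generic,
#' promoter-anchored, SE-promoter, SE-SE, SNP-promoter), per-bin biases, and
#' the per-gene expression drivers.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `ground_truth` (a list; see fields in source).
#' @export
generate_ground_truth <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_bins; res <- spec$resolution; len <- spec$chrom_length
  bt <- bin_table(spec$chrom, len, res)

  ## TAD segmentation first; edges snapped to bins so the planted truth is
  ## expressible at the working resolution
  tedges <- 0
  while (tedges[length(tedges)] < len)
    tedges <- c(tedges, tedges[length(tedges)] +
                  res * round(stats::runif(1, spec$tad_len_range[1],
                                           spec$tad_len_range[2]) / res))
  tedges[length(tedges)] <- len
  tad_of_bin <- findInterval(bt$start, tedges, rightmost.closed = TRUE)
  boundary_bins <- bin_index(bt, tedges[-c(1, length(tedges))])
  tads <- data.frame(chrom = spec$chrom,
                     start = tedges[-length(tedges)], end = tedges[-1])

  ## compartment blocks = contiguous runs of whole TADs (compartment
  ## boundaries coincide with domain boundaries, as in real genomes),
  ## alternating sign, with block lengths near the requested range
  n_tads <- length(tedges) - 1L
  blk_of_tad <- integer(n_tads)
  blk <- 1L; acc <- 0
  target <- stats::runif(1, spec$comp_block_range[1], spec$comp_block_range[2])
  for (t in seq_len(n_tads)) {
    blk_of_tad[t] <- blk
    acc <- acc + (tedges[t + 1L] - tedges[t])
    if (acc >= target && t < n_tads) {
      blk <- blk + 1L; acc <- 0
      target <- stats::runif(1, spec$comp_block_range[1],
                             spec$comp_block_range[2])
    }
  }
  n_blk <- max(blk_of_tad)
  blk_sign <- rep_len(c(1, -1), n_blk)
  if (stats::runif(1) < 0.5) blk_sign <- -blk_sign
  blk_of_bin <- blk_of_tad[tad_of_bin]
  edges <- tedges[c(1L, which(diff(blk_of_tad) != 0) + 1L, n_tads + 1L)]
  c_early <- blk_sign[blk_of_bin]
  ## stage switching: flip a fraction of blocks in the late stages
  n_flip <- round(spec$switch_frac * n_blk)
  flip_blocks <- if (n_flip > 0) sample.int(n_blk, n_flip) else integer()
  blk_sign_late <- blk_sign
  blk_sign_late[flip_blocks] <- -blk_sign_late[flip_blocks]
  c_late <- blk_sign_late[blk_of_bin]

  ## genes: TSS density coupled to early-stage compartment sign
  w <- ifelse(c_early > 0, spec$gene_density_contrast, 1)
  gene_bin <- sample.int(n, spec$n_genes, replace = TRUE, prob = w) - 1L
  tss <- pmin(len - 1, gene_bin * res + floor(stats::runif(spec$n_genes, 0, res)))
  strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
  glen <- round(stats::runif(spec$n_genes, 5e3, 5e4))
  gstart <- ifelse(strand == "+", tss, pmax(0, tss - glen))
  gend <- ifelse(strand == "+", pmin(len, tss + glen), tss + 1)
  genes <- data.frame(gene = sprintf("G%04d", seq_len(spec$n_genes)),
                      chrom = spec$chrom, start = gstart, end = gend,
                      strand = strand, tss = tss,
                      bin = gene_bin, stringsAsFactors = FALSE)

  ## loop list; keep planted pixels Chebyshev-separated so the neighborhood
  ## filter sees isolated peaks
  min_sep <- 6L
  d_rng <- pmax(2L, round(spec$loop_dist_range / res))
  loops <- data.frame(i = integer(), j = integer(), phi = numeric(),
                      type = character(), gene = character(),
                      se = integer(), snp = character(),
                      stringsAsFactors = FALSE)
  too_close <- function(i, j) {
    nrow(loops) > 0 &&
      any(pmax(abs(loops$i - i), abs(loops$j - j)) < min_sep)
  }
  ## target the within-TAD fraction directly: decide per loop whether it
  ## must be intra-TAD, then retry attempts until one matches
  cur_want <- stats::runif(1) < spec$frac_loops_in_tad
  tad_ok <- function(i, j)
    (tad_of_bin[i + 1L] == tad_of_bin[j + 1L]) == cur_want
  add_loop <- function(i, j, phi, type, gene = NA_character_,
                       se = NA_integer_, snp = NA_character_) {
    if (i > j) { t <- i; i <- j; j <- t }
    if (j - i < 2L || j >= n || i < 0 || too_close(i, j)) return(FALSE)
    loops[nrow(loops) + 1L, ] <<- list(i, j, phi, type, gene, se, snp)
    TRUE
  }

  ## super-enhancer loci (bins), kept apart
  se_bin <- integer()
  guard <- 0
  while (length(se_bin) < spec$n_se && guard < 2000) {
    guard <- guard + 1
    cand <- sample(seq(10L, n - 11L), 1L)
    if (!length(se_bin) || min(abs(se_bin - cand)) > 25L) se_bin <- c(se_bin, cand)
  }
  se_tbl <- NULL
  if (length(se_bin)) {
    se_tbl <- do.call(rbind, lapply(seq_along(se_bin), function(k) {
      nk <- sample(4:6, 1)
      width <- round(stats::runif(nk, 1000, 2000))
      gap <- round(stats::runif(nk - 1, 2000, 8000))
      s0 <- se_bin[k] * res + 1000
      starts <- s0 + cumsum(c(0, width[-nk] + gap))
      data.frame(se_id = k, locus_bin = se_bin[k],
                 start = starts, end = starts + width,
                 signal = spec$se_signal * stats::runif(nk, 0.8, 1.2))
    }))
    ## one SE -> promoter loop each, preferring genes in the SE's TAD
    for (k in seq_along(se_bin)) {
      ok <- which(abs(genes$bin - se_bin[k]) >= d_rng[1] &
                    abs(genes$bin - se_bin[k]) <= d_rng[2] &
                    genes$bin != se_bin[k])
      same <- ok[tad_of_bin[genes$bin[ok] + 1L] == tad_of_bin[se_bin[k] + 1L]]
      pool <- if (length(same)) same else ok
      if (length(pool)) {
        g <- if (length(pool) == 1) pool else sample(pool, 1)
        add_loop(se_bin[k], genes$bin[g], spec$phi_se, "se_promoter",
                 gene = genes$gene[g], se = k)
      }
    }
    ## cis SE-SE loops
    pairs <- which(outer(se_bin, se_bin, function(a, b) abs(a - b)) >= d_rng[1] &
                     outer(se_bin, se_bin, function(a, b) abs(a - b)) <= 2 * d_rng[2],
                   arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      take <- utils::head(sample(nrow(pairs)), spec$n_se_pairs)
      for (r in take)
        add_loop(se_bin[pairs[r, 1]], se_bin[pairs[r, 2]], spec$phi_se,
                 "se_se", se = pairs[r, 1])
    }
  }

  ## typical-enhancer clusters: 3-4 weak constituents, stitchable
  te_cl <- NULL
  if (spec$n_te_clusters > 0) {
    cl_bins <- integer(); guard <- 0
    avoid <- se_bin
    while (length(cl_bins) < spec$n_te_clusters && guard < 2000) {
      guard <- guard + 1
      cand <- sample(seq(5L, n - 6L), 1L)
      if (!length(c(avoid, cl_bins)) ||
          min(abs(c(avoid, cl_bins) - cand)) > 10L)
        cl_bins <- c(cl_bins, cand)
    }
    te_cl <- do.call(rbind, lapply(cl_bins, function(b) {
      nk <- sample(3:4, 1)
      width <- round(stats::runif(nk, 800, 1500))
      gap <- round(stats::runif(nk - 1, 3000, 9000))
      s0 <- b * res + 1000
      starts <- s0 + cumsum(c(0, width[-nk] + gap))
      data.frame(start = starts, end = starts + width,
                 signal = spec$te_signal * stats::runif(nk, 0.6, 1.4))
    }))
    ## typical enhancers loop to promoters too (ordinary strength, no
    ## expression boost) so TE-linked genes exist for comparison tests
    for (b in cl_bins) {
      ok <- which(abs(genes$bin - b) >= d_rng[1] &
                    abs(genes$bin - b) <= d_rng[2] & genes$bin != b)
      same <- ok[tad_of_bin[genes$bin[ok] + 1L] == tad_of_bin[b + 1L]]
      pool <- if (length(same)) same else ok
      if (length(pool)) {
        g <- if (length(pool) == 1) pool else sample(pool, 1)
        add_loop(b, genes$bin[g], spec$phi, "te_promoter",
                 gene = genes$gene[g])
      }
    }
  }

  ## TE peaks, isolated (> 12.5 kb from anything)
  occupied <- rbind(
    if (!is.null(se_tbl)) cbind(se_tbl$start, se_tbl$end),
    if (!is.null(te_cl)) cbind(te_cl$start, te_cl$end))
  if (is.null(occupied)) occupied <- matrix(numeric(), ncol = 2)
  te_starts <- numeric()
  guard <- 0
  while (length(te_starts) < spec$n_te_peaks && guard < 20 * spec$n_te_peaks) {
    guard <- guard + 1
    s <- stats::runif(1, 0, len - 2000)
    near <- any(abs(occupied[, 1] - s) < 15000 | abs(occupied[, 2] - s) < 15000)
    if (!near && (!length(te_starts) || min(abs(te_starts - s)) > 15000))
      te_starts <- c(te_starts, s)
  }
  te_tbl <- data.frame(start = round(te_starts),
                       end = round(te_starts) + round(stats::runif(length(te_starts), 800, 1500)),
                       signal = spec$te_signal * stats::runif(length(te_starts), 0.6, 1.4))
  if (!is.null(te_cl)) te_tbl <- rbind(te_cl, te_tbl)

  ## SNPs: linked index SNPs sit in distal anchors looped to promoters
  n_linked <- round(spec$frac_linked_snps * spec$n_index_snps)
  snp_list <- list()
  made <- 0; guard <- 0
  while (made < n_linked && guard < 50 * max(1, n_linked)) {
    guard <- guard + 1
    g <- sample.int(nrow(genes), 1)
    ## the intended link must be resolvable: no second promoter in the bin
    if (sum(genes$bin == genes$bin[g]) > 1) next
    d <- sample(seq(d_rng[1], d_rng[2]), 1)
    sbin <- genes$bin[g] + sample(c(-d, d), 1)
    if (sbin < 0 || sbin >= n || sbin == genes$bin[g]) next
    ## keep the SNP anchor intergenic-ish: not a promoter bin itself
    if (sbin %in% genes$bin) next
    if (!tad_ok(min(sbin, genes$bin[g]), max(sbin, genes$bin[g]))) next
    if (!add_loop(sbin, genes$bin[g], spec$phi_se, "snp_promoter",
                  gene = genes$gene[g],
                  snp = sprintf("rs%05d", 10000 + made + 1))) next
    made <- made + 1
    cur_want <- stats::runif(1) < spec$frac_loops_in_tad
    snp_list[[made]] <- data.frame(
      rsid = sprintf("rs%05d", 10000 + made),
      pos = sbin * res + round(stats::runif(1, 0.2, 0.8) * res),
      p = 10^-stats::runif(1, 7, 12), linked_gene = genes$gene[g],
      stringsAsFactors = FALSE)
  }
  ## unlinked index SNPs go to bins clear of any planted loop anchor, so
  ## "no intended link" really means no planted interaction
  anchor_bins <- unique(c(loops$i, loops$j))
  free_pos <- function() {
    for (a in 1:50) {
      p <- round(stats::runif(1, 0, len - 1))
      if (!length(anchor_bins) ||
          min(abs(bin_index(bt, p) - anchor_bins)) > 1) return(p)
    }
    p
  }
  n_unlinked <- spec$n_index_snps - length(snp_list)
  if (n_unlinked > 0) {
    for (k in seq_len(n_unlinked))
      snp_list[[length(snp_list) + 1L]] <- data.frame(
        rsid = sprintf("rs%05d", 20000 + k),
        pos = free_pos(),
        p = 10^-stats::runif(1, 7, 12), linked_gene = NA_character_,
        stringsAsFactors = FALSE)
  }
  snps <- if (length(snp_list)) do.call(rbind, snp_list) else
    data.frame(rsid = character(), pos = numeric(), p = numeric(),
               linked_gene = character(), stringsAsFactors = FALSE)

  ## generic loops, a fraction re-anchored at promoters; prefer within-TAD
  n_prom <- round(spec$frac_promoter_loops * spec$n_loops)
  made <- 0; guard <- 0
  while (made < spec$n_loops && guard < 100 * max(1, spec$n_loops)) {
    guard <- guard + 1
    promoter_loop <- made < n_prom
    if (promoter_loop) {
      g <- sample.int(nrow(genes), 1)
      d <- sample(seq(d_rng[1], d_rng[2]), 1)
      i <- genes$bin[g] + sample(c(-d, d), 1)
      j <- genes$bin[g]
      gene <- genes$gene[g]
    } else {
      i <- sample.int(n, 1) - 1L
      d <- sample(seq(d_rng[1], d_rng[2]), 1)
      j <- i + d
      gene <- NA_character_
    }
    if (is.na(j) || min(i, j) < 0 || max(i, j) >= n) next
    if (!tad_ok(min(i, j), max(i, j))) next
    if (add_loop(i, j, spec$phi,
                 if (promoter_loop) "promoter" else "generic", gene = gene)) {
      made <- made + 1
      cur_want <- stats::runif(1) < spec$frac_loops_in_tad
    }
  }

  ## per-bin biases, with a few dead bins
  b <- exp(stats::runif(n, log(spec$bias_range[1]), log(spec$bias_range[2])))
  dead <- if (spec$n_dead_bins > 0) sample.int(n, spec$n_dead_bins) else integer()
  b[dead] <- 0

  ## expression drivers
  traj <- sample(c(0L, 1L, 2L), spec$n_genes, replace = TRUE,
                 prob = c(1 - spec$traj_frac, spec$traj_frac / 2, spec$traj_frac / 2))
  baseline <- stats::rnorm(spec$n_genes, 3, 1)
  ## per-loop, per-stage strength trend for promoter-anchored loops
  loop_stage_strength <- NULL
  prom_loops <- which(!is.na(loops$gene) & loops$type %in% c("promoter", "se_promoter"))
  if (length(prom_loops)) {
    loop_stage_strength <- t(sapply(prom_loops, function(l) {
      dir <- sample(c(-1, 1), 1)
      1 + dir * seq(-0.4, 0.4, length.out = spec$n_stages)
    }))
    rownames(loop_stage_strength) <- as.character(prom_loops)
  }

  structure(list(
    spec = spec, bin_table = bt,
    c_early = c_early, c_late = c_late, flip_blocks = flip_blocks,
    comp_edges = edges,
    tad_edges = tedges, tads = tads, tad_of_bin = tad_of_bin,
    boundary_bins = boundary_bins,
    genes = genes, loops = loops,
    se = se_tbl, se_bins = se_bin, te = te_tbl,
    snps = snps, biases = b, dead_bins = dead,
    traj_class = traj, baseline = baseline,
    loop_stage_strength = loop_stage_strength),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d bins: %d boundaries, %d loops, %d SEs, %d genes, %d SNPs\n",
    x$spec$n_bins, length(x$boundary_bins), nrow(x$loops),
    length(x$se_bins), nrow(x$genes), nrow(x$snps)))
  invisible(x)
}

#' Compartment sign per bin at a given stage
#' @param truth A [generate_ground_truth()] object.
#' @param stage Stage index in `1..n_stages`.
#' @return +1/-1 vector per bin.
#' @export
truth_compartment <- function(truth, stage = 1) {
  if (stage <= ceiling(truth$spec$n_stages / 2)) truth$c_early else truth$c_late
}

#' Generate a raw synthetic Hi-C contact matrix
#'
#' Samples Poisson counts at the intensity model described in
#' [synthetic_spec()]. Biases are applied but not revealed in the returned
#' matrix (they live in the ground truth).
#'
#' @param spec A [synthetic_spec()].
#' @param truth Optional precomputed [generate_ground_truth()]; generated
#'   from `spec` if missing.
#' @param stage Stage whose compartment configuration is used (default 1).
#' @param seed_offset Added to `spec$seed` for the count draw, so several
#'   independent matrices can share one layout.
#' @return `list(matrix = contact_matrix raw, truth = ground_truth)`.
#' @export
generate_hic <- function(spec, truth = NULL, stage = 1, seed_offset = 1L) {
  if (is.null(truth)) truth <- generate_ground_truth(spec)
  n <- spec$n_bins
  max_d <- if (is.null(spec$max_dist_bins)) n - 1L else
    min(n - 1L, as.integer(spec$max_dist_bins))
  set.seed(spec$seed + seed_offset + 101L * (stage - 1L))

  cc <- truth_compartment(truth, stage)
  tad <- truth$tad_of_bin
  b <- truth$biases

  ## enumerate pixels by distance
  d_vec <- rep.int(0:max_d, n - (0:max_d))
  i <- unlist(lapply(0:max_d, function(d) 0:(n - 1L - d)), use.names = FALSE)
  j <- i + d_vec

  lam <- (d_vec + 1)^(-spec$alpha) *
    (1 + spec$plaid_amp * cc[i + 1L] * cc[j + 1L]) *
    ifelse(tad[i + 1L] == tad[j + 1L], spec$tau, 1)

  ## loop pixels and 1-bin shoulders at phi/2
  if (nrow(truth$loops)) {
    key <- i * as.numeric(n) + j
    mult <- rep(1, length(key))
    sh_key <- c(); sh_val <- c()
    for (r in seq_len(nrow(truth$loops))) {
      li <- truth$loops$i[r]; lj <- truth$loops$j[r]; ph <- truth$loops$phi[r]
      for (di in -1:1) for (dj in -1:1) {
        ii <- li + di; jj <- lj + dj
        if (ii < 0 || jj >= n || ii >= jj) next
        sh_key <- c(sh_key, ii * as.numeric(n) + jj)
        sh_val <- c(sh_val, if (di == 0 && dj == 0) ph else ph / 2)
      }
    }
    m <- match(sh_key, key)
    ok <- !is.na(m)
    mult[m[ok]] <- pmax(mult[m[ok]], sh_val[ok])
    lam <- lam * mult
  }

  L <- spec$library_size / sum(lam)
  if (!is.finite(L)) stop("degenerate spec: zero total intensity")
  lam <- L * lam * b[i + 1L] * b[j + 1L]
  if (max(lam) > 1e9) stop("spec implies overflowing intensities")
  counts <- stats::rpois(length(lam), lam)
  keep <- counts > 0
  cm <- contact_matrix(truth$bin_table, i[keep], j[keep], counts[keep],
                       state = "raw")
  list(matrix = cm, truth = truth, scale = L)
}

#' Generate ChIP-seq-like tracks and gene annotation from a ground truth
#'
#' CTCF peaks concentrate at planted TAD boundaries over a uniform
#' background; H3K27ac peaks are the SE constituent clusters plus isolated
#' TE peaks; gene models and a binned gene-density track come straight from
#' the planted genes.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param ctcf_background Expected number of background CTCF peaks
#'   (default 30; 0 puts every peak at a boundary).
#' @return list with `h3k27ac` (peak intervals with `score` = signal),
#'   `ctcf` (peak intervals), `genes` (gene models), `gene_density`
#'   (per-bin TSS count track).
#' @export
generate_tracks <- function(truth, ctcf_background = 30) {
  spec <- truth$spec
  set.seed(spec$seed + 7L)
  res <- spec$resolution; len <- spec$chrom_length
  ## CTCF: one peak near each boundary +/- < 1 bin, plus uniform background
  bpos <- truth$boundary_bins * res +
    round(stats::runif(length(truth$boundary_bins), -0.4, 0.4) * res)
  bpos <- pmin(pmax(bpos, 0), len - 400)
  nbg <- if (ctcf_background > 0) stats::rpois(1, ctcf_background) else 0
  cpos <- c(bpos, round(stats::runif(nbg, 0, len - 400)))
  ctcf <- data.frame(chrom = spec$chrom, start = cpos, end = cpos + 400,
                     name = sprintf("ctcf_%d", seq_along(cpos)),
                     score = stats::runif(length(cpos), 5, 50), strand = ".",
                     stringsAsFactors = FALSE)
  ## H3K27ac: SE constituents + TE peaks
  h3_parts <- list()
  if (!is.null(truth$se) && nrow(truth$se))
    h3_parts$se <- data.frame(chrom = spec$chrom, start = truth$se$start,
                              end = truth$se$end,
                              name = sprintf("se%d_c%d", truth$se$se_id,
                                             seq_len(nrow(truth$se))),
                              score = truth$se$signal, strand = ".",
                              stringsAsFactors = FALSE)
  if (nrow(truth$te))
    h3_parts$te <- data.frame(chrom = spec$chrom, start = truth$te$start,
                              end = truth$te$end,
                              name = sprintf("te_%d", seq_len(nrow(truth$te))),
                              score = truth$te$signal, strand = ".",
                              stringsAsFactors = FALSE)
  h3 <- if (length(h3_parts)) do.call(rbind, h3_parts) else empty_intervals()
  rownames(h3) <- NULL
  tss_iv <- data.frame(chrom = truth$genes$chrom, start = truth$genes$tss,
                       end = truth$genes$tss + 1)
  gene_density <- bin_signal(tss_iv, truth$bin_table, reducer = "count")
  list(h3k27ac = h3, ctcf = ctcf,
       genes = gene_models(truth$genes[, c("gene", "chrom", "start", "end", "strand")]),
       gene_density = gene_density)
}

#' Generate a stage x region expression table from a ground truth
#'
#' Per gene and sample, `log2 FPKM = baseline + beta_comp * 1[A bin at the
#' sample's stage] + beta_loop * (stage strength of a linked promoter loop) +
#' beta_se * 1[SE-linked] + stage trend (per trajectory class) + noise`.
#'
#' @param truth A [generate_ground_truth()] object.
#' @return An [expression_table()]; drivers are recorded in `truth`
#'   (`traj_class`, `loop_stage_strength`).
#' @export
generate_expression <- function(truth) {
  spec <- truth$spec
  set.seed(spec$seed + 13L)
  ng <- nrow(truth$genes)
  stages <- seq_len(spec$n_stages)
  regions <- sprintf("R%d", seq_len(spec$n_regions))
  samples <- expand.grid(region = regions, stage = stages,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_S%d", samples$region, samples$stage)

  se_linked <- truth$genes$gene %in%
    truth$loops$gene[truth$loops$type == "se_promoter"]
  prom_loops <- which(!is.na(truth$loops$gene) &
                        truth$loops$type %in% c("promoter", "se_promoter"))
  gene_loop <- match(truth$genes$gene, truth$loops$gene[prom_loops])

  trend <- matrix(0, ng, spec$n_stages)
  ramp <- seq(-0.5, 0.5, length.out = spec$n_stages) * spec$trend_amp
  for (cls in c(1L, 2L)) {
    sel <- truth$traj_class == cls
    if (any(sel))
      trend[sel, ] <- matrix(if (cls == 1L) ramp else -ramp, sum(sel),
                             spec$n_stages, byrow = TRUE)
  }

  fpkm <- matrix(0, ng, nrow(samples),
                 dimnames = list(truth$genes$gene, samples$sample))
  for (s in seq_len(nrow(samples))) {
    st <- samples$stage[s]
    cc <- truth_compartment(truth, st)
    in_a <- cc[truth$genes$bin + 1L] > 0
    loop_str <- rep(0, ng)
    if (length(prom_loops) && !is.null(truth$loop_stage_strength)) {
      has <- !is.na(gene_loop)
      loop_str[has] <- truth$loop_stage_strength[gene_loop[has], st]
    }
    lg <- truth$baseline + spec$beta_comp * in_a +
      spec$beta_loop * loop_str + spec$beta_se * se_linked +
      trend[, st] + stats::rnorm(ng, 0, spec$expr_noise_sd)
    fpkm[, s] <- 2^lg
  }
  expression_table(fpkm, samples)
}

#' Generate GWAS SNP and LD tables from a ground truth
#'
#' Emits the planted index SNPs (association p spanning 1e-12..1e-7), null
#' SNPs above the 1e-6 threshold, LD proxies within a 50-kb window at
#' varying r-squared (including one duplicate-position proxy to exercise
#' dedupe), and the intended SNP-to-gene link list.
#'
#' @param truth A [generate_ground_truth()] object.
#' @return list with `snps` (rsid, chrom, pos, p, trait), `ld` (index_rsid,
#'   proxy_rsid, chrom, pos, r2), `intended_links` (rsid, gene).
#' @export
generate_snps <- function(truth) {
  spec <- truth$spec
  set.seed(spec$seed + 19L)
  idx <- truth$snps
  nidx <- nrow(idx)
  null_snps <- if (spec$n_null_snps > 0)
    data.frame(rsid = sprintf("rs%05d", 30000 + seq_len(spec$n_null_snps)),
               pos = round(stats::runif(spec$n_null_snps, 0, spec$chrom_length - 1)),
               p = 10^-stats::runif(spec$n_null_snps, 3, 5.9),
               linked_gene = NA_character_, stringsAsFactors = FALSE)
  else idx[0, ]
  all_snps <- rbind(idx, null_snps)
  snps <- data.frame(rsid = all_snps$rsid, chrom = spec$chrom,
                     pos = all_snps$pos, p = all_snps$p,
                     trait = "synthetic_trait", stringsAsFactors = FALSE)
  ## LD proxies for index SNPs
  ld <- NULL
  if (nidx) {
    rows <- lapply(seq_len(nidx), function(k) {
      np <- sample(0:3, 1)
      if (np == 0) return(NULL)
      data.frame(index_rsid = idx$rsid[k],
                 proxy_rsid = sprintf("%s_p%d", idx$rsid[k], seq_len(np)),
                 chrom = spec$chrom,
                 pos = pmin(pmax(idx$pos[k] +
                                   round(stats::runif(np, -25000, 25000)), 0),
                            spec$chrom_length - 1),
                 r2 = round(stats::runif(np, 0.5, 1), 3),
                 stringsAsFactors = FALSE)
    })
    ld <- do.call(rbind, rows)
    if (!is.null(ld) && nrow(ld)) {
      ## one duplicate-position proxy to exercise position dedupe
      ld$pos[1] <- idx$pos[1]
      ld$r2[1] <- 0.95
    }
  }
  if (is.null(ld))
    ld <- data.frame(index_rsid = character(), proxy_rsid = character(),
                     chrom = character(), pos = numeric(), r2 = numeric(),
                     stringsAsFactors = FALSE)
  intended <- idx[!is.na(idx$linked_gene), c("rsid", "linked_gene")]
  names(intended) <- c("rsid", "gene")
  list(snps = snps, ld = ld, intended_links = intended)
}

#' Generate a uniform-background trans (inter-chromosomal) contact matrix
#'
#' A rectangular Poisson field with constant intensity; used as the null
#' background for trans SE-SE enrichment.
#'
#' @param spec A [synthetic_spec()].
#' @param n_bins_other Bin count of the partner chromosome.
#' @param mean_count Constant expected count per pixel (default 0.5).
#' @param seed_offset Added to the spec seed.
#' @return Dense `n_bins x n_bins_other` count matrix.
#' @export
generate_trans <- function(spec, n_bins_other = spec$n_bins,
                           mean_count = 0.5, seed_offset = 23L) {
  set.seed(spec$seed + seed_offset)
  matrix(stats::rpois(spec$n_bins * n_bins_other, mean_count),
         spec$n_bins, n_bins_other)
}

#' Serialize a ground truth to JSON
#' @param truth A [generate_ground_truth()] object.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$bin_table <- NULL
  class(out) <- NULL
  class(out$spec) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}
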