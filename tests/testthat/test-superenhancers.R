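# brute-force stitching oracle: transitive closure of the pairwise-gap graph
stitch_oracle <- function(starts, ends, gap_bp) {
  n <- length(starts)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    g <- max(starts[a], starts[b]) - min(ends[a], ends[b])
    adj[a, b] <- g <= gap_bp
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (adj[a, b] && comp[b] != comp[a]) {
        comp[comp == comp[b]] <- comp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

test_that("stitching merges peaks within the gap and applies the constituent filter", {
  pk <- data.frame(chrom = "chrS", start = c(0, 5000, 10000),
                   end = c(1000, 6000, 11000), score = c(2, 3, 4))
  st <- stitch(pk)                     # 4-kb gaps < 12.5 kb
  expect_equal(nrow(st), 1L)
  expect_equal(st$n_constituents, 3L)
  expect_equal(st$signal, 9)
  expect_equal(st$start, 0)
  expect_equal(st$end, 11000)
  # 13-kb gaps: three singletons, all dropped by the constituent filter
  pk2 <- data.frame(chrom = "chrS", start = c(0, 14000, 28000),
                    end = c(1000, 15000, 29000), score = 1)
  expect_equal(nrow(stitch(pk2)), 0L)
  # a peak inside the TSS exclusion zone is removed before stitching
  st3 <- stitch(pk, tss = 5500, tss_flank_bp = 2500)
  expect_equal(nrow(st3), 0L)          # middle constituent gone -> <3 left
  expect_equal(nrow(stitch(pk[0, ])), 0L)
})

test_that("stitching matches the brute-force interval-graph oracle on random peak sets", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 40
    starts <- sort(round(runif(n, 0, 5e5)))
    ends <- starts + round(runif(n, 500, 3000))
    pk <- data.frame(chrom = "chrS", start = starts, end = ends, score = 1)
    st <- stitch(pk, min_constituents = 1L)
    comp <- stitch_oracle(starts, ends, 12500)
    expect_equal(nrow(st), length(unique(comp)))
    sizes <- sort(as.integer(table(comp)))
    expect_equal(sort(st$n_constituents), sizes)
    # order-independence
    ord <- sample(n)
    st2 <- stitch(pk[ord, ], min_constituents = 1L)
    expect_equal(st2$start, st$start)
  }
})

test_that("the tangent cutoff splits exceptional-signal regions from the rest", {
  reg <- data.frame(chrom = "chrS", start = 1:5 * 1e5, end = 1:5 * 1e5 + 1e4,
                    n_constituents = 3L, signal = c(1, 1, 1, 1, 10))
  rs <- rank_and_split(reg)
  expect_equal(sum(rs$class == "SE"), 1L)
  expect_equal(rs$signal[rs$class == "SE"], 10)
  # all-equal signals: flat curve, no SEs
  reg$signal <- 4
  expect_equal(sum(rank_and_split(reg)$class == "SE"), 0L)
  # geometric signals: cutoff index matches a brute-force slope scan
  n <- 20
  regg <- data.frame(chrom = "chrS", start = 1:n, end = 1:n + 1,
                     n_constituents = 3L, signal = 2^(1:n))
  rg <- rank_and_split(regg)
  x <- (0:(n - 1)) / (n - 1)
  y <- (sort(regg$signal) - min(regg$signal)) / diff(range(regg$signal))
  slope <- diff(y) / diff(x)
  cut_idx <- min(which(c(slope, Inf) > 1))
  expect_equal(sum(rg$class == "SE"), n - cut_idx)
  # ranking consistency: every SE outranks every TE
  expect_gt(min(rg$signal[rg$class == "SE"]),
            max(rg$signal[rg$class == "TE"]))
})

test_that("SE specificity uses reciprocal overlap against every other region", {
  a <- data.frame(start = c(0, 10000), end = c(4000, 14000))
  b <- data.frame(start = c(3000), end = c(7000))    # 25% reciprocal w/ a1
  sp <- se_specificity(list(A = a, B = b), min_overlap_frac = 0.3)
  spa <- sp[sp$region == "A", ]
  expect_true(all(spa$specific))           # 0.25 < 0.3 threshold
  # identical SE in both regions: shared
  sp2 <- se_specificity(list(A = a, B = a))
  expect_false(any(sp2$specific))
  # SE present in one region only
  sp3 <- se_specificity(list(A = a, B = a[0, ]))
  expect_true(all(sp3$specific[sp3$region == "A"]))
})

test_that("SE-gene linkage goes through significant promoter interactions", {
  bs <- balanced_small(seed = 62)
  tracks <- generate_tracks(bs$truth)
  sig <- significant_interactions(bs$bal, max_dist = 100L)
  st <- rank_and_split(stitch(tracks$h3k27ac, tss = tracks$genes$tss))
  se <- st[st$class == "SE", ]
  lk <- link_se_to_genes(se, sig, tracks$genes, bs$truth$bin_table)
  planted <- bs$truth$loops[bs$truth$loops$type == "se_promoter", ]
  planted <- planted[bs$truth$tad_of_bin[planted$i + 1] ==
                       bs$truth$tad_of_bin[planted$j + 1], ]
  expect_gte(sum(planted$gene %in% lk$gene), 0.5 * nrow(planted))
  # an SE with no interactions yields no pairs
  far_se <- data.frame(start = 1, end = 2)
  expect_equal(nrow(link_se_to_genes(far_se, sig[0, ], tracks$genes,
                                     bs$truth$bin_table)), 0L)
})

test_that("two genes on one anchor bin are both linked and flagged ambiguous", {
  bt <- bin_table("chrS", 2e6, 1e4)
  genes <- gene_models(data.frame(
    gene = c("G1", "G2"), chrom = "chrS", start = c(501000, 505000),
    end = c(503000, 508000), strand = "+", stringsAsFactors = FALSE))
  sig <- data.frame(i = 10L, j = 50L, d = 40L, value = 9, p = 1e-6,
                    q = 1e-5, significant = TRUE)
  ses <- data.frame(start = 100000, end = 105000)
  lk <- link_se_to_genes(ses, sig, genes, bt)
  expect_equal(sort(lk$gene), c("G1", "G2"))
  expect_true(all(lk$ambiguous))
})

test_that("SE-linked genes outrank TE-linked genes in expression under the planted boost", {
  truth <- generate_ground_truth(small_spec(seed = 63))
  et <- generate_expression(truth)
  se_genes <- truth$loops$gene[truth$loops$type == "se_promoter"]
  te_genes <- truth$loops$gene[truth$loops$type == "te_promoter"]
  r <- se_vs_te_expression(se_genes, te_genes, et)
  expect_gt(r$shift, 0)
  expect_lt(r$p, 0.05)
  expect_warning(expect_null(se_vs_te_expression(character(), te_genes, et)),
                 "empty")
})

test_that("cis SE-SE contacts are enriched over the trans background", {
  bs <- balanced_small(seed = 64)
  oe <- observed_over_expected(bs$bal)
  tm <- generate_trans(bs$truth$spec, n_bins_other = 200)
  en <- se_interaction_enrichment(unique(bs$truth$se_bins),
                                  te_bins = seq(5, 195, by = 10), oe, tm)
  expect_lt(en$p_cis_gt_trans, 0.05)
  expect_equal(en$trans_enrichment, 1, tolerance = 0.05)
  expect_error(
    se_interaction_enrichment(c(1L, 190L), seq(5, 195, 10), oe, tm,
                              max_dist = 10L),
    "no SE pairs")
})
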