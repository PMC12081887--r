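test_that("the generator is deterministic under a fixed seed", {
  s1 <- generate_hic(small_spec(seed = 11))
  s2 <- generate_hic(small_spec(seed = 11))
  expect_identical(s1$matrix$value, s2$matrix$value)
  expect_identical(s1$truth$loops, s2$truth$loops)
  e1 <- generate_expression(s1$truth)
  e2 <- generate_expression(s2$truth)
  expect_identical(e1$fpkm, e2$fpkm)
  p1 <- generate_snps(s1$truth)
  p2 <- generate_snps(s2$truth)
  expect_identical(p1$snps, p2$snps)
  s3 <- generate_hic(small_spec(seed = 12))
  expect_false(identical(s1$matrix$value, s3$matrix$value))
})

test_that("a null spec yields pure power-law decay within Poisson error", {
  spec <- null_spec(small_spec(seed = 21))
  sim <- generate_hic(spec)
  cm <- sim$matrix
  n <- spec$n_bins
  for (d in c(1L, 5L, 20L)) {
    sel <- cm$j - cm$i == d
    obs_mean <- sum(cm$value[sel]) / (n - d)      # absent pixels are zeros
    lam <- sim$scale * (d + 1)^(-spec$alpha)
    se <- sqrt(lam / (n - d))
    expect_lt(abs(obs_mean - lam), 4 * se)
  }
  # log-log decay slope near -alpha
  cmb <- cm; cmb$state <- "balanced"
  e <- expected_by_distance(cmb)
  fit <- lm(log(e[2:60]) ~ log(2:60 + 0))
  expect_equal(unname(coef(fit)[2]), -spec$alpha, tolerance = 0.1)
})

test_that("planted loop pixels carry their fold enrichment in expectation", {
  spec <- small_spec(seed = 22, bias_range = c(1, 1), n_dead_bins = 0)
  sim <- generate_hic(spec)
  truth <- sim$truth
  cm <- sim$matrix
  key <- cm$i * 1e4 + cm$j
  lp <- truth$loops
  # compare each loop pixel to the mean of its distance stratum among
  # same-TAD-status pixels: the ratio recovers phi
  ratios <- vapply(seq_len(nrow(lp)), function(r) {
    d <- lp$j[r] - lp$i[r]
    sel <- cm$j - cm$i == d
    same <- truth$tad_of_bin[cm$i[sel] + 1] == truth$tad_of_bin[cm$j[sel] + 1]
    in_tad <- truth$tad_of_bin[lp$i[r] + 1] == truth$tad_of_bin[lp$j[r] + 1]
    denom <- sum(cm$value[sel][same == in_tad]) /
      max(1, sum((cm$j - cm$i == d)) * 0 + sum(same == in_tad))
    v <- cm$value[match(lp$i[r] * 1e4 + lp$j[r], key)]
    if (is.na(v) || denom == 0) NA_real_ else v / denom
  }, numeric(1))
  expect_gt(median(ratios, na.rm = TRUE), 2.5)
})

test_that("ground truth features are internally consistent and unique", {
  truth <- generate_ground_truth(small_spec(seed = 23))
  expect_false(any(duplicated(truth$loops[, c("i", "j")])))
  expect_false(any(duplicated(truth$boundary_bins)))
  expect_true(all(diff(truth$tad_edges) > 0))
  expect_true(all(truth$c_early %in% c(-1, 1)))
  # switch blocks actually differ between stages
  expect_true(any(truth$c_early != truth$c_late) ||
                length(truth$flip_blocks) == 0)
  # intended SNP links each appear exactly once
  sn <- truth$snps[!is.na(truth$snps$linked_gene), ]
  expect_false(any(duplicated(sn$rsid)))
  # serializes to JSON
  f <- tempfile(fileext = ".json")
  write_ground_truth(truth, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("CTCF peaks sit at boundaries when background is off", {
  truth <- generate_ground_truth(small_spec(seed = 24))
  tracks <- generate_tracks(truth, ctcf_background = 0)
  bt <- truth$bin_table
  peak_bins <- bin_index(bt, pmin((tracks$ctcf$start + tracks$ctcf$end) / 2,
                                  bt$chrom_length - 1))
  off <- vapply(peak_bins, function(b) min(abs(truth$boundary_bins - b)),
                numeric(1))
  expect_true(all(off <= 1))
})

test_that("SE constituent clusters are stitchable and gene density follows compartments", {
  truth <- generate_ground_truth(small_spec(seed = 25))
  tracks <- generate_tracks(truth)
  # within each planted SE, consecutive constituent gaps are under 12.5 kb
  for (k in unique(truth$se$se_id)) {
    con <- truth$se[truth$se$se_id == k, ]
    gaps <- con$start[-1] - con$end[-nrow(con)]
    expect_true(all(gaps < 12500))
    expect_gte(nrow(con), 3)
  }
  expect_gt(cor(tracks$gene_density, truth$c_early), 0)
})

test_that("expression couples to compartment status in the planted direction", {
  truth <- generate_ground_truth(small_spec(seed = 26))
  et <- generate_expression(truth)
  cc <- truth_compartment(truth, 1)
  in_a <- cc[truth$genes$bin + 1] > 0
  s1 <- rownames(et$samples)[et$samples$stage == 1]
  lfc <- log2(rowMeans(et$fpkm[, s1, drop = FALSE]) + 1)
  expect_gt(mean(lfc[in_a]) - mean(lfc[!in_a]), 0)
  # beta_comp = 0 removes the difference in expectation
  spec0 <- small_spec(seed = 26, beta_comp = 0, traj_frac = 0, beta_se = 0)
  t0 <- generate_ground_truth(spec0)
  e0 <- generate_expression(t0)
  in_a0 <- truth_compartment(t0, 1)[t0$genes$bin + 1] > 0
  l0 <- log2(rowMeans(e0$fpkm[, rownames(e0$samples)[e0$samples$stage == 1],
                              drop = FALSE]) + 1)
  expect_gt(t.test(l0[in_a0], l0[!in_a0])$p.value, 0.01)
})

test_that("SNP tables exercise the association threshold and dedupe", {
  truth <- generate_ground_truth(small_spec(seed = 27))
  sn <- generate_snps(truth)
  n_pass <- sum(sn$snps$p <= 1e-6)
  expect_equal(n_pass, truth$spec$n_index_snps)
  expect_equal(nrow(sn$snps) - n_pass, truth$spec$n_null_snps)
  # at least one duplicate-position proxy is planted
  if (nrow(sn$ld)) {
    expect_true(any(sn$ld$pos %in% sn$snps$pos))
  }
  # intended links point at real genes
  expect_true(all(sn$intended_links$gene %in% truth$genes$gene))
})

test_that("a null spec drives callers to their nominal false-positive behavior", {
  spec <- null_spec(small_spec(seed = 28))
  sim <- generate_hic(spec)
  bal <- ice_balance(mask_low_coverage(sim$matrix))
  prof <- detect_boundaries(normalize_insulation(
    insulation_score(observed_over_expected(bal))))
  # no planted boundaries: few valleys survive the strength threshold
  expect_lt(nrow(prof$boundaries), 0.05 * spec$n_bins)
  loops <- sweep_and_merge(bal, max_dist = 100L)
  expect_lt(nrow(loops), 5)
})
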