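test_that("a constant matrix has flat insulation and zero normalized score", {
  cm <- cm_from_dense(matrix(5, 30, 30), resolution = 4e4)
  cm$state <- "balanced"
  prof <- normalize_insulation(insulation_score(cm, window_bp = 2e5))
  scored <- !is.na(prof$raw)
  expect_gt(sum(scored), 0)
  expect_true(all(abs(prof$norm[scored]) < 1e-12))
  # doubling the matrix leaves the normalized profile unchanged
  cm2 <- cm; cm2$value <- cm$value * 2
  prof2 <- normalize_insulation(insulation_score(cm2, window_bp = 2e5))
  expect_equal(prof2$norm, prof$norm)
  # mean of 2^norm over scored bins is 1 by construction
  expect_equal(mean(2^prof$norm[scored]), 1, tolerance = 1e-12)
  expect_error(insulation_score(cm, window_bp = 4e4), "at least 2")
  expect_error(insulation_score(cm, window_bp = 1e5), "multiple")
})

test_that("a two-block diagonal matrix puts the insulation minimum at the junction", {
  n <- 30
  m <- matrix(0.2, n, n)
  m[1:15, 1:15] <- 5
  m[16:30, 16:30] <- 5
  cm <- cm_from_dense(m, resolution = 4e4)
  cm$state <- "balanced"
  # plain mean: strict argmin lands on the junction bins
  pm <- normalize_insulation(insulation_score(cm, window_bp = 2e5,
                                              trim = FALSE))
  junction <- which.min(pm$norm) - 1L       # 0-based; block edge is 14|15
  expect_lte(abs(junction - 14.5), 1)
  # trimmed mean: the valley is a plateau covering the junction; a single
  # boundary is reported inside it
  prof <- detect_boundaries(normalize_insulation(
    insulation_score(cm, window_bp = 2e5)), delta = 0.1)
  expect_equal(nrow(prof$boundaries), 1L)
  expect_lte(abs(prof$boundaries$bin - 14.5), 2.5)
})

test_that("fully masked squares yield missing scores", {
  m <- matrix(4, 30, 30)
  cm <- cm_from_dense(m, resolution = 4e4)
  cm$mask[10:20] <- FALSE
  keep <- cm$mask[cm$i + 1] & cm$mask[cm$j + 1]
  cm <- contact_matrix(cm$bin_table, cm$i[keep], cm$j[keep], cm$value[keep],
                       mask = cm$mask)
  cm$state <- "balanced"
  prof <- insulation_score(cm, window_bp = 2e5)
  expect_true(all(is.na(prof$raw[13:17])))
})

test_that("boundary detection respects strength, monotonicity and plateau ties", {
  bt <- bin_table("chrS", 12e5, 4e4)
  mk <- function(v) structure(list(bin_table = bt, window_bins = 3L,
                                   raw = 2^v, norm = v, boundaries = NULL),
                              class = "insulation_profile")
  # monotone profile: no interior minima
  p <- detect_boundaries(mk(seq(-1, 1, length.out = 30)))
  expect_equal(nrow(p$boundaries), 0L)
  # two adjacent equal minima: a single boundary at the leftmost bin
  v <- rep(0, 30); v[14:15] <- -1
  p2 <- detect_boundaries(mk(v), delta = 0.5)
  expect_equal(nrow(p2$boundaries), 1L)
  expect_equal(p2$boundaries$bin, 13L)
  expect_equal(p2$boundaries$strength, 1)
  # a shallow valley below delta is not reported
  v3 <- rep(0, 30); v3[10] <- -0.05
  expect_equal(nrow(detect_boundaries(mk(v3), delta = 0.1)$boundaries), 0L)
})

test_that("planted boundaries are recovered from synthetic maps", {
  bs <- balanced_small(seed = 41)
  prof <- detect_boundaries(normalize_insulation(
    insulation_score(observed_over_expected(bs$bal))))
  sc <- score_against_truth(list(insulation = prof), bs$truth)
  expect_gt(sc$boundary_recall, 0.75)
  expect_gt(sc$boundary_precision, 0.75)
  # every reported boundary meets the strength threshold
  expect_true(all(prof$boundaries$strength >= 0.1))
})

test_that("TADs are delimited by boundaries with a minimum size", {
  bt <- bin_table("chrS", 4e6, 4e4)
  raw <- rep(1, 100); raw[1:5] <- NA; raw[96:100] <- NA
  prof <- structure(list(bin_table = bt, window_bins = 5L, raw = raw,
                         norm = log2(raw),
                         boundaries = data.frame(
                           chrom = "chrS", start = c(20, 30) * 4e4,
                           end = c(21, 31) * 4e4, bin = c(20L, 30L),
                           strength = c(1, 1), norm_is = c(-1, -1))),
                    class = "insulation_profile")
  tads <- tads_from_boundaries(prof)
  expect_equal(nrow(tads), 3L)                 # k boundaries -> k+1 TADs
  expect_equal(tads$end[2] - tads$start[2], 4e5)  # bins 20..30 = 400 kb
  expect_true(all(tads$end - tads$start >= 4e5))
  # no boundaries: one TAD spanning the scored span
  prof0 <- prof; prof0$boundaries <- prof$boundaries[0, ]
  t0 <- tads_from_boundaries(prof0)
  expect_equal(nrow(t0), 1L)
  expect_equal(t0$start, 5 * 4e4)
})

test_that("most planted loops fall inside called TADs", {
  bs <- balanced_small(seed = 42)
  prof <- detect_boundaries(normalize_insulation(
    insulation_score(observed_over_expected(bs$bal))))
  tads <- tads_from_boundaries(prof)
  lp <- bs$truth$loops
  res <- bs$bal$bin_table$resolution
  in_tad <- vapply(seq_len(nrow(lp)), function(r) {
    any(tads$start <= lp$i[r] * res & tads$end >= (lp$j[r] + 1) * res)
  }, logical(1))
  planted_frac <- mean(bs$truth$tad_of_bin[lp$i + 1] ==
                         bs$truth$tad_of_bin[lp$j + 1])
  expect_gt(mean(in_tad), planted_frac - 0.2)
})

test_that("differential insulation reports maximal runs above threshold", {
  bt <- bin_table("chrS", 1.2e6, 4e4)
  mk <- function(v) structure(list(bin_table = bt, window_bins = 3L,
                                   raw = 2^v, norm = v, boundaries = NULL),
                              class = "insulation_profile")
  a <- mk(rep(0, 30))
  expect_equal(nrow(differential_insulation(a, a)), 0L)
  # single-bin spike with min_run = 2 is ignored
  v <- rep(0, 30); v[10] <- 1
  expect_equal(nrow(differential_insulation(mk(v), a, min_abs_diff = 0.5,
                                            min_run = 2)), 0L)
  # constructed 3-bin divergence at threshold: one region of 3 bins
  v3 <- rep(0, 30); v3[12:14] <- 0.5
  dd <- differential_insulation(mk(v3), a, min_abs_diff = 0.5, min_run = 2)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$n_bins, 3L)
})

test_that("meta-profiles spike at anchors and flatten on uniform peaks", {
  anchors <- data.frame(chrom = "chrS", start = seq(2e6, 8e6, by = 1e6) - 100,
                        end = seq(2e6, 8e6, by = 1e6) + 100)
  mids <- (anchors$start + anchors$end) / 2
  peaks <- data.frame(chrom = "chrS", start = mids - 200, end = mids + 200)
  mp <- meta_profile(anchors, peaks, flank_bp = 2e5, bin_bp = 4e4)
  center <- which(mp$offset_bp == 0)
  expect_true(all(mp$signal[center] > mp$signal[-center]))
  # uniform peaks: flat within sampling error
  set.seed(43)
  upk <- data.frame(chrom = "chrS", start = runif(4000, 0, 1e7))
  upk$end <- upk$start + 200
  mu <- meta_profile(anchors, upk, flank_bp = 2e5, bin_bp = 4e4)
  expect_lt(max(mu$signal) / max(1e-9, min(mu$signal)), 2.5)
  expect_error(meta_profile(anchors[0, ], peaks), "empty")
})
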