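test_that("the leading eigenvector of a plaid correlation matrix tracks the sign vector", {
  set.seed(31)
  n <- 60
  cvec <- rep(c(1, -1), each = 10, length.out = n)
  cc <- outer(cvec, cvec) * 0.8
  diag(cc) <- 1
  pcs <- compute_pcs(cc, k = 3)
  expect_equal(ncol(pcs), 3L)
  expect_gt(abs(cor(pcs[, 1], cvec)), 0.99)
  expect_error(compute_pcs(matrix(NA_real_, 4, 4)), "degenerate")
})

test_that("PC selection follows gene density and orientation is antisymmetric and idempotent", {
  set.seed(32)
  n <- 60
  cvec <- rep(c(1, -1), each = 12, length.out = n)
  cc <- outer(cvec, cvec) * 0.7 + diag(0.3, n)
  pcs <- compute_pcs(cc, k = 3)
  bt <- bin_table("chrS", n * 1e5, 1e5)
  dens <- 2 + cvec + rnorm(n, 0, 0.2)
  prof <- select_and_orient(pcs, dens, bt)
  expect_equal(prof$selected_pc, 1L)
  expect_false(prof$unresolved)
  # A bins are the gene-dense ones
  expect_gt(mean(prof$label[cvec > 0] == "A", na.rm = TRUE), 0.95)
  # flipping the density track flips every label
  prof_f <- select_and_orient(pcs, -dens + 5, bt)
  ok <- !is.na(prof$label)
  expect_true(all(prof$label[ok] != prof_f$label[ok]))
  # re-orienting oriented values changes nothing
  prof2 <- select_and_orient(prof$pcs * ifelse(prof$pc == pcs[, 1], 1, -1),
                             dens, bt)
  expect_equal(prof2$label, prof$label)
  # uncorrelated density -> unresolved, no labels
  prof_u <- select_and_orient(pcs, rnorm(n), bt, min_cor = 0.9)
  expect_true(prof_u$unresolved)
  expect_true(all(is.na(prof_u$label)))
})

test_that("planted compartment signs are recovered from synthetic contact maps", {
  bs <- balanced_small(seed = 33)
  tracks <- generate_tracks(bs$truth)
  prof <- call_compartments(bs$bal, tracks$gene_density)
  sc <- score_against_truth(list(compartments = prof), bs$truth)
  expect_gt(sc$compartment_agreement, 0.95)
})

test_that("switch classification counts sign flips on co-labeled bins", {
  bt <- bin_table("chrS", 1e6, 1e5)
  mk <- function(lab) structure(list(bin_table = bt, label = lab,
                                     unresolved = FALSE),
                                class = "compartment_profile")
  a <- mk(rep(c("A", "B"), 5))
  b3 <- a$label
  b3[c(1, 4, 6)] <- ifelse(b3[c(1, 4, 6)] == "A", "B", "A")
  sw <- classify_switches(a, mk(b3))
  expect_equal(sum(sw %in% c("A->B", "B->A")), 3L)
  expect_true(all(classify_switches(a, a) %in% c("A->A", "B->B")))
  inv <- mk(ifelse(a$label == "A", "B", "A"))
  expect_true(all(classify_switches(a, inv) %in% c("A->B", "B->A")))
})

test_that("compartment dynamics ANOVA is calibrated on null data and powered on shifts", {
  set.seed(34)
  n_bins <- 300; stages <- rep(1:5, each = 3)
  pc <- matrix(rnorm(n_bins * 15, 0, 0.1), n_bins, 15)
  dyn <- compartment_dynamics(pc, stages)
  expect_lte(mean(dyn$dynamic), 0.05 + 3 * sqrt(0.05 * 0.95 / n_bins))
  expect_true(all(dyn$q >= dyn$p, na.rm = TRUE))
  # constant bin: F = 0, not dynamic
  pc0 <- pc; pc0[1, ] <- 0.3
  d0 <- compartment_dynamics(pc0, stages)
  expect_equal(d0$F[1], 0)
  expect_false(d0$dynamic[1])
  # planted 3-sigma stage shift: raw detection power matches F-theory
  # (ncp = 32.4 at this design gives power ~0.98 at alpha = 0.05)
  shifted <- sample(n_bins, 30)
  pc2 <- pc
  pc2[shifted, stages >= 4] <- pc2[shifted, stages >= 4] + 0.3
  d2 <- compartment_dynamics(pc2, stages)
  theory <- 1 - pf(qf(0.95, 4, 10), 4, 10, ncp = 32.4)
  expect_gt(mean(d2$p[shifted] < 0.05), theory - 0.15)
  expect_gt(mean(d2$p[shifted] < 0.05), 0.9)
  expect_gt(mean(d2$dynamic[shifted]), 0.6)
  expect_error(compartment_dynamics(pc, rep(1, 15)), "2 stages")
  expect_error(compartment_dynamics(pc[, 1:5], 1:5), "2 samples")
})

test_that("compartment strength is near 1 under shuffled labels and scale-invariant", {
  bs <- balanced_small(seed = 35)
  oe <- observed_over_expected(bs$bal)
  tracks <- generate_tracks(bs$truth)
  prof <- call_compartments(bs$bal, tracks$gene_density)
  st <- compartment_strength(oe, prof)
  expect_gt(st$strength, 1.2)
  expect_equal(st$saddle, t(st$saddle))
  # shuffled PC -> strength collapses toward 1
  set.seed(35)
  shuf <- prof$pc[order(runif(length(prof$pc)))]
  st0 <- compartment_strength(oe, shuf)
  expect_lt(abs(st0$strength - 1), 0.25)
  # global rescaling leaves strength unchanged
  oe2 <- oe; oe2$value <- oe$value * 7
  expect_equal(compartment_strength(oe2, prof)$strength, st$strength)
})

test_that("B->A switching genes shift up under the planted coupling", {
  spec <- small_spec(seed = 36, switch_frac = 0.3)
  truth <- generate_ground_truth(spec)
  et <- generate_expression(truth)
  bt <- truth$bin_table
  # truth-derived switch classes isolate the expression machinery
  lab <- function(x) ifelse(x > 0, "A", "B")
  sw <- paste0(lab(truth$c_early), "->", lab(truth$c_late))
  tracks <- generate_tracks(truth)
  early_s <- rownames(et$samples)[et$samples$stage == 1]
  late_s <- rownames(et$samples)[et$samples$stage == spec$n_stages]
  # test whichever switch direction this layout planted
  classes <- intersect(c("B->A", "A->B"), unique(sw))
  expect_gt(length(classes), 0)
  for (cl in classes) {
    r <- switch_expression_test(sw, et, tracks$genes, bt, early_s, late_s, cl)
    if (is.null(r)) next      # no genes landed in a small flipped block
    expect_lt(r$p, 0.05)
    if (cl == "B->A") expect_gt(r$shift, 0) else expect_lt(r$shift, 0)
  }
  # empty class is skipped with a warning
  expect_warning(
    expect_null(switch_expression_test(rep("A->A", spec$n_bins), et,
                                       tracks$genes, bt, early_s, late_s,
                                       "B->A")),
    "no genes")
})
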