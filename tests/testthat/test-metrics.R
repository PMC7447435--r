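# Evaluation metrics: contingency, adjusted Rand error, VOI, boundary PR,
# PSNR, SSIM.

test_that("contingency counts voxels jointly and excludes ignore label", {
  seg <- array(c(rep(1L, 10), rep(2L, 20), rep(3L, 2)), c(4, 4, 2))
  gt <- array(c(rep(1L, 10), rep(2L, 20), rep(0L, 2)), c(4, 4, 2))
  ct <- contingency(seg, gt)
  expect_equal(ct$n, 30L)
  expect_equal(ct$counts$n, c(10L, 20L))
  expect_warning(contingency(seg, array(0L, dim(seg))), "no positive")
  # random pair against a naive double-loop count
  rp <- random_label_pair(c(5, 5, 4), 3, 4, seed = 1)
  ct2 <- contingency(rp$seg, rp$gt)
  naive <- matrix(0L, 3, 4)
  for (i in seq_along(rp$seg)) {
    naive[rp$seg[i], rp$gt[i]] <- naive[rp$seg[i], rp$gt[i]] + 1L
  }
  for (r in seq_len(nrow(ct2$counts))) {
    expect_equal(ct2$counts$n[r], naive[ct2$counts$s[r], ct2$counts$g[r]])
  }
  expect_error(contingency(seg, array(1L, c(2, 2, 2))), "shape")
})

test_that("adjusted Rand error is 0 for identical labelings and matches pair counting", {
  lab <- generate_voronoi_labels(tissue_sim_config(shape = c(6, 6, 6),
                                                   n_cells = 4, rng_seed = 1))
  expect_equal(arand_error(lab, lab), 0)
  perm <- array(c(3L, 4L, 1L, 2L)[lab], dim(lab))
  expect_equal(arand_error(perm, lab), 0)
  # one cluster vs two equal halves: closed form gives ARand error 1
  seg1 <- array(1L, c(4, 4, 2))
  gt2 <- array(rep(c(1L, 2L), each = 16), c(4, 4, 2))
  expect_equal(arand_error(seg1, gt2), 1)
  for (s in 1:10) {
    rp <- random_label_pair(c(5, 4, 4), sample(2:5, 1), sample(2:5, 1), s)
    expect_equal(arand_error(rp$seg, rp$gt),
                 oracle_arand_pairs(rp$seg, rp$gt), tolerance = 1e-12)
  }
  suppressWarnings(
    expect_error(arand_error(array(1L, c(2, 2, 2)), array(0L, c(2, 2, 2)))))
})

test_that("VOI split/merge equal conditional entropies (natural log)", {
  lab <- generate_voronoi_labels(tissue_sim_config(shape = c(6, 6, 6),
                                                   n_cells = 3, rng_seed = 2))
  expect_equal(unname(voi(lab, lab)), c(0, 0))
  # one gt region split into two equal halves: (ln 2, 0)
  gt <- array(1L, c(4, 4, 4))
  seg <- array(rep(c(1L, 2L), each = 32), c(4, 4, 4))
  expect_equal(voi(seg, gt), c(voi_split = log(2), voi_merge = 0))
  for (s in 1:10) {
    rp <- random_label_pair(c(5, 4, 4), sample(2:5, 1), sample(2:5, 1), s + 50)
    expect_equal(voi(rp$seg, rp$gt), oracle_voi(rp$seg, rp$gt),
                 tolerance = 1e-12)
    # identity: split + merge = H(seg) + H(gt) - 2 I(seg; gt)
    v <- voi(rp$seg, rp$gt)
    n <- length(rp$seg)
    H <- function(x) { p <- table(x) / n; -sum(p * log(p)) }
    joint <- table(as.vector(rp$seg), as.vector(rp$gt)) / n
    I <- sum(joint[joint > 0] *
               log(joint[joint > 0] /
                     (rowSums(joint)[row(joint)[joint > 0]] *
                        colSums(joint)[col(joint)[joint > 0]])))
    expect_equal(unname(v[1] + v[2]), H(rp$seg) + H(rp$gt) - 2 * I,
                 tolerance = 1e-10)
  }
})

test_that("boundary precision/recall follow the voxel-wise definitions", {
  gt <- array(0, c(6, 6, 6)); gt[3:4, , ] <- 1
  q <- mean(gt)
  # perfect prediction
  pr <- boundary_pr_curve(gt, gt, thresholds = c(0.3, 0.7))
  expect_true(all(pr$precision == 1 & pr$recall == 1 & pr$f1 == 1))
  # predict everything: recall 1, precision = boundary fraction
  ones <- array(1, dim(gt))
  pr2 <- boundary_pr_curve(ones, gt, thresholds = 0.5)
  expect_equal(pr2$recall, 1)
  expect_equal(pr2$precision, q)
  expect_equal(pr2$f1, 2 * q / (1 + q))
  # nothing predicted, non-empty truth: all zero (F1 convention)
  pr3 <- boundary_pr_curve(array(0, dim(gt)), gt, thresholds = 0.5)
  expect_equal(pr3$precision + pr3$recall + pr3$f1, 0)
  # nothing predicted, empty truth: precision 1 by convention
  pr4 <- boundary_pr_curve(array(0, dim(gt)), array(0, dim(gt)), thresholds = 0.5)
  expect_equal(pr4$precision, 1)
  expect_error(boundary_pr_curve(gt, gt * 0.5), "binary")
  # spatial tolerance relaxes matching of a 1-voxel-shifted prediction
  shifted <- array(0, dim(gt)); shifted[4:5, , ] <- 1
  strict <- boundary_pr_curve(shifted, gt, thresholds = 0.5)
  tol <- boundary_pr_curve(shifted, gt, thresholds = 0.5, tolerance = 1)
  expect_gt(tol$f1, strict$f1)
  expect_equal(tol$precision, 1)
})

test_that("PSNR follows its closed form and decreases with noise", {
  a <- array(runif(4^3), c(4, 4, 4))
  expect_identical(psnr(a, a), Inf)
  b <- array(0, c(4, 4, 4)); b[] <- 0.5   # MSE vs 0 map = 0.25
  expect_equal(psnr(b, array(0, c(4, 4, 4)), data_range = 1),
               10 * log10(4), tolerance = 1e-12)
  set.seed(2)
  p1 <- psnr(a + rnorm(64, sd = 0.05), a)
  p2 <- psnr(a + rnorm(64, sd = 0.2), a)
  expect_gt(p1, p2)
})

test_that("SSIM equals the direct per-window evaluation", {
  set.seed(3)
  a <- array(runif(9 * 9 * 9), c(9, 9, 9))
  expect_equal(ssim(a, a), 1)
  b <- array(0.5, dim(a))
  expect_lt(ssim(a, b), 1)
  noisy <- pmin(pmax(a + rnorm(length(a), sd = 0.2), 0), 1)
  expect_equal(ssim(a, noisy), oracle_ssim(a, noisy), tolerance = 1e-6)
  # 2D single-slice volumes use an in-plane window
  a2 <- array(runif(9 * 9), c(1, 9, 9))
  n2 <- pmin(pmax(a2 + rnorm(81, sd = 0.1), 0), 1)
  expect_equal(ssim(a2, n2), oracle_ssim(a2, n2), tolerance = 1e-6)
  expect_error(ssim(array(0, c(3, 3, 3)), array(0, c(3, 3, 3))), "window")
})
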