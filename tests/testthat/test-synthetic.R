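# Synthetic tissue generator: Voronoi labelings, boundary targets, membrane
# image simulation, and boundary-map corruption.

test_that("voronoi labeling matches brute-force nearest-seed assignment", {
  cfg <- tissue_sim_config(shape = c(12, 12, 12), n_cells = 6, rng_seed = 11)
  lab <- generate_voronoi_labels(cfg)
  expect_setequal(unique(as.vector(lab)), 1:6)
  seeds <- with(list(), {
    # recover the seed draw exactly as the generator makes it
    tissueseg:::with_seed(11L, sample.int(prod(cfg$shape), 6))
  })
  expect_identical(unname(lab), unname(oracle_nearest_seed(cfg$shape, seeds)))
})

test_that("voronoi labeling is a deterministic complete partition", {
  cfg <- tissue_sim_config(shape = c(16, 16, 16), n_cells = 5, rng_seed = 7)
  a <- generate_voronoi_labels(cfg)
  b <- generate_voronoi_labels(cfg)
  expect_identical(a, b)
  expect_true(all(a > 0))
  expect_equal(sort(unique(as.vector(a))), 1:5)
  one <- generate_voronoi_labels(tissue_sim_config(shape = c(8, 8, 8),
                                                   n_cells = 1, rng_seed = 1))
  expect_true(all(one == 1L))
  expect_error(tissue_sim_config(shape = c(2, 2, 2), n_cells = 9),
               "n_cells")
  expect_error(tissue_sim_config(shape = c(0, 4, 4), n_cells = 1), "shape")
})

test_that("boundary target marks the two flanking layers of a flat interface", {
  lab <- array(1L, c(8, 6, 6))
  lab[5:8, , ] <- 2L
  bt0 <- labels_to_boundary_target(lab, sigma = 0)
  expected <- array(0, c(8, 6, 6)); expected[4:5, , ] <- 1
  expect_identical(bt0, expected)
  # sigma = 1 blur + 0.5 threshold against the dense convolution oracle
  bt1 <- labels_to_boundary_target(lab, sigma = 1)
  mask <- array(as.numeric(oracle_boundary_scan(lab)), dim(lab))
  expect_identical(bt1,
                   array(as.numeric(oracle_gauss_blur(mask, 1) > 0.5), dim(lab)))
})

test_that("boundary target is label-permutation invariant and 0 for one label", {
  cfg <- tissue_sim_config(shape = c(10, 10, 10), n_cells = 4, rng_seed = 3)
  lab <- generate_voronoi_labels(cfg)
  perm <- c(3L, 1L, 4L, 2L)
  lab2 <- array(perm[lab], dim(lab))
  expect_identical(labels_to_boundary_target(lab, 1),
                   labels_to_boundary_target(lab2, 1))
  # sigma = 0 equals the raw mask
  expect_identical(labels_to_boundary_target(lab, 0),
                   array(as.numeric(oracle_boundary_scan(lab)), dim(lab)))
  uniform <- array(1L, c(6, 6, 6))
  expect_true(all(labels_to_boundary_target(uniform, 1) == 0))
  expect_error(labels_to_boundary_target(array(0L, c(4, 4, 4)), 1),
               "positive")
})

test_that("membrane simulation: no corruption reproduces the mask, gaps are counted", {
  cfg <- tissue_sim_config(shape = c(16, 16, 16), n_cells = 4,
                           membrane_sigma = 0, noise_gaussian_sd = 0,
                           noise_poisson_scale = 0, gap_fraction = 0,
                           rng_seed = 5)
  lab <- generate_voronoi_labels(cfg)
  img <- simulate_membrane_image(lab, cfg)
  mask <- labels_to_boundary_target(lab, 0)
  expect_equal(img, mask)
  # 20% gap deletion zeroes exactly round(0.2 * boundary count) voxels
  cfg2 <- tissue_sim_config(shape = c(16, 16, 16), n_cells = 4,
                            membrane_sigma = 0, noise_gaussian_sd = 0,
                            noise_poisson_scale = 0, gap_fraction = 0.2,
                            rng_seed = 5)
  img2 <- simulate_membrane_image(lab, cfg2)
  expect_equal(sum(mask == 1 & img2 == 0), round(0.2 * sum(mask)))
  # determinism
  expect_identical(img2, simulate_membrane_image(lab, cfg2))
})

test_that("boundary-map corruption is identity-configurable, clipped, reproducible", {
  cfg0 <- tissue_sim_config(shape = c(12, 12, 12), n_cells = 4,
                            membrane_sigma = 0, noise_gaussian_sd = 0,
                            noise_poisson_scale = 0, gap_fraction = 0,
                            rng_seed = 2)
  lab <- generate_voronoi_labels(cfg0)
  bt <- labels_to_boundary_target(lab, 1)
  expect_equal(corrupt_boundary_map(bt, cfg0), bt)
  cfg <- tissue_sim_config(shape = c(12, 12, 12), n_cells = 4,
                           membrane_sigma = 0.5, noise_gaussian_sd = 0.3,
                           noise_poisson_scale = 0.1, gap_fraction = 0.1,
                           rng_seed = 2)
  out <- corrupt_boundary_map(bt, cfg)
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, corrupt_boundary_map(bt, cfg))
  zero <- array(0, c(12, 12, 12))
  z <- corrupt_boundary_map(zero, cfg)
  expect_true(all(z >= 0 & z <= 1))
})
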