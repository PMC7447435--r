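# Region adjacency graph construction and the signed-graph partitioners.

test_that("RAG edges and interface means match exhaustive enumeration", {
  # two half-volumes, probability 0.9 on both flanking layers
  sv <- array(1L, c(8, 8, 8)); sv[5:8, , ] <- 2L
  bm <- array(0, c(8, 8, 8)); bm[4:5, , ] <- 0.9
  rag <- build_rag(sv, bm)
  expect_equal(nrow(rag$edges), 1)
  expect_equal(rag$edges$mean_prob, 0.9)
  expect_equal(rag$edges$contact_area, 64L)
  # 2x2 grid of cuboids: 4 edges, no diagonal
  g <- array(1L, c(4, 8, 8))
  g[, 5:8, 1:4] <- 2L; g[, 1:4, 5:8] <- 3L; g[, 5:8, 5:8] <- 4L
  rag2 <- build_rag(g, array(0.5, dim(g)))
  expect_equal(nrow(rag2$edges), 4)
  expect_false(any(paste(rag2$edges$u, rag2$edges$v) %in% c("1 4", "2 3")))
  # random small volume: means and areas equal the brute-force oracle
  set.seed(8)
  sv3 <- generate_voronoi_labels(tissue_sim_config(shape = c(7, 7, 7),
                                                   n_cells = 5, rng_seed = 8))
  bm3 <- array(runif(7^3), c(7, 7, 7))
  rag3 <- build_rag(sv3, bm3)
  o <- oracle_interfaces(sv3)
  expect_equal(nrow(rag3$edges), length(o))
  for (i in seq_len(nrow(rag3$edges))) {
    key <- paste(rag3$edges$u[i], rag3$edges$v[i])
    expect_equal(rag3$edges$mean_prob[i], mean(bm3[o[[key]]$vox]))
    expect_equal(rag3$edges$contact_area[i], o[[key]]$faces)
  }
  # single region: one node, no edges
  rag1 <- build_rag(array(1L, c(4, 4, 4)), array(0, c(4, 4, 4)))
  expect_equal(nrow(rag1$nodes), 1)
  expect_equal(nrow(rag1$edges), 0)
})

test_that("signed weight mapping is symmetric at 0.5 and strictly decreasing", {
  expect_equal(to_signed_weight(0.5, 0.5), 0)
  expect_equal(to_signed_weight(0.5, 0.6), log(0.4 / 0.6))
  expect_lt(to_signed_weight(0.5, 0.6), 0)
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(to_signed_weight(ps, 0.6)) < 0))
  bs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(sapply(bs, function(b) to_signed_weight(0.3, b))) < 0))
  expect_error(to_signed_weight(0.5, 1), "beta_bias")
})

test_that("gasp contracts attractive edges and respects repulsion", {
  n <- 4
  path <- make_rag(n, list(u = 1:3, v = 2:4, p = rep(0.5, 3)))
  p <- gasp_average(path, weights = c(2, -1, 2))
  expect_equal(unname(p), c(1, 1, 2, 2))
  all_attr <- make_rag(4, list(u = c(1, 2, 3), v = c(2, 3, 4), p = rep(0.1, 3)))
  expect_equal(max(gasp_average(all_attr, 0.5)), 1)
  all_rep <- make_rag(4, list(u = c(1, 2, 3), v = c(2, 3, 4), p = rep(0.9, 3)))
  expect_equal(max(gasp_average(all_rep, 0.5)), 4)
})

test_that("gasp cluster count is non-decreasing in the splitting bias", {
  for (s in 1:3) {
    fx <- corrupted_fixture(s, shape = c(32L, 32L, 32L), n_cells = 8L)
    sv <- dt_watershed(fx$bmap)
    rag <- build_rag(sv, fx$bmap)
    ks <- sapply(c(0.3, 0.4, 0.5, 0.6, 0.7), function(b) max(gasp_average(rag, b)))
    expect_true(all(diff(ks) >= 0), label = paste("fixture", s))
  }
})

test_that("mutex watershed honors constraints and is rescale-invariant", {
  tri <- make_rag(3, list(u = c(1, 1, 2), v = c(2, 3, 3), p = rep(0.5, 3)))
  p <- unname(mutex_watershed(tri, weights = c(3, 2, -5)))
  expect_equal(max(p), 2)
  expect_true(p[2] != p[3])   # endpoints of the dominant repulsive edge
  expect_equal(p[1], p[2])    # strongest attractive edge merged first
  allp <- make_rag(4, list(u = c(1, 2, 3), v = c(2, 3, 4), p = rep(0.5, 3)))
  expect_equal(max(mutex_watershed(allp, weights = c(1, 2, 3))), 1)
  expect_equal(max(mutex_watershed(allp, weights = -c(1, 2, 3))), 4)
  for (s in 1:5) {
    rg <- random_signed_graph(7, s)
    p1 <- mutex_watershed(rg$rag, weights = rg$w)
    p2 <- mutex_watershed(rg$rag, weights = 3.7 * rg$w)
    expect_identical(p1, p2)
  }
})

test_that("greedy multicut approaches the exact enumeration optimum", {
  two <- make_rag(2, list(u = 1, v = 2, p = 0.5))
  expect_equal(max(multicut_exact(two, weights = 1)), 1)
  expect_equal(max(multicut_exact(two, weights = -1)), 2)
  # triangle (+1, +1, -3): the optimum cuts exactly one attractive edge;
  # verify against all 5 partitions of 3 elements enumerated by hand
  tri <- make_rag(3, list(u = c(1, 1, 2), v = c(2, 3, 3), p = rep(0.5, 3)))
  w <- c(1, 1, -3)
  parts <- list(c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(1, 2, 2), c(1, 2, 3))
  objs <- sapply(parts, function(a) {
    sum(w[c(a[1] != a[2], a[1] != a[3], a[2] != a[3])])
  })
  pe <- multicut_exact(tri, weights = w)
  expect_equal(attr(pe, "objective"), min(objs))
  expect_equal(sum(w[c(pe[1] != pe[2], pe[1] != pe[3], pe[2] != pe[3])]),
               min(objs))
  # all-attractive and all-repulsive ends
  allp <- make_rag(4, list(u = c(1, 2, 3), v = c(2, 3, 4), p = rep(0.5, 3)))
  pg <- multicut_greedy(allp, weights = c(1, 2, 3))
  expect_equal(max(pg), 1); expect_equal(attr(pg, "objective"), 0)
  pr <- multicut_greedy(allp, weights = c(-1, -2, -3))
  expect_equal(max(pr), 4)
  expect_equal(attr(pr, "objective"), -6)  # all (negative) edges are cut
  # exact oracle never exceeds greedy; greedy usually matches it
  for (s in 1:20) {
    rg <- random_signed_graph(sample(4:7, 1), s + 100)
    og <- attr(multicut_greedy(rg$rag, weights = rg$w), "objective")
    oe <- attr(multicut_exact(rg$rag, weights = rg$w), "objective")
    expect_lte(oe, og + 1e-9)
  }
  expect_error(multicut_exact(make_rag(13, list(u = 1, v = 2, p = 0.5))),
               "12 nodes")
})

test_that("partitioners are deterministic and label-permutation equivariant", {
  fx <- make_clean_rag(shape = c(12, 12, 12), n_parent = 3, n_child = 7,
                       seed = 4)
  for (fn in list(gasp_average, mutex_watershed, multicut_greedy)) {
    p1 <- fn(fx$rag)
    p2 <- fn(fx$rag)
    expect_identical(unname(p1), unname(p2))
  }
})

test_that("projection maps supervoxels to cluster labels with conserved counts", {
  sv <- generate_voronoi_labels(tissue_sim_config(shape = c(8, 8, 8),
                                                  n_cells = 5, rng_seed = 2))
  ident <- seq_len(5)
  expect_identical(project_partition(sv, ident), sv)
  allone <- rep(1L, 5)
  expect_true(all(project_partition(sv, allone) == 1L))
  part <- c(1L, 2L, 1L, 2L, 1L)
  seg <- project_partition(sv, part)
  for (k in 1:2) {
    expect_equal(sum(seg == k), sum(tabulate(sv)[part == k]))
  }
  expect_error(project_partition(sv, c(1L, 2L)), "missing")
})
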