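# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (double loops, dense enumeration) and shares no code
# with the implementation it checks.

# Nearest-seed assignment by explicit per-voxel loop over seeds (Euclidean in
# voxel units, ties to the lowest seed index). Coordinates are 0-based
# (z, y, x) with z the fastest-varying axis.
oracle_nearest_seed <- function(shape, seed_idx) {
  n <- prod(shape)
  out <- integer(n)
  sz <- (seed_idx - 1) %% shape[1]
  sy <- ((seed_idx - 1) %/% shape[1]) %% shape[2]
  sx <- (seed_idx - 1) %/% (shape[1] * shape[2])
  for (i in seq_len(n)) {
    z <- (i - 1) %% shape[1]
    y <- ((i - 1) %/% shape[1]) %% shape[2]
    x <- (i - 1) %/% (shape[1] * shape[2])
    d2 <- (z - sz)^2 + (y - sy)^2 + (x - sx)^2
    out[i] <- which.min(d2)   # which.min takes the first (lowest index) tie
  }
  array(out, shape)
}

# Boundary voxels by explicit 26-neighborhood scan.
oracle_boundary_scan <- function(labels) {
  d <- dim(labels)
  out <- array(0L, d)
  for (i3 in seq_len(d[3])) for (i2 in seq_len(d[2])) for (i1 in seq_len(d[1])) {
    li <- labels[i1, i2, i3]
    if (li <= 0) next
    for (o3 in -1:1) for (o2 in -1:1) for (o1 in -1:1) {
      j1 <- i1 + o1; j2 <- i2 + o2; j3 <- i3 + o3
      if (j1 < 1 || j1 > d[1] || j2 < 1 || j2 > d[2] || j3 < 1 || j3 > d[3]) next
      lj <- labels[j1, j2, j3]
      if (lj > 0 && lj != li) out[i1, i2, i3] <- 1L
    }
  }
  out
}

# Dense Gaussian convolution with symmetric reflection, evaluated directly
# (no separability), kernel radius round(4*sigma).
oracle_gauss_blur <- function(x, sigma) {
  d <- dim(x)
  r <- max(1, round(4 * sigma))
  off <- -r:r
  k1 <- exp(-0.5 * off^2 / sigma^2); k1 <- k1 / sum(k1)
  reflect <- function(j, n) {
    while (j < 1 || j > n) { if (j < 1) j <- 1 - j; if (j > n) j <- 2 * n + 1 - j }
    j
  }
  out <- array(0, d)
  for (i3 in seq_len(d[3])) for (i2 in seq_len(d[2])) for (i1 in seq_len(d[1])) {
    acc <- 0
    for (o3 in off) for (o2 in off) for (o1 in off) {
      j1 <- if (d[1] > 1) reflect(i1 + o1, d[1]) else i1
      j2 <- if (d[2] > 1) reflect(i2 + o2, d[2]) else i2
      j3 <- if (d[3] > 1) reflect(i3 + o3, d[3]) else i3
      w1 <- if (d[1] > 1) k1[o1 + r + 1] else (if (o1 == 0) 1 else 0)
      w2 <- if (d[2] > 1) k1[o2 + r + 1] else (if (o2 == 0) 1 else 0)
      w3 <- if (d[3] > 1) k1[o3 + r + 1] else (if (o3 == 0) 1 else 0)
      acc <- acc + w1 * w2 * w3 * x[j1, j2, j3]
    }
    out[i1, i2, i3] <- acc
  }
  out
}

# Adjusted Rand error by direct pair counting over all voxel pairs.
oracle_arand_pairs <- function(seg, gt) {
  keep <- gt > 0
  s <- as.integer(seg[keep]); g <- as.integer(gt[keep])
  n <- length(s)
  same_s <- outer(s, s, "==")[upper.tri(diag(n))]
  same_g <- outer(g, g, "==")[upper.tri(diag(n))]
  a <- as.numeric(sum(same_s & same_g))    # pairs together in both
  sum_a <- as.numeric(sum(same_g))         # pairs together in gt
  sum_b <- as.numeric(sum(same_s))         # pairs together in seg
  total <- n * (n - 1) / 2
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  ari <- (a - expected) / (max_index - expected)
  1 - ari
}

# Conditional entropies by direct p log p summation over the joint table.
oracle_voi <- function(seg, gt) {
  keep <- gt > 0
  s <- as.integer(seg[keep]); g <- as.integer(gt[keep])
  n <- length(s)
  tab <- table(s, g)
  p <- tab / n
  pg <- colSums(p); ps <- rowSums(p)
  split <- 0; merge <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) {
      split <- split - p[i, j] * log(p[i, j] / pg[j])
      merge <- merge - p[i, j] * log(p[i, j] / ps[i])
    }
  }
  c(voi_split = as.numeric(split), voi_merge = as.numeric(merge))
}

# Interface enumeration: per adjacent region pair, the unique voxels of
# either region touching the other across a face, by explicit loops.
oracle_interfaces <- function(labels) {
  d <- dim(labels)
  res <- list()
  add <- function(a, b, ia, ib) {
    key <- paste(min(a, b), max(a, b))
    cur <- res[[key]]
    if (is.null(cur)) cur <- list(vox = integer(0), faces = 0L)
    cur$vox <- c(cur$vox, ia, ib)
    cur$faces <- cur$faces + 1L
    res[[key]] <<- cur
  }
  lin <- function(i1, i2, i3) i1 + d[1] * (i2 - 1) + d[1] * d[2] * (i3 - 1)
  for (i3 in seq_len(d[3])) for (i2 in seq_len(d[2])) for (i1 in seq_len(d[1])) {
    la <- labels[i1, i2, i3]
    if (i1 < d[1] && labels[i1 + 1, i2, i3] != la)
      add(la, labels[i1 + 1, i2, i3], lin(i1, i2, i3), lin(i1 + 1, i2, i3))
    if (i2 < d[2] && labels[i1, i2 + 1, i3] != la)
      add(la, labels[i1, i2 + 1, i3], lin(i1, i2, i3), lin(i1, i2 + 1, i3))
    if (i3 < d[3] && labels[i1, i2, i3 + 1] != la)
      add(la, labels[i1, i2, i3 + 1], lin(i1, i2, i3), lin(i1, i2, i3 + 1))
  }
  lapply(res, function(e) list(vox = unique(e$vox), faces = e$faces))
}

# Per-window SSIM evaluated directly window by window (uniform window,
# sample covariance), averaged over fully interior windows.
oracle_ssim <- function(x, y, window = 7, data_range = 1) {
  d <- dim(x)
  r <- (window - 1) / 2
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  active <- d > 1
  rs <- ifelse(active, r, 0)
  vals <- c()
  for (i3 in seq((rs[3] + 1), d[3] - rs[3])) {
    for (i2 in seq((rs[2] + 1), d[2] - rs[2])) {
      for (i1 in seq((rs[1] + 1), d[1] - rs[1])) {
        wx <- x[(i1 - rs[1]):(i1 + rs[1]), (i2 - rs[2]):(i2 + rs[2]),
                (i3 - rs[3]):(i3 + rs[3])]
        wy <- y[(i1 - rs[1]):(i1 + rs[1]), (i2 - rs[2]):(i2 + rs[2]),
                (i3 - rs[3]):(i3 + rs[3])]
        m1 <- mean(wx); m2 <- mean(wy)
        v1 <- stats::var(as.vector(wx)); v2 <- stats::var(as.vector(wy))
        cv <- stats::cov(as.vector(wx), as.vector(wy))
        vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * cv + C2)) /
                        ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
      }
    }
  }
  mean(vals)
}

# Random label pair on a small grid for metric cross-checks.
random_label_pair <- function(shape, k1, k2, seed) {
  set.seed(seed)
  list(seg = array(sample.int(k1, prod(shape), replace = TRUE), shape),
       gt = array(sample.int(k2, prod(shape), replace = TRUE), shape))
}

# Hand-built RAG from an explicit edge list (u, v, p).
make_rag <- function(n, edges) {
  structure(list(
    nodes = data.frame(id = seq_len(n), size = rep(1L, n)),
    edges = data.frame(u = edges$u, v = edges$v, mean_prob = edges$p,
                       contact_area = edges$area %||% rep(1L, length(edges$u))),
    shape = c(1L, 1L, n)), class = "rag")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Random signed graph wrapped as a RAG (weights supplied separately).
random_signed_graph <- function(n, seed, p_edge = 0.7) {
  set.seed(seed)
  all_e <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(all_e)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  e <- all_e[keep, , drop = FALSE]
  list(rag = make_rag(n, list(u = e[, 1], v = e[, 2],
                              p = rep(0.5, nrow(e)))),
       w = stats::rnorm(nrow(e)))
}

# Two-level Voronoi construction: ground-truth "cells" (parents) subdivided
# into supervoxels (children); returns the child label volume, the parent
# cluster of each child, and a clean RAG with p = 0 within a parent and
# p = 1 between parents.
make_clean_rag <- function(shape = c(20, 20, 20), n_parent = 4,
                           n_child = 12, seed = 1) {
  parents <- generate_voronoi_labels(
    tissue_sim_config(shape = shape, n_cells = n_parent, rng_seed = seed))
  children <- generate_voronoi_labels(
    tissue_sim_config(shape = shape, n_cells = n_child, rng_seed = seed + 500))
  # digitized Voronoi regions are not guaranteed 6-connected: split both
  # levels into connected components so every graph object is connected
  parents <- split_components_test(parents)
  combo <- (parents - 1L) * (max(children) + 1L) + children
  combo <- split_components_test(combo)
  parent_of <- sapply(seq_len(max(combo)), function(i) {
    unique(parents[combo == i])[1]
  })
  fp <- tissueseg:::face_pairs(combo)
  key <- paste(fp$u, fp$v)
  first <- !duplicated(key)
  e <- fp[first, ]
  p <- ifelse(parent_of[e$u] == parent_of[e$v], 0, 1)
  list(rag = make_rag(max(combo), list(u = e$u, v = e$v, p = p)),
       parent_of = parent_of, labels = combo, parents = parents)
}

# Split every label of a full partition into its 6-connected components.
split_components_test <- function(labels) {
  out <- array(0L, dim(labels))
  nxt <- 0L
  for (l in unique(as.vector(labels))) {
    cc <- tissueseg:::cpp_label6(array(as.integer(labels == l), dim(labels)))
    out[cc > 0] <- cc[cc > 0] + nxt
    nxt <- nxt + max(cc)
  }
  out
}

densify_labels_test <- function(labels) {
  u <- unique(as.vector(labels))
  out <- array(match(labels, u), dim(labels))
  storage.mode(out) <- "integer"
  out
}

# Shared small fixtures for the corrupted-volume experiments.
corrupted_fixture <- function(seed, shape = c(64L, 64L, 64L), n_cells = 20L) {
  cfg <- tissue_sim_config(shape = shape, n_cells = n_cells,
                           membrane_sigma = 0, noise_gaussian_sd = 0.1,
                           noise_poisson_scale = 0, gap_fraction = 0.05,
                           rng_seed = seed)
  labels <- generate_voronoi_labels(cfg)
  target <- labels_to_boundary_target(labels, sigma = 1.0)
  list(labels = labels, target = target,
       bmap = corrupt_boundary_map(target, cfg))
}

# Self-cleaning temporary directory for IO tests.
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("tseg")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
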