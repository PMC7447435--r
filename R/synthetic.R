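#' Configuration for the synthetic tissue simulator
#'
#' Bundles the parameters used to generate Voronoi ground-truth labelings and
#' to corrupt membrane/boundary signal so that the whole segmentation pipeline
#' can be exercised without microscopy data. Defaults describe the standard
#' study conditions used throughout the package's tests: moderately blurred
#' membranes (\code{membrane_sigma = 1} voxel), additive Gaussian noise of
#' sd 0.1 on a unit-amplitude membrane signal, no shot noise, and 5\% of
#' membrane voxels dropped to emulate locally weak boundary staining.
#'
#' @param shape integer vector of 3 positive sizes, axis order (z, y, x).
#' @param n_cells number of Voronoi cells; must not exceed \code{prod(shape)}.
#' @param membrane_sigma Gaussian blur (in voxels) applied to the membrane
#'   signal; 0 disables blurring.
#' @param noise_gaussian_sd sd of additive Gaussian noise.
#' @param noise_poisson_scale scale of signal-dependent shot noise; the
#'   corrupted value is \code{rpois(x / s) * s} (variance \code{s * x}),
#'   0 disables it.
#' @param gap_fraction fraction of membrane-surface voxels zeroed (before
#'   blurring) to simulate boundary drop-outs, in \[0, 1\].
#' @param rng_seed integer seed making every simulator bit-reproducible.
#' @return an object of class \code{tissue_sim_config}.
#' @export
tissue_sim_config <- function(shape = c(64L, 64L, 64L), n_cells = 20L,
                              membrane_sigma = 1.0, noise_gaussian_sd = 0.1,
                              noise_poisson_scale = 0, gap_fraction = 0.05,
                              rng_seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("shape must be 3 positive integers")
  }
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L || n_cells > prod(shape)) {
    stop("n_cells must be in [1, prod(shape)]")
  }
  if (membrane_sigma < 0) stop("membrane_sigma must be >= 0")
  if (noise_gaussian_sd < 0) stop("noise_gaussian_sd must be >= 0")
  if (noise_poisson_scale < 0) stop("noise_poisson_scale must be >= 0")
  if (gap_fraction < 0 || gap_fraction > 1) stop("gap_fraction must be in [0, 1]")
  structure(list(shape = shape, n_cells = n_cells,
                 membrane_sigma = membrane_sigma,
                 noise_gaussian_sd = noise_gaussian_sd,
                 noise_poisson_scale = noise_poisson_scale,
                 gap_fraction = gap_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "tissue_sim_config")
}

assert_sim_config <- function(config) {
  if (!inherits(config, "tissue_sim_config")) {
    stop("config must be created by tissue_sim_config()")
  }
  config
}

#' Generate a Voronoi ground-truth label volume
#'
#' Samples \code{n_cells} distinct seed voxels uniformly at random and assigns
#' every voxel the label of its nearest seed (Euclidean distance in voxel
#' units, ties broken by the lowest seed index). The result is a complete
#' partition with labels dense in 1..n_cells; cells are convex, emulating the
#' densely packed, convex-ish cells of plant tissue.
#'
#' @param config a [tissue_sim_config()].
#' @return integer label array of dim \code{config$shape}.
#' @export
generate_voronoi_labels <- function(config) {
  config <- assert_sim_config(config)
  d <- config$shape
  n <- prod(d)
  seeds <- with_seed(config$rng_seed, sample.int(n, config$n_cells))
  sz <- (seeds - 1L) %% d[1]
  sy <- ((seeds - 1L) %/% d[1]) %% d[2]
  sx <- (seeds - 1L) %/% (d[1] * d[2])
  cz <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  cy <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  cx <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  best <- rep.int(Inf, n)
  lab <- integer(n)
  for (k in seq_len(config$n_cells)) {
    d2 <- (cz - sz[k])^2 + (cy - sy[k])^2 + (cx - sx[k])^2
    upd <- d2 < best            # strict: earlier seed wins ties
    best[upd] <- d2[upd]
    lab[upd] <- k
  }
  dim(lab) <- d
  lab
}

#' Boundary training target from a ground-truth labeling
#'
#' Marks the two-voxel-thick boundary between differently labeled regions
#' (both voxels flanking every inter-label face, 6-connectivity), convolves it
#' with an isotropic Gaussian of width \code{sigma}, and thresholds the result
#' at 0.5, yielding a binary \{0, 1\} target map. \code{sigma = 0} returns the
#' raw two-voxel-thick mask. Faces against label 0 (ignore/background) are
#' not boundaries. The output is invariant under permutations of the positive
#' label values.
#'
#' @param labels integer label volume with at least one positive label.
#' @param sigma Gaussian width in voxels; default 1.
#' @return numeric array of the same shape with values in \{0, 1\}.
#' @export
labels_to_boundary_target <- function(labels, sigma = 1.0) {
  labels <- assert_label_volume(labels)
  if (sigma < 0) stop("sigma must be >= 0")
  if (!any(labels > 0L)) stop("label volume has no positive labels")
  mask <- cpp_boundary_mask(labels)
  if (sigma == 0) {
    out <- array(as.numeric(mask), dim(labels))
  } else {
    blurred <- cpp_gaussian_blur3d(array(as.numeric(mask), dim(labels)), sigma)
    out <- array(as.numeric(blurred > 0.5), dim(labels))
  }
  out
}

# Shared corruption chain: zero a fraction of "membrane" voxels, blur, add
# Gaussian noise, add shot noise. `positive` flags the voxels eligible for
# gap deletion. Returns the corrupted array (not yet clipped).
corrupt_signal <- function(x, positive, config, seed_offset) {
  with_seed(config$rng_seed + seed_offset, {
    if (config$gap_fraction > 0) {
      idx <- which(positive)
      n_zero <- round(config$gap_fraction * length(idx))
      if (n_zero > 0) x[sample(idx, n_zero)] <- 0
    }
    if (config$membrane_sigma > 0) {
      x <- cpp_gaussian_blur3d(x, config$membrane_sigma)
    }
    if (config$noise_gaussian_sd > 0) {
      x <- x + rnorm(length(x), sd = config$noise_gaussian_sd)
    }
    if (config$noise_poisson_scale > 0) {
      s <- config$noise_poisson_scale
      lam <- pmax(x, 0) / s
      x <- array(rpois(length(x), lam) * s, dim(x))
    }
    x
  })
}

#' Simulate a membrane-stained intensity volume
#'
#' Paints a bright (value 1) membrane signal on the inter-label boundary mask
#' and a dark (value 0) interior, deletes a \code{gap_fraction} of the
#' membrane voxels (before blurring, emulating weak-boundary drop-outs),
#' blurs with \code{membrane_sigma}, then adds Gaussian and shot noise.
#' Negative values are clipped to 0. Bit-reproducible given
#' \code{config$rng_seed}.
#'
#' @param labels ground-truth label volume.
#' @param config a [tissue_sim_config()].
#' @return numeric intensity array of the same shape.
#' @export
simulate_membrane_image <- function(labels, config) {
  labels <- assert_label_volume(labels)
  config <- assert_sim_config(config)
  mask <- cpp_boundary_mask(labels)
  img <- array(as.numeric(mask), dim(labels))
  img <- corrupt_signal(img, mask == 1L, config, seed_offset = 1000003L)
  pmax(img, 0)
}

#' Corrupt a boundary probability map
#'
#' Applies the same corruption chain as [simulate_membrane_image()] directly
#' to a probability map: gap deletion on voxels with value > 0.5, Gaussian
#' blur, additive Gaussian noise, shot noise; the result is clipped back to
#' \[0, 1\]. Used to emulate imperfect CNN output (blurry or locally missing
#' boundary evidence) when testing the partitioning stages in isolation.
#'
#' @param bmap boundary probability map in \[0, 1\].
#' @param config a [tissue_sim_config()].
#' @return corrupted boundary map in \[0, 1\], same shape.
#' @export
corrupt_boundary_map <- function(bmap, config) {
  bmap <- assert_boundary_map(bmap)
  config <- assert_sim_config(config)
  out <- corrupt_signal(bmap, bmap > 0.5, config, seed_offset = 2000003L)
  .clamp(out, 0, 1)
}
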