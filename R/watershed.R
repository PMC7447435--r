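#' Distance-transform watershed parameters
#'
#' @param delta boundary-probability threshold in (0, 1); default 0.4.
#' @param seed_sigma Gaussian smoothing (voxels) of the distance transform
#'   before seed extraction; default 2.
#' @param min_region_voxels regions smaller than this are merged into the
#'   neighbor with the largest shared surface; default 50.
#' @param use_2d_slices run the watershed independently per z-slice (2D
#'   supervoxels) instead of in 3D.
#' @param flood_alpha weight of the smoothed boundary map in the flooding
#'   priority (the remainder weights the inverted, normalized distance
#'   transform); default 0.9. With \code{flood_alpha = 0} flooding runs on
#'   the pure negated distance transform.
#' @param flood_sigma Gaussian smoothing of the boundary map used in the
#'   flooding priority; default 2.
#' @return an object of class \code{watershed_params}.
#' @export
watershed_params <- function(delta = 0.4, seed_sigma = 2.0,
                             min_region_voxels = 50L, use_2d_slices = FALSE,
                             flood_alpha = 0.9, flood_sigma = 2.0) {
  if (delta <= 0 || delta >= 1) stop("delta must be strictly between 0 and 1")
  if (seed_sigma < 0) stop("seed_sigma must be >= 0")
  if (min_region_voxels < 0) stop("min_region_voxels must be >= 0")
  if (flood_alpha < 0 || flood_alpha > 1) stop("flood_alpha must be in [0, 1]")
  structure(list(delta = delta, seed_sigma = seed_sigma,
                 min_region_voxels = as.integer(min_region_voxels),
                 use_2d_slices = isTRUE(use_2d_slices),
                 flood_alpha = flood_alpha, flood_sigma = flood_sigma),
            class = "watershed_params")
}

#' Distance-transform watershed oversegmentation
#'
#' Thresholds the boundary map at \code{delta}, computes the Euclidean
#' distance of every voxel to the thresholded boundary, smooths the distance
#' map with a Gaussian of width \code{seed_sigma}, places one seed per
#' regional maximum of the smoothed map (a connected plateau yields exactly
#' one seed, at its lowest scan-order voxel), floods the whole volume by
#' descending smoothed distance (6-connectivity, ties broken by scan order),
#' and finally merges regions smaller than \code{min_region_voxels} into the
#' neighbor sharing the largest contact surface. The output is a complete
#' partition with labels dense in 1..K; it is deterministic for identical
#' inputs.
#'
#' @param bmap boundary probability map in \[0, 1\].
#' @param params a [watershed_params()].
#' @return integer label volume (supervoxels).
#' @export
dt_watershed <- function(bmap, params = watershed_params()) {
  bmap <- assert_boundary_map(bmap)
  if (params$use_2d_slices) {
    d <- dim(bmap)
    out <- array(0L, d)
    offset <- 0L
    p2 <- params; p2$use_2d_slices <- FALSE
    for (z in seq_len(d[1])) {
      sl <- bmap[z, , , drop = FALSE]
      lab <- dt_watershed(sl, p2)
      out[z, , ] <- lab + offset
      offset <- offset + max(lab)
    }
    return(out)
  }
  B <- array(as.integer(bmap > params$delta), dim(bmap))
  n_fg <- sum(B)
  if (n_fg == length(B)) {
    warning("boundary mask covers the whole volume; returning a single region")
    return(array(1L, dim(bmap)))
  }
  if (n_fg == 0L) {
    # no boundary evidence at all: a single region covers the volume
    return(array(1L, dim(bmap)))
  }
  D <- sqrt(cpp_edt_sq(B))
  Ds <- cpp_gaussian_blur3d(D, params$seed_sigma)
  seeds <- cpp_regional_maxima(Ds)
  # Flooding priority (popped highest-first): a blend of the negated smoothed
  # boundary map and the normalized distance transform. Dominating with the
  # smoothed boundary map places the watershed lines on the boundary-evidence
  # ridge (and carries them across local signal gaps) instead of on the
  # distance-geometry midline, which is what pure -D flooding would do.
  a <- params$flood_alpha
  prio <- if (a > 0) {
    bs <- cpp_gaussian_blur3d(bmap, params$flood_sigma)
    a * (1 - bs) + (1 - a) * D / max(D)
  } else {
    D / max(D)
  }
  lab <- cpp_seeded_watershed(prio, seeds)
  remove_small_regions(lab, params$min_region_voxels)
}

#' Merge undersized regions into their best neighbor
#'
#' Every region smaller than \code{min_voxels} is absorbed by the adjacent
#' region with which it shares the largest contact surface (face count; ties
#' broken by the lowest neighbor label). Smallest regions are merged first;
#' the sole remaining region is never removed. Labels are re-densified to
#' 1..K in scan order of first occurrence.
#'
#' @param labels complete partition (all voxels > 0).
#' @param min_voxels minimum surviving region size.
#' @return integer label volume.
#' @export
remove_small_regions <- function(labels, min_voxels) {
  labels <- assert_label_volume(labels)
  if (any(labels == 0L)) stop("labels must be a complete partition (no zeros)")
  sizes <- tabulate(labels)
  ids <- which(sizes > 0L)
  if (length(ids) <= 1L || min_voxels <= 1L) return(densify_labels(labels))
  fp <- face_pairs(labels)
  u <- v <- area <- NULL  # data.table NSE
  edges <- if (nrow(fp)) fp[, list(area = .N), by = list(u, v)] else
    data.table::data.table(u = integer(), v = integer(), area = integer())
  parent <- seq_len(length(sizes))           # label -> current region id
  repeat {
    alive <- which(sizes > 0L)
    if (length(alive) <= 1L) break
    small <- alive[sizes[alive] < min_voxels]
    if (length(small) == 0L) break
    s <- small[which.min(sizes[small])]      # smallest first; ties -> lowest id
    nb <- edges[u == s | v == s]
    if (nrow(nb) == 0L) { sizes[s] <- min_voxels; next }  # isolated (cannot occur in a partition)
    nb_id <- ifelse(nb$u == s, nb$v, nb$u)
    best <- nb_id[order(-nb$area, nb_id)][1L]
    # merge s into best
    parent[parent == s] <- best
    sizes[best] <- sizes[best] + sizes[s]
    sizes[s] <- 0L
    edges[u == s, u := best]
    edges[v == s, v := best]
    sw <- edges$u > edges$v
    if (any(sw)) {
      tmp <- edges$u[sw]; edges$u[sw] <- edges$v[sw]; edges$v[sw] <- tmp
    }
    edges <- edges[u != v, list(area = sum(area)), by = list(u, v)]
  }
  densify_labels(array(parent[labels], dim(labels)))
}
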