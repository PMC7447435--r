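#' Build the supervoxel region adjacency graph
#'
#' Nodes are the supervoxel labels (with voxel counts); one edge connects
#' every 6-adjacent region pair. An edge's interface voxel set contains every
#' voxel of either region that touches the other region across a face; the
#' edge carries the arithmetic mean of the boundary-map values over that set
#' (\code{mean_prob}) and the number of touching face pairs
#' (\code{contact_area}).
#'
#' @param supervoxels complete integer partition (labels 1..K).
#' @param bmap boundary probability map of the same shape.
#' @return an object of class \code{rag}: list with \code{nodes}
#'   (data.frame id, size), \code{edges} (data.frame u, v, mean_prob,
#'   contact_area) and \code{shape}.
#' @export
build_rag <- function(supervoxels, bmap) {
  supervoxels <- assert_label_volume(supervoxels)
  bmap <- assert_boundary_map(bmap)
  assert_same_shape(supervoxels, bmap)
  if (any(supervoxels == 0L)) stop("supervoxels must be a complete partition")
  sizes <- tabulate(supervoxels)
  ids <- which(sizes > 0L)
  fp <- face_pairs(supervoxels)
  u <- v <- vox <- mean_prob <- contact_area <- NULL  # data.table NSE
  if (nrow(fp) == 0L) {
    edges <- data.frame(u = integer(), v = integer(),
                        mean_prob = numeric(), contact_area = integer())
  } else {
    areas <- fp[, list(contact_area = .N), by = list(u, v)]
    verts <- unique(data.table::data.table(
      u = c(fp$u, fp$u), v = c(fp$v, fp$v), vox = c(fp$ia, fp$ib)))
    pb <- as.numeric(bmap)
    means <- verts[, list(mean_prob = mean(pb[vox])), by = list(u, v)]
    edges <- merge(means, areas, by = c("u", "v"))
    data.table::setkey(edges, u, v)
    edges <- as.data.frame(edges)
  }
  structure(list(nodes = data.frame(id = ids, size = sizes[ids]),
                 edges = edges, shape = dim(supervoxels)),
            class = "rag")
}

#' Signed edge weight from a boundary probability
#'
#' Maps a mean boundary probability to a signed merge affinity:
#' \code{w = log((1 - p) / p) + log((1 - beta_bias) / beta_bias)}.
#' Positive weights are attractive (merge evidence), negative repulsive.
#' The mapping is strictly decreasing in both \code{p} and \code{beta_bias},
#' so a larger bias favors splitting (over-segmentation); at
#' \code{p = beta_bias = 0.5} the weight is exactly 0. Probabilities are
#' clamped to \[1e-5, 1 - 1e-5\] first.
#'
#' @param p probability (vectorized) in \[0, 1\].
#' @param beta_bias bias strictly inside (0, 1); default 0.6.
#' @return signed weight(s).
#' @export
to_signed_weight <- function(p, beta_bias = 0.6) {
  if (beta_bias <= 0 || beta_bias >= 1) stop("beta_bias must be in (0, 1)")
  p <- .clamp(p, 1e-5, 1 - 1e-5)
  log((1 - p) / p) + log((1 - beta_bias) / beta_bias)
}

# Internal: edges with signed weights, renumbered to contiguous node indices
# 1..n. Returns list(n, ids, edges(u, v, w, area)).
rag_graph <- function(rag, beta_bias, weights = NULL) {
  if (!inherits(rag, "rag")) stop("expected a rag object")
  ids <- rag$nodes$id
  e <- rag$edges
  w <- if (is.null(weights)) to_signed_weight(e$mean_prob, beta_bias)
       else {
         if (length(weights) != nrow(e)) stop("need one weight per edge")
         as.numeric(weights)
       }
  data.frame(u = match(e$u, ids), v = match(e$v, ids), w = w,
             area = as.numeric(e$contact_area))
}

finalize_partition <- function(assign_vec, rag) {
  # densify cluster ids to 1..K ordered by smallest member node
  first <- tapply(seq_along(assign_vec), assign_vec, min)
  ord <- order(first)
  remap <- integer(length(first))
  remap[as.integer(names(first))[ord]] <- seq_along(ord)
  out <- remap[assign_vec]
  names(out) <- rag$nodes$id
  out
}

#' Partition objective (multicut cost)
#'
#' Sum of signed edge weights over cut edges (edges whose endpoints lie in
#' different clusters); the quantity minimized by the multicut solvers.
#'
#' @param rag a [build_rag()] graph.
#' @param partition integer cluster assignment per node (in node order).
#' @param beta_bias bias used for the signed weights.
#' @return scalar objective value.
#' @export
multicut_objective <- function(rag, partition, beta_bias = 0.6) {
  g <- rag_graph(rag, beta_bias)
  if (nrow(g) == 0L) return(0)
  sum(g$w[partition[g$u] != partition[g$v]])
}

#' Project a node partition back to the voxel grid
#'
#' Relabels every voxel by the cluster id of its supervoxel; output labels
#' are dense in 1..K.
#'
#' @param supervoxels supervoxel label volume.
#' @param partition integer vector mapping each RAG node (in node-id order)
#'   to its cluster; typically the output of a partitioner.
#' @return integer label volume.
#' @export
project_partition <- function(supervoxels, partition) {
  supervoxels <- assert_label_volume(supervoxels)
  ids <- sort(unique(as.integer(supervoxels[supervoxels > 0L])))
  if (!is.null(names(partition))) {
    m <- match(ids, as.integer(names(partition)))
    if (anyNA(m)) stop("partition is missing supervoxel ids: ",
                       paste(ids[is.na(m)], collapse = ", "))
    lut <- integer(max(ids))
    lut[ids] <- as.integer(partition[m])
  } else {
    if (length(partition) < max(ids)) {
      stop("partition is missing supervoxel ids")
    }
    lut <- as.integer(partition)
  }
  out <- array(lut[supervoxels], dim(supervoxels))
  ks <- sort(unique(as.vector(out[out > 0L])))
  if (identical(ks, seq_along(ks))) {
    storage.mode(out) <- "integer"
    out                      # already dense: keep the caller's cluster ids
  } else {
    densify_labels(out)
  }
}
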