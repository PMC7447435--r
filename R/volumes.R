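# Shared checks and small array utilities. Volumes are plain arrays with
# dim = c(z, y, x); 2D images travel as single-slice volumes (1, y, x).

as_vol3d <- function(x, what = "volume") {
  if (is.null(dim(x))) stop(what, " must be a 2D or 3D array")
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x))
  if (length(dim(x)) != 3L) stop(what, " must be a 2D or 3D array")
  x
}

assert_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(what, " must have identical shapes (",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"), ")")
  }
}

assert_boundary_map <- function(x, what = "boundary map") {
  x <- as_vol3d(x, what)
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    stop(what, " values must lie in [0, 1]")
  }
  x
}

assert_label_volume <- function(x, what = "label volume") {
  x <- as_vol3d(x, what)
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop(what, " must contain non-negative integers")
  }
  storage.mode(x) <- "integer"
  x
}

# Relabel positive labels to dense 1..K, ordered by first occurrence in scan
# order; zeros are preserved.
densify_labels <- function(labels) {
  pos <- labels > 0L
  u <- unique(labels[pos])
  out <- labels
  out[pos] <- match(labels[pos], u)
  storage.mode(out) <- "integer"
  out
}

# Symmetric ("mirror") padding: edge sequence d c b a | a b c d | d c b a.
# Pad widths may not exceed the axis length.
mirror_pad <- function(x, before, after) {
  d <- dim(x)
  idx <- vector("list", 3L)
  for (a in 1:3) {
    if (before[a] > d[a] || after[a] > d[a]) {
      stop("mirror padding wider than the axis (", d[a], " voxels)")
    }
    idx[[a]] <- c(rev(seq_len(before[a])), seq_len(d[a]),
                  d[a] - seq_len(after[a]) + 1L)
  }
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Face-adjacency edge list of a fully labeled volume: one row per ordered
# face pair, columns u <= v plus the linear indices of the two flanking
# voxels. Used by the RAG builder and small-region removal.
face_pairs <- function(labels) {
  d <- dim(labels)
  n <- prod(d)
  lab <- as.integer(labels)
  res_u <- list(); res_v <- list(); res_ia <- list(); res_ib <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  k <- 0L
  for (a in 1:3) {
    if (d[a] < 2L) next
    i1 <- if (a == 1) seq_len(d[1] - 1L) else seq_len(d[1])
    i2 <- if (a == 2) seq_len(d[2] - 1L) else seq_len(d[2])
    i3 <- if (a == 3) seq_len(d[3] - 1L) else seq_len(d[3])
    base <- as.vector(outer(outer(i1 - 1L, (i2 - 1L) * d[1], "+"),
                            (i3 - 1L) * d[1] * d[2], "+")) + 1L
    nb <- base + strides[a]
    la <- lab[base]; lb <- lab[nb]
    sel <- la != lb
    if (!any(sel)) next
    k <- k + 1L
    res_u[[k]] <- pmin(la[sel], lb[sel])
    res_v[[k]] <- pmax(la[sel], lb[sel])
    res_ia[[k]] <- base[sel]
    res_ib[[k]] <- nb[sel]
  }
  if (k == 0L) {
    return(data.table::data.table(u = integer(), v = integer(),
                                  ia = integer(), ib = integer()))
  }
  data.table::data.table(u = unlist(res_u), v = unlist(res_v),
                         ia = unlist(res_ia), ib = unlist(res_ib))
}
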